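test_that("sd_from_sem applies the classical identity", {
  expect_equal(sd_from_sem(3, 0.75), 6)
  expect_equal(sd_from_sem(2, 0), 2)
  expect_equal(sd_from_sem(2.5, 0.84), 6.25)
  expect_error(sd_from_sem(3, 1), "reliability")
  expect_error(sd_from_sem(3, -0.1), "reliability")
  expect_error(sd_from_sem(-1, 0.5), "sem")
})

test_that("mixture_variance adds the dispersion of component means", {
  expect_equal(mixture_variance(c(0.3, 0.7), c(5, 5), c(2, 4)), 0.3 * 2 + 0.7 * 4)
  expect_equal(mixture_variance(c(0.5, 0.5), c(0, 2), c(1, 1)), 2)
  expect_equal(mixture_variance(1, 3, 7), 7)
  expect_error(mixture_variance(c(0.5, 0.5), c(0, 1, 2), c(1, 1)), "length")
  expect_error(mixture_variance(c(0.5, 0.6), c(0, 1), c(1, 1)), "sum to 1")
  # dispersion term is nonnegative: mixture variance >= mean variance
  set.seed(4)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    w <- runif(k); w <- w / sum(w)
    mu <- rnorm(k, 0, 5); v <- runif(k, 0.5, 4)
    expect_gte(mixture_variance(w, mu, v), sum(w * v) - 1e-12)
  }
})

test_that("mixture_variance matches the pooled-sample oracle", {
  set.seed(8)
  w <- c(0.3, 0.7); mu <- c(1, 5); sd <- c(2, 1)
  n <- 1e6
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  pooled <- rnorm(n, mu[comp], sd[comp])
  expect_equal(mixture_variance(w, mu, sd^2), var(pooled),
               tolerance = 0.005)
})

test_that("band weights are proportional overlaps summing to one", {
  bands <- data.frame(age_min_months = c(36L, 60L),
                      age_max_months = c(60L, 84L))
  bw <- band_weights(c(36L, 84L), bands)
  expect_equal(bw$weight, c(0.5, 0.5))
  expect_equal(band_weights(c(36L, 60L), bands)$weight, 1)
  expect_error(band_weights(c(36L, 96L), bands), "cover only")

  tb <- generate_table_set()
  st <- sem_table(tb, "Receptive")
  bw2 <- band_weights(c(144L, 204L), st)
  expect_equal(sum(bw2$weight), 1)
  expect_identical(nrow(bw2), 5L)   # five 12-month bands in 12-16y
})

test_that("the anchoring chain traces V-scale band -> raw -> GSV", {
  tb <- chain_fixture()
  # impairment 3 targets V-scale 6; band raws 10-14 -> mean raw 12 ->
  # gsv(12) = 40
  sc <- scenario(c(3, 6), 3, "X")
  expect_identical(sc$midpoint_months, 60L)
  expect_equal(scenario_mean_gsv(tb, sc), 40)
  # degenerate floor chain: V-scale 1 band is raw 0 alone -> gsv 10
  sc5 <- scenario(c(3, 6), 5, "Y")
  expect_equal(scenario_mean_gsv(tb, sc5), 10)
  # single SEM band: sigma is sd_from_sem directly
  expect_equal(scenario_sigma(tb, sc), 6)            # 3 / sqrt(0.25)
  expect_equal(scenario_sigma(tb, sc5), 10)          # 4 / sqrt(0.16)
})

test_that("an absent target band signals an infeasible scenario", {
  tb <- chain_fixture()
  # merge the V-scale 9 band of X into 8 so 9 is unattainable
  v <- tb$vscale
  i8 <- which(v$subdomain == "X" & v$vscale == 8)
  i9 <- which(v$subdomain == "X" & v$vscale == 9)
  v$raw_max[i8] <- v$raw_max[i9]
  v <- v[-i9, ]
  tb2 <- table_set(tb$gsv, v, tb$sem)
  sc <- scenario(c(3, 6), 2, "X")   # targets V-scale 9
  expect_error(scenario_mean_gsv(tb2, sc), class = "abilitysim_infeasible")
  # intact table: V-scale 9 band is raws 19-20 -> mean raw 20 -> gsv 60
  expect_equal(scenario_mean_gsv(tb, sc), 60)
})

test_that("scenario sigma is invariant to splitting an age band in half", {
  tb <- chain_fixture()
  split <- function(d) {
    a <- d; b <- d
    a$age_max_months <- 60L
    b$age_min_months <- 60L
    rbind(a, b)
  }
  tb2 <- table_set(tb$gsv, split(tb$vscale), split(tb$sem))
  sc <- scenario(c(3, 6), 3, "X")
  expect_equal(scenario_sigma(tb2, sc), scenario_sigma(tb, sc))
})

test_that("treatment delta is 0.8 sigma or zero", {
  expect_equal(treatment_delta(10, "large"), 8)
  expect_equal(treatment_delta(10, "zero"), 0)
  for (s in c(0.5, 3, 17)) expect_equal(treatment_delta(s, "large") / s, 0.8)
  expect_error(treatment_delta(0, "large"), "sigma")
})

test_that("planned and covariate-adjusted sample sizes match the design", {
  expect_identical(required_total_n(0.8, 0.05, 0.90), 66L)
  # hand evaluation: 4 * qnorm(.975)^2 / 0.64 = 24.009 -> even ceiling
  expect_identical(required_total_n(0.8, 0.05, 0.50), 26L)
  pw <- seq(0.5, 0.95, by = 0.05)
  expect_true(all(diff(vapply(pw, function(p) required_total_n(0.8, 0.05, p),
                              integer(1))) >= 0))
  expect_identical(ancova_adjusted_n(66L, 0.8), 24L)
  expect_identical(ancova_adjusted_n(50L, 0), 50L)
  expect_identical(ancova_adjusted_n(100L, 0.5), 76L)
})

test_that("the normal-approximation N agrees with a t-based search within 2", {
  # independent oracle: smallest even total with t-test power >= 90%
  n_arm <- 2
  while (stats::power.t.test(n = n_arm, delta = 0.8, sd = 1,
                             sig.level = 0.05)$power < 0.90) {
    n_arm <- n_arm + 1
  }
  expect_lte(abs(2 * n_arm - required_total_n(0.8, 0.05, 0.90)), 2)
})

test_that("design_config derives the simulated sample size", {
  d <- design_config()
  expect_identical(d$n_planned, 66L)
  expect_identical(d$n_total, 24L)
  expect_output(print(d), "simulated N=24")
})
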