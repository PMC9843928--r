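test_that("fit_ancova matches the explicit normal-equations solve", {
  set.seed(33)
  for (i in 1:200) {
    n <- 2 * sample(4:20, 1)
    arm <- rep(0:1, each = n / 2)
    b <- rnorm(n, 50, 8)
    e <- 3 + 0.8 * b + 4 * arm + rnorm(n, 0, 5)
    fit <- fit_ancova(e, b, arm)
    orc <- ancova_oracle(e, b, arm)
    expect_equal(fit$beta_group, orc$beta, tolerance = 1e-10)
    expect_equal(fit$t_stat, orc$t, tolerance = 1e-9)
    expect_lt(abs(fit$p_value - orc$p), 1e-9)
  }
})

test_that("rank deficiency and zero residual variance are degenerate", {
  arm <- rep(0:1, each = 6)
  b <- rep(5, 12)                      # constant baseline: rank deficient
  e <- rnorm(12)
  expect_identical(fit_ancova(e, b, arm)$status, "degenerate")
  b2 <- rnorm(12)
  expect_identical(fit_ancova(b2, b2, arm)$status, "degenerate")  # RSS = 0
  expect_identical(fit_ancova(rep(1, 12), rep(1, 12), arm)$status,
                   "degenerate")
  expect_error(fit_ancova(e, b, rep(0, 12)), "both arms")
  expect_error(fit_ancova(e[1:10], b, arm), "equal length")
})

test_that("vectorized ANCOVA agrees with the per-dataset fit", {
  set.seed(34)
  n <- 24; R <- 60
  arm <- rep(0:1, each = n / 2)
  B <- matrix(rnorm(n * R, 40, 6), n)
  Y <- 0.8 * B + matrix(rnorm(n * R, 0, 4), n) + outer(arm * 3, rep(1, R))
  # include integer-valued and degenerate columns as the V-scale path makes
  B[, 1] <- rep(1, n); Y[, 2] <- B[, 2]
  B[, 3] <- round(B[, 3]); Y[, 3] <- round(Y[, 3])
  bat <- abilitysim:::batch_ancova(B, Y, arm)
  for (j in 1:R) {
    fit <- fit_ancova(Y[, j], B[, j], arm)
    expect_identical(bat$degenerate[j], fit$status == "degenerate")
    if (fit$status == "ok") {
      expect_equal(bat$p[j], fit$p_value, tolerance = 1e-9)
      expect_equal(bat$beta[j], fit$beta_group, tolerance = 1e-9)
    }
  }
})

test_that("null p-values are uniform and reject at the nominal rate", {
  set.seed(35)
  n <- 24; R <- 10000
  arm <- rep(0:1, each = n / 2)
  B <- matrix(rnorm(n * R), n)
  Y <- 0.8 * B + matrix(rnorm(n * R, 0, 0.6), n)
  bat <- abilitysim:::batch_ancova(B, Y, arm)
  expect_false(any(bat$degenerate))
  expect_gt(stats::ks.test(bat$p, "punif")$p.value, 0.001)
  # 0.05 +/- 3 * sqrt(.05 * .95 / 10000)
  expect_lt(abs(mean(bat$p < 0.05) - 0.05), 0.007)
})

test_that("complete floors are classified per arm and timepoint", {
  mk <- function(vb, ve) {
    structure(data.frame(arm = rep(c("PBO", "TRT"), each = 12),
                         gsv_tab_baseline = 50, gsv_tab_endpoint = 50,
                         vscale_baseline = vb, vscale_endpoint = ve),
              gsv_min = 10, class = c("trial_dataset", "data.frame"))
  }
  expect_identical(classify_floor(mk(rep(1L, 24), rep(1L, 24)), "vscale"),
                   "both_floor")
  expect_identical(classify_floor(mk(rep(c(1L, 5L), each = 12),
                                     rep(c(1L, 5L), each = 12)), "vscale"),
                   "pbo_floor")
  expect_identical(classify_floor(mk(rep(5L, 24), rep(5L, 24)), "vscale"),
                   "none")
  # baseline floor alone is not a complete floor
  expect_identical(classify_floor(mk(rep(1L, 24), rep(c(1L, 2L), 12)),
                                  "vscale"), "none")
  ds <- mk(rep(2L, 24), rep(2L, 24))
  ds$gsv_tab_baseline <- rep(10, 24); ds$gsv_tab_endpoint <- rep(10, 24)
  expect_identical(classify_floor(ds, "gsv"), "both_floor")
})

test_that("rejection requires an ok fit, no complete floor, and p < alpha", {
  mkfit <- function(p, status = "ok", floor = "none") {
    structure(list(scale = "gsv", beta_group = 1, se = 1, t_stat = 1,
                   p_value = p, status = status, floor_class = floor,
                   df = 21L), class = "ancova_fit")
  }
  expect_true(decide_rejection(mkfit(0.049)))
  expect_false(decide_rejection(mkfit(0.05)))          # strict inequality
  expect_false(decide_rejection(mkfit(0.01, status = "degenerate")))
  expect_false(decide_rejection(mkfit(0.001, floor = "trt_floor")))
  # monotone in alpha: lowering alpha never converts fail to reject
  set.seed(36)
  for (i in 1:50) {
    p <- runif(1)
    a1 <- runif(1); a2 <- a1 * runif(1)   # a2 < a1
    f <- mkfit(p)
    expect_false(!decide_rejection(f, a1) && decide_rejection(f, a2))
  }
})

test_that("the closed-form power accounts for covariate imbalance", {
  exact <- ancova_power_closed_form()
  plug <- ancova_power_closed_form(method = "plug-in")
  expect_gt(plug, exact)          # ignoring imbalance overstates power
  expect_lt(plug - exact, 0.03)
  expect_gt(exact, 0.8); expect_lt(exact, 0.9)
  # at rho = 0 the design reduces to a plain two-arm comparison with a
  # noise covariate; both forms bracket the t-test power at N = 24
  tt <- stats::power.t.test(n = 12, delta = 0.8, sd = 1,
                            sig.level = 0.05)$power
  expect_lt(ancova_power_closed_form(rho = 0), tt + 0.01)
})
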