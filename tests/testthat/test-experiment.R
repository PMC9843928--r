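test_that("the scenario grid enumerates feasible cells and logs skips", {
  tb <- chain_fixture()
  g <- build_scenario_grid(tb, design_config(),
                           age_ranges = list(c(3L, 6L)))
  # 1 age range x 5 impairments x 2 subdomains, all bands present
  expect_identical(nrow(g$scenarios), 10L)
  expect_identical(nrow(g$skipped), 0L)
  expect_true(all(g$scenarios$sigma > 0))
  expect_true(all(g$scenarios$mu >= 10))

  # removing one band skips exactly that cell
  v <- tb$vscale
  i8 <- which(v$subdomain == "X" & v$vscale == 8)
  i9 <- which(v$subdomain == "X" & v$vscale == 9)
  v$raw_max[i8] <- v$raw_max[i9]
  tb2 <- table_set(tb$gsv, v[-i9, ], tb$sem)
  g2 <- build_scenario_grid(tb2, design_config(),
                            age_ranges = list(c(3L, 6L)))
  expect_identical(nrow(g2$scenarios), 9L)
  expect_identical(nrow(g2$skipped), 1L)
  expect_identical(g2$skipped$subdomain, "X")
  expect_identical(g2$skipped$impairment_sd, 2L)
})

test_that("the default synthetic grid covers the full design", {
  tb <- generate_table_set()
  g <- build_scenario_grid(tb, design_config())
  expect_identical(nrow(g$scenarios) + nrow(g$skipped), 110L)
  expect_gt(nrow(g$scenarios), 90L)
  # every feasible condition appears in both age ranges
  expect_setequal(unique(g$scenarios$age_min), c(3L, 12L))
  expect_setequal(unique(g$scenarios$impairment_sd), 1:5)
})

test_that("saturating floor tables give zero V-scale power, full floors", {
  tb <- floor_fixture()
  sc <- scenario(c(3, 6), 5, "F")
  r <- run_scenario(sc, tb, design_config(), n_reps = 300, seed = 3)
  expect_identical(r$power_vscale, 0)
  expect_identical(r$floor_rate_vscale, 1)
  expect_identical(r$degenerate_rate_vscale, 1)
  expect_gt(r$power_gsv, 0.5)   # GSV analysis unaffected by the floor
})

test_that("vectorized scenario runs agree with the per-dataset pipeline", {
  tb <- chain_fixture()
  d <- design_config()
  sc <- scenario(c(3, 6), 3, "X")
  p <- scenario_params(tb, sc, d)
  r <- run_scenario(sc, tb, d, n_reps = 400, seed = 17)
  byhand <- mean(vapply(1:400, function(i) {
    ds <- simulate_trial(p, d, sc, tb, seed = 5000 + i)
    decide_rejection(analyze_trial(ds, "gsv"), d$alpha)
  }, logical(1)))
  # same estimand, independent streams: binomial agreement
  se <- sqrt(2 * 0.86 * 0.14 / 400)
  expect_lt(abs(r$power_gsv - byhand), 4 * se)
  # determinism of the vectorized path
  expect_identical(r, run_scenario(sc, tb, d, n_reps = 400, seed = 17))
})

test_that("condition summaries follow the quantile rules", {
  res <- data.frame(
    subdomain = c("A", "B", "C"), age_min = 3L, age_max = 6L,
    impairment_sd = 2L, effect = "large", n_reps = 5000L,
    power_gsv = c(0.86, 0.86, 0.86), power_vscale = c(0.8, 0.6, 0.7),
    floor_rate_gsv = 0, floor_rate_vscale = 0,
    degenerate_rate_gsv = 0, degenerate_rate_vscale = 0,
    median_diff_gsv = 1, median_diff_vscale = 1, seed = 1L)
  s <- summarize_by_condition(res)
  expect_identical(nrow(s), 1L)
  expect_equal(s$power_gsv_median, 0.86)
  expect_equal(s$power_vscale_median, 0.7)
  expect_equal(s$decrease_min, 0.06)
  expect_equal(s$decrease_q1, 0.11)
  expect_equal(s$decrease_median, 0.16)
  expect_equal(s$decrease_q3, 0.21)
  expect_equal(s$decrease_max, 0.26)
  # quantiles are ordered, decreases nonnegative when GSV dominates
  qs <- unlist(s[c("decrease_min", "decrease_q1", "decrease_median",
                   "decrease_q3", "decrease_max")])
  expect_true(all(diff(qs) >= 0) && all(qs >= 0))
  # single subdomain: min = median = max
  s1 <- summarize_by_condition(res[1, ])
  expect_equal(s1$decrease_min, s1$decrease_max)
  expect_equal(s1$decrease_min, s1$decrease_median)
})

test_that("run_study writes deterministic outputs and honors modes", {
  tb <- chain_fixture()
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- function(out) {
    study_config(tables = tb, age_ranges = list(c(3L, 6L)),
                 reps_effect = 60L, reps_null = 80L, seed = 4L,
                 out_dir = out)
  }
  st1 <- suppressMessages(run_study(cfg(dir1)))
  st2 <- suppressMessages(run_study(cfg(dir2)))
  expect_identical(st1$results, st2$results)
  f1 <- file.path(dir1, c("scenario_results.csv", "condition_summary.csv"))
  expect_true(all(file.exists(f1)))
  expect_identical(readLines(f1[1]),
                   readLines(file.path(dir2, "scenario_results.csv")))
  expect_identical(st1$results$n_reps,
                   rep(c(60L, 80L), each = 10L))

  # zero-effect-only study: type-I columns, no power columns
  st0 <- suppressMessages(run_study(
    study_config(tables = tb, age_ranges = list(c(3L, 6L)),
                 effects = "zero", reps_null = 80L, seed = 4L)))
  expect_true(all(c("typeI_gsv_median", "typeI_vscale_median") %in%
                    names(st0$summary)))
  expect_false(any(grepl("^power_", names(st0$summary))))
})

test_that("YAML configs map onto study settings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("design:", "  d: 0.8", "  rho: 0.8",
               "grid:", "  age_ranges:", "  - [3, 6]",
               "  impairments: [1, 5]",
               "reps:", "  effect: 50", "  null: 70",
               "seed: 12"), path)
  cfg <- read_study_config(path)
  expect_identical(cfg$reps_effect, 50L)
  expect_identical(cfg$reps_null, 70L)
  expect_identical(cfg$seed, 12L)
  expect_identical(cfg$impairments, c(1L, 5L))
  expect_identical(cfg$design$n_total, 24L)
})
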