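#' Trial design configuration
#'
#' Planning arithmetic for the simulated two-arm trial.  The planned total
#' sample size achieves the target power for a standardized mean
#' difference `d` in a plain two-sample comparison; because the analysis
#' adjusts for the baseline score (correlated `rho` with the endpoint),
#' the simulated sample size is reduced proportionally by `1 - rho^2` and
#' rounded up to an even total for balanced arms.  At the defaults this
#' gives 66 planned and 24 simulated participants.
#'
#' @param d standardized effect size used for planning (Cohen's d).
#' @param alpha two-sided significance level.
#' @param target_power power the planned sample size must achieve.
#' @param rho within-subject baseline/endpoint correlation.
#' @param followup_months months between baseline and endpoint.
#' @param n_total total simulated sample size; derived from the other
#'   parameters when `NULL`.
#' @return An object of class `design_config`.
#' @export
design_config <- function(d = 0.8, alpha = 0.05, target_power = 0.90,
                          rho = 0.8, followup_months = 6L, n_total = NULL) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(target_power > 0 && target_power < 1,
              "target_power must be in (0, 1)")
  assert_that(d > 0, "d must be > 0")
  assert_that(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  n_planned <- required_total_n(d, alpha, target_power)
  if (is.null(n_total)) n_total <- ancova_adjusted_n(n_planned, rho)
  assert_that(n_total %% 2L == 0L && n_total >= 6L,
              "n_total must be even and >= 6")
  structure(list(d = d, alpha = alpha, target_power = target_power,
                 rho = rho, followup_months = as.integer(followup_months),
                 n_planned = n_planned, n_total = as.integer(n_total)),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config> d=", x$d, ", alpha=", x$alpha,
      ", target power=", x$target_power, ", rho=", x$rho, "\n",
      "  planned N=", x$n_planned, " -> simulated N=", x$n_total,
      " (", x$n_total / 2, "/arm), follow-up ", x$followup_months,
      " months\n", sep = "")
  invisible(x)
}

#' One cell of the simulation design grid
#'
#' @param age_range two-element year range, `c(3, 6)` or `c(12, 16)`
#'   (inclusive of the upper year, so the month ranges are `[36, 84)` and
#'   `[144, 204)` with midpoints 60 and 174 months).
#' @param impairment_sd sample impairment in SD below the normative mean
#'   on the V-scale metric: 1-5, i.e. target V-scale 12, 9, 6, 3 or 1.
#' @param subdomain subdomain identifier.
#' @param effect `"large"` (0.8 SD endpoint shift) or `"zero"` (type-I
#'   error condition).
#' @return An object of class `scenario`.
#' @export
scenario <- function(age_range, impairment_sd, subdomain,
                     effect = c("large", "zero")) {
  effect <- match.arg(effect)
  assert_that(length(age_range) == 2 && age_range[1] < age_range[2],
              "age_range must be an increasing pair of years")
  assert_that(impairment_sd %in% 1:5, "impairment_sd must be in 1..5")
  months <- c(age_range[1] * 12L, (age_range[2] + 1L) * 12L)
  structure(list(age_range = as.integer(age_range),
                 months_range = as.integer(months),
                 midpoint_months = as.integer(mean(months)),
                 impairment_sd = as.integer(impairment_sd),
                 target_vscale = c(12L, 9L, 6L, 3L, 1L)[impairment_sd],
                 subdomain = subdomain, effect = effect),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$subdomain, ", ages ", x$age_range[1], "-",
      x$age_range[2], " y, impairment ", x$impairment_sd,
      " SD (V-scale ", x$target_vscale, "), effect=", x$effect, "\n",
      sep = "")
  invisible(x)
}

#' Score SD from its standard error of measurement
#'
#' `SD = SEM / sqrt(1 - r)`, where `r` is the score's reliability: the
#' classical-test-theory identity relating measurement error to the
#' population score SD.
#'
#' @param sem standard error of measurement (> 0).
#' @param reliability reliability coefficient in `[0, 1)`.
#' @return The implied score SD.
#' @export
sd_from_sem <- function(sem, reliability) {
  assert_that(all(sem > 0), "sem must be > 0")
  assert_that(all(reliability >= 0 & reliability < 1),
              "reliability must lie in [0, 1)")
  sem / sqrt(1 - reliability)
}

#' Variance of a mixture of distributions
#'
#' For components with weights `w`, means `mu` and variances `s2`,
#' `Var = sum(w * s2) + (sum(w * mu^2) - (sum(w * mu))^2)`: the weighted
#' average variance plus the dispersion of the component means.
#'
#' @param weights nonnegative weights summing to 1 (tolerance 1e-9).
#' @param means component means.
#' @param variances component variances.
#' @return The mixture variance.
#' @export
mixture_variance <- function(weights, means, variances) {
  assert_that(length(weights) == length(means) &&
                length(weights) == length(variances),
              "weights, means and variances must have equal length")
  assert_that(abs(sum(weights) - 1) <= 1e-9, "weights must sum to 1")
  assert_that(all(weights >= 0), "weights must be nonnegative")
  sum(weights * variances) +
    (sum(weights * means^2) - sum(weights * means)^2)
}

#' Proportional overlap weights of age bands over an age range
#'
#' @param months_range half-open `[min, max)` month range of the design
#'   factor.
#' @param bands data.frame with columns `age_min_months`,
#'   `age_max_months` (half-open bands).
#' @return The rows of `bands` that overlap the range, with columns
#'   `weight` (overlap months / range months; sums to 1) and
#'   `midpoint_months` added.  Errors if the bands leave part of the
#'   range uncovered.
#' @export
band_weights <- function(months_range, bands) {
  bands <- unique(bands[c("age_min_months", "age_max_months")])
  bands <- bands[order(bands$age_min_months), , drop = FALSE]
  ov <- pmin(bands$age_max_months, months_range[2]) -
    pmax(bands$age_min_months, months_range[1])
  keep <- ov > 0
  covered <- sum(ov[keep])
  assert_that(covered == diff(months_range),
              "age bands cover only %d of %d months of the range [%d, %d)",
              covered, diff(months_range), months_range[1], months_range[2])
  out <- bands[keep, , drop = FALSE]
  out$weight <- ov[keep] / covered
  out$midpoint_months <- (out$age_min_months + out$age_max_months) / 2
  rownames(out) <- NULL
  out
}

#' Generative mean GSV of a scenario
#'
#' The anchoring chain: at the evaluation age (by default the midpoint of
#' the scenario's month range, i.e. 5y0m or 14y6m), look up the raw-score
#' band of the target V-scale (12/9/6/3/1 for impairment 1-5), take its
#' mean raw score, and convert that raw score to a GSV.
#'
#' @param tables a `table_set`.
#' @param scenario a [scenario()].
#' @param age_months evaluation age; defaults to the scenario midpoint.
#' @return The mean GSV (numeric).  Propagates an
#'   `abilitysim_infeasible` condition when the target V-scale band is
#'   absent at this age.
#' @export
scenario_mean_gsv <- function(tables, scenario, age_months = NULL) {
  age <- age_months %||% scenario$midpoint_months
  vt <- vscale_table(tables, scenario$subdomain)
  gt <- gsv_table(tables, scenario$subdomain)
  raw <- mean_raw_for_vscale(vt, age, scenario$target_vscale)
  as.numeric(gsv_from_raw(gt, raw))
}

#' Generative GSV standard deviation of a scenario
#'
#' The design age range spans several normative age bands, each with its
#' own SEM-derived SD (`sd_from_sem`) and its own anchored mean
#' (`scenario_mean_gsv` at the band midpoint).  The scenario SD is the
#' square root of the variance of that mixture, with weights proportional
#' to each band's overlap with the age range.
#'
#' @inheritParams scenario_mean_gsv
#' @return The mixture SD (numeric).
#' @export
scenario_sigma <- function(tables, scenario) {
  st <- sem_table(tables, scenario$subdomain)
  bw <- band_weights(scenario$months_range, st)
  i <- match(paste(bw$age_min_months, bw$age_max_months),
             paste(st$age_min_months, st$age_max_months))
  assert_that(!anyNA(i), "missing SEM/reliability row for an age band")
  sds <- sd_from_sem(st$sem_gsv[i], st$reliability[i])
  mus <- vapply(bw$midpoint_months, function(a) {
    scenario_mean_gsv(tables, scenario, age_months = a)
  }, 0)
  sqrt(mixture_variance(bw$weight, mus, sds^2))
}

#' Treatment-arm endpoint mean shift
#'
#' `0.8 * sigma` under the large-effect condition, 0 under the zero-effect
#' (type-I error) condition.  The same mixture SD that generates the
#' scores is used, so the standardized effect is exactly `d`.
#'
#' @param sigma generative GSV SD.
#' @param condition `"large"` or `"zero"`.
#' @param d standardized effect size under the large condition.
#' @return The shift in GSV units.
#' @export
treatment_delta <- function(sigma, condition = c("large", "zero"), d = 0.8) {
  condition <- match.arg(condition)
  assert_that(sigma > 0, "sigma must be > 0")
  if (condition == "large") d * sigma else 0
}

#' Planned total sample size for a two-sample comparison
#'
#' Normal-approximation formula
#' `N = 4 * (z_{1-alpha/2} + z_{power})^2 / d^2`, rounded up to an even
#' total.  At `d = 0.8`, `alpha = 0.05`, `power = 0.90` this gives 66.
#'
#' @param d standardized mean difference.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return Even integer total sample size.
#' @export
required_total_n <- function(d, alpha = 0.05, power = 0.90) {
  assert_that(d > 0, "d must be > 0")
  assert_that(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  even_ceiling(4 * z^2 / d^2)
}

#' Covariate-adjusted simulated sample size
#'
#' Adjusting for a baseline covariate correlated `rho` with the endpoint
#' reduces the required sample size proportionally by `1 - rho^2`; the
#' result is rounded up to an even total for balanced arms.  At
#' `n_total = 66`, `rho = 0.8` this gives 24.
#'
#' @param n_total unadjusted total sample size.
#' @param rho baseline/endpoint correlation.
#' @return Even integer total sample size.
#' @export
ancova_adjusted_n <- function(n_total, rho) {
  assert_that(n_total > 0, "n_total must be > 0")
  assert_that(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  even_ceiling(n_total * (1 - rho^2))
}

#' Generative parameters of one scenario
#'
#' Bundles the anchored mean, mixture SD, within-subject correlation and
#' treatment shift that drive the bivariate-normal score generator.
#'
#' @inheritParams scenario_mean_gsv
#' @param design a [design_config()].
#' @return An object of class `generative_params` with elements `mu`
#'   (shared baseline and placebo-endpoint mean), `sigma`, `rho`, `delta`.
#' @export
scenario_params <- function(tables, scenario, design = design_config()) {
  mu <- scenario_mean_gsv(tables, scenario)
  sigma <- scenario_sigma(tables, scenario)
  structure(list(mu = mu, sigma = sigma, rho = design$rho,
                 delta = treatment_delta(sigma, scenario$effect, design$d)),
            class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf("<generative_params> mu=%.2f sigma=%.2f rho=%.2f delta=%.2f\n",
              x$mu, x$sigma, x$rho, x$delta))
  invisible(x)
}
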