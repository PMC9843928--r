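#' Draw correlated baseline/endpoint score pairs
#'
#' i.i.d. draws from a bivariate normal with means `(mu_b, mu_e)`, common
#' SD `sigma` and correlation `rho`, via the Cholesky construction
#' `Y = mu_e + sigma * (rho * Z1 + sqrt(1 - rho^2) * Z2)`.
#'
#' @param mu_b,mu_e baseline and endpoint means.
#' @param sigma common SD (> 0).
#' @param rho correlation, `|rho| < 1`.
#' @param n number of pairs.
#' @return `n x 2` matrix with columns `baseline`, `endpoint`.
#' @export
draw_correlated_pairs <- function(mu_b, mu_e, sigma, rho, n) {
  assert_that(sigma > 0, "sigma must be > 0")
  assert_that(abs(rho) < 1, "rho must satisfy |rho| < 1")
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(baseline = mu_b + sigma * z1,
        endpoint = mu_e + sigma * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Draw participant ages
#'
#' Baseline ages are drawn with uniform probability and replacement from
#' the integer months of the half-open design range; endpoint age adds a
#' constant follow-up.
#'
#' @param months_range half-open `[min, max)` month range.
#' @param n number of participants.
#' @param followup follow-up interval in months.
#' @return `n x 2` integer matrix with columns `baseline`, `endpoint`.
#' @export
draw_ages <- function(months_range, n, followup = 6L) {
  assert_that(months_range[1] < months_range[2],
              "months_range must be non-empty")
  b <- months_range[1] - 1L +
    sample.int(months_range[2] - months_range[1], n, replace = TRUE)
  cbind(baseline = b, endpoint = b + as.integer(followup))
}

# Round continuous GSV draws to the nearest tabulated GSV (ties upward),
# clipping at the table extremes.  `gvals` must be sorted unique values.
round_to_tabulated <- function(x, gvals) {
  K <- length(gvals)
  idx <- findInterval(x, gvals)
  idx[idx == 0L] <- 1L
  up <- idx < K & (gvals[pmin(idx + 1L, K)] - x) <= (x - gvals[idx])
  idx + as.integer(up)
}

# Precomputed per-subdomain lookup structures for the hot conversion path.
subdomain_lookup <- function(tables, subdomain) {
  gt <- gsv_table(tables, subdomain)
  med <- median_raw_by_gsv(gt)
  vt <- vscale_table(tables, subdomain)
  bands <- unique(vt[c("age_min_months", "age_max_months")])
  bands <- bands[order(bands$age_min_months), , drop = FALSE]
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    r <- vt[vt$age_min_months == bands$age_min_months[b], , drop = FALSE]
    r[order(r$raw_min), , drop = FALSE]
  })
  list(subdomain = subdomain,
       gvals = med$gsv, rawmed = med$raw,
       gsv_min = min(gt$gsv), gsv_max = max(gt$gsv),
       band_lo = bands$age_min_months, band_hi = bands$age_max_months,
       band_rows = rows)
}

# Vectorized GSV -> (tabulated GSV, raw, V-scale) over the lookup built by
# subdomain_lookup().
convert_gsv <- function(lookup, gsv, age_months) {
  idx <- round_to_tabulated(gsv, lookup$gvals)
  raw <- lookup$rawmed[idx]
  bi <- findInterval(age_months, lookup$band_lo)
  ok <- bi >= 1L & age_months < lookup$band_hi[pmax(bi, 1L)]
  assert_that(all(ok), "age(s) outside the supported range: %s",
              paste(utils::head(unique(age_months[!ok])), collapse = ", "))
  v <- integer(length(gsv))
  for (b in unique(bi)) {
    rows <- lookup$band_rows[[b]]
    sel <- bi == b
    v[sel] <- rows$vscale[findInterval(raw[sel], rows$raw_min)]
  }
  list(gsv_tab = lookup$gvals[idx], raw = raw, vscale = v)
}

#' Convert continuous GSV draws to V-scale scores
#'
#' The score-conversion chain applied to simulated data: the continuous
#' GSV is rounded to the nearest tabulated GSV (ties upward) and clipped
#' into the table range; the tabulated GSV is inverted to a raw score by
#' the median rule ([raw_from_gsv()]); the raw score is converted to a
#' V-scale score in the normative age band containing `age_months`.
#'
#' @param tables a `table_set`.
#' @param subdomain subdomain identifier.
#' @param gsv continuous GSV value(s).
#' @param age_months integer age(s) in months (recycled if scalar).
#' @return data.frame with columns `vscale` and `at_floor`
#'   (`vscale == 1`).
#' @export
gsv_to_vscale <- function(tables, subdomain, gsv, age_months) {
  lk <- subdomain_lookup(tables, subdomain)
  n <- max(length(gsv), length(age_months))
  res <- convert_gsv(lk, rep_len(gsv, n), rep_len(age_months, n))
  data.frame(vscale = res$vscale, at_floor = res$vscale == 1L)
}

#' Simulate one parallel-arm trial dataset
#'
#' Balanced allocation (`n_total/2` per arm).  Placebo baseline/endpoint
#' GSV pairs are drawn from `(mu, mu)`, treatment pairs from
#' `(mu, mu + delta)`, both with SD `sigma` and correlation `rho`;
#' baseline ages are uniform on the scenario's month range with endpoint
#' ages a fixed follow-up later; V-scale scores are derived from each
#' record's own age at the relevant timepoint.
#'
#' @param params a [scenario_params()] (or any list with `mu`, `sigma`,
#'   `rho`, `delta`).
#' @param design a [design_config()].
#' @param scenario a [scenario()].
#' @param tables a `table_set`.
#' @param seed optional integer; when given the dataset is a pure
#'   function of `(params, design, scenario, seed)` and the caller's RNG
#'   stream is left untouched.
#' @return A data.frame of class `trial_dataset` with columns `arm`
#'   (`"PBO"`/`"TRT"`), `age_baseline_months`, `age_endpoint_months`,
#'   `gsv_baseline`, `gsv_endpoint` (continuous draws),
#'   `gsv_tab_baseline`, `gsv_tab_endpoint` (table-rounded values),
#'   `vscale_baseline`, `vscale_endpoint`.  Attributes record the
#'   subdomain and the tabulated GSV range (used by
#'   [classify_floor()]).
#' @export
simulate_trial <- function(params, design, scenario, tables, seed = NULL) {
  gen <- function() {
    n_arm <- design$n_total %/% 2L
    pbo <- draw_correlated_pairs(params$mu, params$mu,
                                 params$sigma, params$rho, n_arm)
    trt <- draw_correlated_pairs(params$mu, params$mu + params$delta,
                                 params$sigma, params$rho, n_arm)
    ages <- draw_ages(scenario$months_range, design$n_total,
                      design$followup_months)
    list(gb = c(pbo[, 1], trt[, 1]), ge = c(pbo[, 2], trt[, 2]),
         ab = ages[, 1], ae = ages[, 2], n_arm = n_arm)
  }
  d <- if (is.null(seed)) gen() else with_seed(seed, gen())

  lk <- subdomain_lookup(tables, scenario$subdomain)
  cb <- convert_gsv(lk, d$gb, d$ab)
  ce <- convert_gsv(lk, d$ge, d$ae)

  out <- data.frame(
    arm = rep(c("PBO", "TRT"), each = d$n_arm),
    age_baseline_months = d$ab, age_endpoint_months = d$ae,
    gsv_baseline = d$gb, gsv_endpoint = d$ge,
    gsv_tab_baseline = cb$gsv_tab, gsv_tab_endpoint = ce$gsv_tab,
    vscale_baseline = cb$vscale, vscale_endpoint = ce$vscale,
    stringsAsFactors = FALSE)
  structure(out, subdomain = scenario$subdomain,
            gsv_min = lk$gsv_min, gsv_max = lk$gsv_max,
            class = c("trial_dataset", "data.frame"))
}
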