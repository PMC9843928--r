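#' Configuration for the synthetic table generator
#'
#' The generator emulates the structure of a published adaptive-behavior
#' test's scoring appendices without reproducing any copyrighted value:
#' 11 subdomains, monotone raw -> GSV maps starting at 10 with subdomain
#' maxima in 110-197, age-banded raw -> V-scale bands on a mean-15/SD-3
#' scale floored at 1, and per-age-band GSV SEMs (about 2-9) with
#' internal-consistency reliabilities (about 0.69-0.97).
#'
#' Development of the median raw score with age follows a saturating
#' logistic per subdomain.  Subdomains differ in when they saturate:
#' expressive/receptive-communication-like subdomains saturate in early
#' childhood (so adolescent samples far below age expectations sit deep in
#' the V-scale floor band), while a written-communication-like subdomain
#' saturates late.
#'
#' @param n_subdomains number of subdomains (default 11).
#' @param subdomain_names identifiers; defaults to 11 adaptive-behavior
#'   subdomain names.
#' @param max_raw_range integer range the per-subdomain maximum raw score
#'   is drawn from.
#' @param age_support supported age range in months (half-open).
#' @param band_width width of each normative age band, months.
#' @param growth_midpoint per-subdomain age (months) at which the median
#'   raw score reaches half its maximum.
#' @param growth_rate per-subdomain logistic time-scale (months); smaller
#'   is steeper.
#' @param asymptote typical fully developed performance as a fraction of
#'   the maximum raw score: real scales keep difficult items above the
#'   typical adult level, so the normative median saturates below
#'   `max_raw` and above-average scores remain expressible at all ages.
#' @param within_age_raw_sd SD of the raw-score distribution at a fixed
#'   age, expressed as a fraction of the subdomain's maximum raw score at
#'   full development; the effective SD scales with developmental level
#'   as `0.45 + 0.55 * m(age)/max_raw`, since raw-score variability is
#'   compressed near the bottom of a scale.  The default keeps the
#'   normative growth over one year at roughly one within-age SD, so a
#'   one-year developmental lag costs about 2-3 V-scale points, as in
#'   real norm tables.
#' @param tail_widening widening of the raw bands toward the V-scale
#'   floor: the effective SD grows by this factor per SD of depth below
#'   the normative mean, mimicking the widening of raw bands at extreme
#'   low scores in inferentially normed tables (0 = none).
#' @param gsv_max_range integer range the per-subdomain maximum GSV is
#'   drawn from.
#' @param sem_range admissible range for the per-age-band GSV SEM.
#' @param reliability_range range the per-age-band reliability is drawn
#'   from.  The SEM is then derived from the reliability and the
#'   within-age GSV SD the tables themselves imply
#'   (`SEM = SD * sqrt(1 - r)`), clamped into `sem_range`: SEM,
#'   reliability and band geometry describe one population, as they do in
#'   a real instrument.
#' @param seed integer seed; generation is deterministic given the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subdomains = 11L,
                         subdomain_names = NULL,
                         max_raw_range = c(80L, 180L),
                         age_support = c(24L, 216L),
                         band_width = 12L,
                         growth_midpoint = NULL,
                         growth_rate = NULL,
                         asymptote = 0.85,
                         within_age_raw_sd = 0.09,
                         tail_widening = 0.25,
                         gsv_max_range = c(110L, 197L),
                         sem_range = c(2, 9),
                         reliability_range = c(0.69, 0.97),
                         seed = 20230117L) {
  default_names <- c("Receptive", "Expressive", "Written", "Personal",
                     "Domestic", "Community", "Interpersonal",
                     "PlayLeisure", "Coping", "GrossMotor", "FineMotor")
  default_mid <- c(18, 26, 160, 120, 130, 140, 110, 95, 120, 12, 30)
  default_rate <- c(36, 38, 45, 55, 55, 55, 50, 48, 50, 30, 36)

  assert_that(n_subdomains >= 1, "n_subdomains must be >= 1")
  if (is.null(subdomain_names)) {
    subdomain_names <- if (n_subdomains <= 11L) default_names[seq_len(n_subdomains)]
    else c(default_names, paste0("Sub", seq_len(n_subdomains - 11L)))
  }
  assert_that(length(subdomain_names) == n_subdomains,
              "need %d subdomain names", n_subdomains)
  if (is.null(growth_midpoint)) {
    growth_midpoint <- rep_len(default_mid, n_subdomains)
  }
  if (is.null(growth_rate)) {
    growth_rate <- rep_len(default_rate, n_subdomains)
  }
  assert_that(length(growth_midpoint) == n_subdomains &&
                length(growth_rate) == n_subdomains,
              "growth_midpoint/growth_rate must have one entry per subdomain")
  assert_that(diff(range(max_raw_range)) >= 0 && min(max_raw_range) > 0,
              "max_raw_range must be a positive non-empty range")
  assert_that(age_support[1] < age_support[2], "age_support must be non-empty")
  assert_that((age_support[2] - age_support[1]) %% band_width == 0,
              "band_width must divide the age support evenly")
  assert_that(min(gsv_max_range) >= 110 && max(gsv_max_range) <= 197,
              "gsv_max_range must lie within [110, 197]")
  assert_that(asymptote > 0 && asymptote <= 1,
              "asymptote must be in (0, 1]")
  assert_that(within_age_raw_sd > 0 && within_age_raw_sd < 0.5,
              "within_age_raw_sd must be in (0, 0.5)")
  assert_that(sem_range[1] > 0 && sem_range[1] <= sem_range[2],
              "invalid sem_range")
  assert_that(reliability_range[1] > 0 && reliability_range[2] < 1 &&
                reliability_range[1] <= reliability_range[2],
              "reliability_range must lie within (0, 1)")

  structure(list(n_subdomains = as.integer(n_subdomains),
                 subdomain_names = subdomain_names,
                 max_raw_range = as.integer(max_raw_range),
                 age_support = as.integer(age_support),
                 band_width = as.integer(band_width),
                 growth_midpoint = growth_midpoint,
                 growth_rate = growth_rate,
                 asymptote = asymptote,
                 within_age_raw_sd = within_age_raw_sd,
                 tail_widening = tail_widening,
                 gsv_max_range = as.integer(gsv_max_range),
                 sem_range = sem_range,
                 reliability_range = reliability_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Median raw score at age `a` (months) for one subdomain.
logistic_median_raw <- function(a, max_raw, midpoint, rate) {
  max_raw * stats::plogis((a - midpoint) / rate)
}

# Signed z-position -> raw-score offset in SD units, widened below the mean.
widened_z <- function(z, tail_widening) {
  ifelse(z >= 0, z, z * (1 + tail_widening * (-z) / 3))
}

#' Generate a synthetic score-conversion table set
#'
#' Builds a complete [table_set()] from a [synth_config()].  Per subdomain:
#' the raw -> GSV map is a random monotone step map from 10 up to the drawn
#' subdomain maximum, with typical increments of 0-3 GSV units per raw
#' score (plateaus included, so the median-raw inversion rule is
#' exercised); per age band, V-scale raw bands are cut at normal quantiles
#' of the age-specific raw-score distribution mapped onto the discrete
#' 1-24 scale (mean 15, SD 3), with band edges forced to partition
#' `[0, max_raw]`; SEM and reliability are drawn uniformly within the
#' configured ranges for each age band.
#'
#' Generation is bit-reproducible given the config (including its seed)
#' and leaves the caller's RNG stream untouched.
#'
#' @param config a [synth_config()].
#' @return A validated `table_set` with provenance `"synthetic"`.
#' @export
generate_table_set <- function(config = synth_config()) {
  assert_that(inherits(config, "synth_config"), "`config` must be a synth_config")
  with_seed(config$seed, {
    gsv_rows <- list(); vsc_rows <- list(); sem_rows <- list()
    band_lo <- seq(config$age_support[1], config$age_support[2] - 1L,
                   by = config$band_width)
    band_hi <- band_lo + config$band_width

    for (i in seq_len(config$n_subdomains)) {
      sub <- config$subdomain_names[i]
      max_raw <- sample(config$max_raw_range[1]:config$max_raw_range[2], 1L)
      gsv_max <- sample(config$gsv_max_range[1]:config$gsv_max_range[2], 1L)

      # monotone quantile-anchored raw -> GSV map
      wgt <- stats::runif(max_raw, 0.3, 1.7)
      cum <- cumsum(wgt) / sum(wgt) * (gsv_max - 10L)
      gsv <- c(10L, 10L + as.integer(round_half_up(cum)))
      gsv_rows[[i]] <- data.frame(subdomain = sub, raw = 0:max_raw,
                                  gsv = gsv, stringsAsFactors = FALSE)

      s_full <- config$within_age_raw_sd * max_raw
      z_cuts <- (1:23 + 0.5 - 15) / 3   # upper edge of bands v = 1..23
      band_mid <- (band_lo + band_hi) / 2
      m_band <- config$asymptote *
        logistic_median_raw(band_mid, max_raw, config$growth_midpoint[i],
                            config$growth_rate[i])
      s_band <- s_full * (0.45 + 0.55 * m_band / max_raw)
      vb <- lapply(seq_along(band_lo), function(b) {
        m <- m_band[b]
        s_raw <- s_band[b]
        cuts <- round_half_up(m + s_raw * widened_z(z_cuts, config$tail_widening))
        cuts <- pmin(pmax(cummax(cuts), 0L), max_raw)
        lo <- c(0L, cuts + 1L)
        hi <- c(cuts, max_raw)
        keep <- lo <= hi
        data.frame(subdomain = sub, age_min_months = band_lo[b],
                   age_max_months = band_hi[b], vscale = (1:24)[keep],
                   raw_min = as.integer(lo[keep]),
                   raw_max = as.integer(hi[keep]), stringsAsFactors = FALSE)
      })
      vsc_rows[[i]] <- do.call(rbind, vb)

      rel <- stats::runif(length(band_lo), config$reliability_range[1],
                          config$reliability_range[2])
      slope <- (gsv_max - 10) / max_raw        # mean GSV units per raw score
      sem <- pmin(pmax(s_band * slope * sqrt(1 - rel), config$sem_range[1]),
                  config$sem_range[2])
      # 6 decimals so the CSV round trip is bit-exact
      sem_rows[[i]] <- data.frame(
        subdomain = sub, age_min_months = band_lo, age_max_months = band_hi,
        sem_gsv = round(sem, 6), reliability = round(rel, 6),
        stringsAsFactors = FALSE)
    }

    table_set(do.call(rbind, gsv_rows), do.call(rbind, vsc_rows),
              do.call(rbind, sem_rows), provenance = "synthetic")
  })
}
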