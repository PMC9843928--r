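#' Build the feasible scenario grid
#'
#' Crosses the age ranges, impairment levels and subdomains, anchors each
#' cell's generative parameters, and logs cells whose target V-scale band
#' is absent at the anchoring age as infeasible (they are skipped, not
#' errors: a band can genuinely be unreachable at an age).
#'
#' @param tables a `table_set`.
#' @param design a [design_config()].
#' @param age_ranges list of year ranges (default the 3-6 and 12-16 year
#'   conditions).
#' @param impairments impairment levels in SD below the normative mean.
#' @param subdomains subdomain identifiers; defaults to all in `tables`.
#' @return An object of class `scenario_grid`: `$scenarios` (data.frame
#'   with the anchored `mu` and `sigma` per feasible cell),
#'   `$scenario_list` (the [scenario()] objects) and `$skipped`
#'   (data.frame of infeasible cells with reasons).
#' @export
build_scenario_grid <- function(tables, design = design_config(),
                                age_ranges = list(c(3L, 6L), c(12L, 16L)),
                                impairments = 1:5, subdomains = NULL) {
  subs <- subdomains %||% abilitysim::subdomains(tables)
  rows <- list(); skip <- list(); scen <- list()
  for (ar in age_ranges) for (imp in impairments) for (sb in subs) {
    sc <- scenario(ar, imp, sb, effect = "large")
    p <- tryCatch(scenario_params(tables, sc, design),
                  abilitysim_infeasible = function(e) e)
    if (is_infeasible_error(p)) {
      skip[[length(skip) + 1L]] <- data.frame(
        age_min = ar[1], age_max = ar[2], impairment_sd = imp,
        subdomain = sb, reason = conditionMessage(p),
        stringsAsFactors = FALSE)
    } else {
      i <- length(scen) + 1L
      scen[[i]] <- sc
      rows[[i]] <- data.frame(
        index = i, age_min = ar[1], age_max = ar[2], impairment_sd = imp,
        subdomain = sb, mu = p$mu, sigma = p$sigma,
        stringsAsFactors = FALSE)
    }
  }
  empty_skip <- data.frame(age_min = integer(), age_max = integer(),
                           impairment_sd = integer(),
                           subdomain = character(), reason = character(),
                           stringsAsFactors = FALSE)
  structure(list(
    scenarios = if (length(rows)) do.call(rbind, rows) else NULL,
    scenario_list = scen,
    skipped = if (length(skip)) do.call(rbind, skip) else empty_skip),
    class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid> ", nrow(x$scenarios), " feasible scenarios, ",
      nrow(x$skipped), " skipped\n", sep = "")
  invisible(x)
}

#' Run all replications of one scenario
#'
#' Simulates `n_reps` trials (vectorized), analyzes every replication by
#' ANCOVA on both endpoint scales, applies the rejection rule
#' ([decide_rejection()]: degenerate fits and complete-floor replications
#' are failures to reject), and summarizes.
#'
#' @param scenario a [scenario()]; its `effect` condition can be
#'   overridden with `effect`.
#' @param tables a `table_set`.
#' @param design a [design_config()].
#' @param n_reps number of replications.
#' @param seed integer seed for this scenario's stream.
#' @param effect optional `"large"` or `"zero"` override.
#' @param gsv_values `"continuous"` or `"tabulated"` GSV analysis values.
#' @return A one-row data.frame (class `scenario_result`): rejection
#'   rates per scale (`power_gsv`, `power_vscale`; type-I rates under the
#'   zero-effect condition), complete-floor and degenerate-fit rates, and
#'   the median raw between-group endpoint difference per scale.
#' @export
run_scenario <- function(scenario, tables, design, n_reps, seed,
                         effect = NULL,
                         gsv_values = c("continuous", "tabulated")) {
  gsv_values <- match.arg(gsv_values)
  if (!is.null(effect)) scenario$effect <- match.arg(effect, c("large", "zero"))
  params <- scenario_params(tables, scenario, design)
  n <- design$n_total; n_arm <- n %/% 2L; R <- as.integer(n_reps)
  lk <- subdomain_lookup(tables, scenario$subdomain)
  rng <- with_seed(seed, {
    list(Z1p = matrix(stats::rnorm(n_arm * R), n_arm),
         Z2p = matrix(stats::rnorm(n_arm * R), n_arm),
         Z1t = matrix(stats::rnorm(n_arm * R), n_arm),
         Z2t = matrix(stats::rnorm(n_arm * R), n_arm),
         ages = matrix(scenario$months_range[1] - 1L +
                         sample.int(scenario$months_range[2] -
                                      scenario$months_range[1],
                                    n * R, replace = TRUE), n))
  })
  s <- params$sigma; rho <- params$rho; q <- sqrt(1 - rho^2)
  B <- rbind(params$mu + s * rng$Z1p,
             params$mu + s * rng$Z1t)
  Y <- rbind(params$mu + s * (rho * rng$Z1p + q * rng$Z2p),
             params$mu + params$delta + s * (rho * rng$Z1t + q * rng$Z2t))
  arm <- rep(0:1, each = n_arm)
  ages_b <- rng$ages
  ages_e <- ages_b + design$followup_months

  cb <- convert_gsv(lk, as.vector(B), as.vector(ages_b))
  ce <- convert_gsv(lk, as.vector(Y), as.vector(ages_e))
  dim_n <- c(n, R)
  Vb <- matrix(cb$vscale, n, R); Ve <- matrix(ce$vscale, n, R)
  Tb <- matrix(cb$gsv_tab, n, R); Te <- matrix(ce$gsv_tab, n, R)

  arm_floor_rates <- function(lo) {
    pbo <- colSums(lo[seq_len(n_arm), , drop = FALSE]) == n_arm
    trt <- colSums(lo[n_arm + seq_len(n_arm), , drop = FALSE]) == n_arm
    list(any = pbo | trt, pbo = pbo, trt = trt)
  }
  fl_v <- arm_floor_rates(Vb == 1L & Ve == 1L)
  fl_g <- arm_floor_rates(Tb == lk$gsv_min & Te == lk$gsv_min)

  if (gsv_values == "continuous") {
    res_g <- batch_ancova(B, Y, arm)
  } else {
    res_g <- batch_ancova(Tb, Te, arm)
  }
  res_v <- batch_ancova(Vb, Ve, arm)

  rejected <- function(res, fl) {
    !res$degenerate & !fl$any & !is.na(res$p) & res$p < design$alpha
  }
  diff_by_arm <- function(E) {
    colMeans(E[n_arm + seq_len(n_arm), , drop = FALSE]) -
      colMeans(E[seq_len(n_arm), , drop = FALSE])
  }

  out <- data.frame(
    subdomain = scenario$subdomain,
    age_min = scenario$age_range[1], age_max = scenario$age_range[2],
    impairment_sd = scenario$impairment_sd, effect = scenario$effect,
    n_reps = R,
    power_gsv = mean(rejected(res_g, fl_g)),
    power_vscale = mean(rejected(res_v, fl_v)),
    floor_rate_gsv = mean(fl_g$any),
    floor_rate_vscale = mean(fl_v$any),
    degenerate_rate_gsv = mean(res_g$degenerate),
    degenerate_rate_vscale = mean(res_v$degenerate),
    median_diff_gsv = stats::median(diff_by_arm(Y)),
    median_diff_vscale = stats::median(diff_by_arm(Ve)),
    seed = seed,
    stringsAsFactors = FALSE)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Study configuration
#'
#' Assembles tables, design, grid and replication settings for
#' [run_study()].  `reps_effect`/`reps_null` default to the study's 5,000
#' large-effect and 10,000 null replications; lower them for smoke runs.
#'
#' @param tables a `table_set`, or `NULL` to generate synthetic tables
#'   from `synth` (seeded independently of `seed` so the table structure
#'   is a fixed study input).
#' @param synth a [synth_config()] used when `tables` is `NULL`.
#' @param design a [design_config()].
#' @param age_ranges,impairments,subdomains grid factors
#'   (see [build_scenario_grid()]).
#' @param effects which effect conditions to run.
#' @param reps_effect,reps_null replications per scenario for the
#'   large-effect and zero-effect conditions.
#' @param gsv_values `"continuous"` or `"tabulated"` GSV analysis values.
#' @param seed root seed; every scenario stream is derived from it.
#' @param out_dir optional directory for `scenario_results.csv` and
#'   `condition_summary.csv`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(tables = NULL, synth = synth_config(),
                         design = design_config(),
                         age_ranges = list(c(3L, 6L), c(12L, 16L)),
                         impairments = 1:5, subdomains = NULL,
                         effects = c("large", "zero"),
                         reps_effect = 5000L, reps_null = 10000L,
                         gsv_values = "continuous",
                         seed = 1L, out_dir = NULL) {
  effects <- match.arg(effects, several.ok = TRUE)
  structure(list(tables = tables, synth = synth, design = design,
                 age_ranges = age_ranges, impairments = impairments,
                 subdomains = subdomains, effects = effects,
                 reps_effect = as.integer(reps_effect),
                 reps_null = as.integer(reps_null),
                 gsv_values = gsv_values,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognized keys: `tables: {mode: synthetic|files, paths: [gsv, vscale,
#' sem]}`, `design: {d, alpha, power, rho, followup_months}`,
#' `grid: {age_ranges, impairments, subdomains}`,
#' `reps: {effect, null}`, `gsv_values`, `seed`, `out_dir`.
#' Missing keys fall back to the [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  assert_that(requireNamespace("yaml", quietly = TRUE),
              "the 'yaml' package is required to read config files")
  cfg <- withCallingHandlers(
    yaml::read_yaml(path),
    warning = function(w) {
      # a bare `null:` key parses to an empty name; handled below
      if (grepl("Empty character vector", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tables <- NULL
  if (!is.null(cfg$tables) && identical(cfg$tables$mode, "files")) {
    p <- cfg$tables$paths
    tables <- load_table_set(p[[1]], p[[2]], p[[3]])
  }
  dz <- cfg$design %||% list()
  design <- design_config(d = dz$d %||% 0.8, alpha = dz$alpha %||% 0.05,
                          target_power = dz$power %||% 0.90,
                          rho = dz$rho %||% 0.8,
                          followup_months = dz$followup_months %||% 6L)
  gr <- cfg$grid %||% list()
  age_ranges <- if (is.null(gr$age_ranges)) list(c(3L, 6L), c(12L, 16L))
  else lapply(gr$age_ranges, as.integer)
  reps <- cfg$reps %||% list()
  # YAML readers parse a bare `null:` key to an empty name
  if (any(names(reps) == "")) names(reps)[names(reps) == ""] <- "null"
  study_config(tables = tables, design = design, age_ranges = age_ranges,
               impairments = gr$impairments %||% 1:5,
               subdomains = gr$subdomains,
               effects = cfg$effects %||% c("large", "zero"),
               reps_effect = reps$effect %||% 5000L,
               reps_null = reps[["null"]] %||% reps$zero %||% 10000L,
               gsv_values = cfg$gsv_values %||% "continuous",
               seed = cfg$seed %||% 1L, out_dir = cfg$out_dir)
}

#' Run the full simulation study
#'
#' Builds (or accepts) the table set, constructs the feasible scenario
#' grid, runs every scenario under the requested effect conditions, and
#' summarizes by condition.  Deterministic given the configuration:
#' scenario streams are derived from the root seed by scenario index and
#' condition, so results do not depend on execution order.
#'
#' @param config a [study_config()] or a YAML path accepted by
#'   [read_study_config()].
#' @return An object of class `ability_study`: `$results` (one row per
#'   scenario x effect condition), `$summary` (condition-level summary,
#'   see [summarize_by_condition()]), `$skipped`, `$tables`, `$config`.
#'   When `config$out_dir` is set, writes `scenario_results.csv` and
#'   `condition_summary.csv` there (power rounded to 2 decimals in the
#'   summary file).
#' @export
run_study <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  assert_that(inherits(config, "study_config"),
              "`config` must be a study_config (or a YAML path)")
  tables <- config$tables %||% generate_table_set(config$synth)
  grid <- build_scenario_grid(tables, config$design,
                              age_ranges = config$age_ranges,
                              impairments = config$impairments,
                              subdomains = config$subdomains)
  if (nrow(grid$skipped) > 0) {
    message("skipping ", nrow(grid$skipped), " infeasible scenario(s):")
    for (i in seq_len(nrow(grid$skipped))) {
      message("  - ", grid$skipped$reason[i])
    }
  }
  res <- list()
  for (eff in config$effects) {
    flag <- if (eff == "large") 0L else 1L
    reps <- if (eff == "large") config$reps_effect else config$reps_null
    for (i in seq_along(grid$scenario_list)) {
      res[[length(res) + 1L]] <- run_scenario(
        grid$scenario_list[[i]], tables, config$design, reps,
        seed = derive_seed(config$seed, i, flag), effect = eff,
        gsv_values = config$gsv_values)
    }
  }
  results <- do.call(rbind, res)
  summary <- summarize_by_condition(results)
  out <- structure(list(results = results, summary = summary,
                        skipped = grid$skipped, tables = tables,
                        config = config),
                   class = "ability_study")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results,
                     file.path(config$out_dir, "scenario_results.csv"),
                     row.names = FALSE)
    rounded <- summary
    num <- vapply(rounded, is.numeric, TRUE) &
      !(names(rounded) %in% c("age_min", "age_max", "impairment_sd",
                              "n_subdomains"))
    rounded[num] <- lapply(rounded[num], round, digits = 2)
    utils::write.csv(rounded,
                     file.path(config$out_dir, "condition_summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.ability_study <- function(x, ...) {
  cat("<ability_study> ", nrow(x$results), " scenario runs (",
      length(unique(x$results$subdomain)), " subdomains; effects: ",
      paste(unique(x$results$effect), collapse = ", "), ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
summary.ability_study <- function(object, ...) object$summary

#' Condition-level summary of scenario results
#'
#' For each age-range x impairment condition: under the large-effect
#' condition, the median power across subdomains per scale and the
#' five-number summary (min, Q1, median, Q3, max; quartiles by the
#' default type-7 rule) of the per-subdomain power decrease
#' `power_gsv - power_vscale`; under the zero-effect condition, the
#' median type-I error rate across subdomains per scale.
#'
#' @param results the `$results` data.frame of an `ability_study` (one
#'   row per scenario x effect condition).
#' @return data.frame with one row per condition x effect present.
#' @export
summarize_by_condition <- function(results) {
  pieces <- list()
  key <- interaction(results$age_min, results$age_max,
                     results$impairment_sd, results$effect, drop = TRUE)
  for (k in levels(key)) {
    d <- results[key == k, , drop = FALSE]
    base <- data.frame(age_min = d$age_min[1], age_max = d$age_max[1],
                       impairment_sd = d$impairment_sd[1],
                       effect = d$effect[1], n_subdomains = nrow(d),
                       stringsAsFactors = FALSE)
    if (d$effect[1] == "large") {
      dec <- d$power_gsv - d$power_vscale
      q <- stats::quantile(dec, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      base$power_gsv_median <- stats::median(d$power_gsv)
      base$power_vscale_median <- stats::median(d$power_vscale)
      base$decrease_min <- q[1]; base$decrease_q1 <- q[2]
      base$decrease_median <- q[3]; base$decrease_q3 <- q[4]
      base$decrease_max <- q[5]
    } else {
      base$typeI_gsv_median <- stats::median(d$power_gsv)
      base$typeI_vscale_median <- stats::median(d$power_vscale)
    }
    pieces[[k]] <- base
  }
  # bind rows with differing columns (large vs zero) via a union of names
  nms <- unique(unlist(lapply(pieces, names)))
  pieces <- lapply(pieces, function(p) {
    p[setdiff(nms, names(p))] <- NA
    p[nms]
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$effect, out$age_min, out$impairment_sd), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
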