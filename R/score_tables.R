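#' Score-conversion table sets
#'
#' A `table_set` bundles the three lookup structures the trial simulator
#' consumes, for every subdomain of the test:
#'
#' * a raw -> GSV table (`gsv`): one row per raw score, giving the
#'   Rasch-derived growth scale value (ability score);
#' * an age-banded raw -> V-scale table (`vscale`): for each normative age
#'   band, contiguous raw-score bands mapping onto the discrete
#'   norm-referenced V-scale (population mean 15, SD 3, minimum 1);
#' * a SEM/reliability table (`sem`): per age band, the GSV standard error
#'   of measurement and the internal-consistency reliability.
#'
#' The publisher's tables are copyrighted and not shipped; use
#' [load_table_set()] on user-supplied CSV files, or
#' [generate_table_set()] for structurally faithful synthetic stand-ins.
#'
#' @param gsv data.frame with columns `subdomain`, `raw`, `gsv`.
#' @param vscale data.frame with columns `subdomain`, `age_min_months`,
#'   `age_max_months`, `vscale`, `raw_min`, `raw_max`.  Age bands are
#'   half-open intervals `[age_min_months, age_max_months)`.
#' @param sem data.frame with columns `subdomain`, `age_min_months`,
#'   `age_max_months`, `sem_gsv`, `reliability`.
#' @param provenance `"synthetic"` or `"user-supplied"`.
#' @return An object of class `table_set`.
#' @seealso [validate_table_set()], [load_table_set()], [write_table_set()]
#' @export
table_set <- function(gsv, vscale, sem, provenance = "user-supplied") {
  x <- structure(list(gsv = as.data.frame(gsv),
                      vscale = as.data.frame(vscale),
                      sem = as.data.frame(sem),
                      provenance = provenance),
                 class = "table_set")
  report <- validate_table_set(x)
  if (nrow(report) > 0L) {
    stop("invalid table set:\n",
         paste0("  [", report$component, "/", report$subdomain, "] ",
                report$message, collapse = "\n"),
         call. = FALSE)
  }
  x
}

#' @export
print.table_set <- function(x, ...) {
  subs <- subdomains(x)
  cat("<table_set> (", x$provenance, ")\n", sep = "")
  cat("  subdomains: ", length(subs), " (",
      paste(utils::head(subs, 5), collapse = ", "),
      if (length(subs) > 5) ", ..." else "", ")\n", sep = "")
  nb <- length(unique(paste(x$sem$age_min_months, x$sem$age_max_months)))
  cat("  age bands:  ", nb, " spanning [",
      min(x$sem$age_min_months), ", ", max(x$sem$age_max_months),
      ") months\n", sep = "")
  invisible(x)
}

#' @export
summary.table_set <- function(object, ...) {
  g <- object$gsv
  per <- split(g, g$subdomain)
  out <- data.frame(
    subdomain = names(per),
    max_raw = vapply(per, function(d) max(d$raw), 0),
    gsv_min = vapply(per, function(d) min(d$gsv), 0),
    gsv_max = vapply(per, function(d) max(d$gsv), 0),
    row.names = NULL
  )
  s <- object$sem
  out$sem_min <- vapply(out$subdomain, function(k) min(s$sem_gsv[s$subdomain == k]), 0)
  out$sem_max <- vapply(out$subdomain, function(k) max(s$sem_gsv[s$subdomain == k]), 0)
  out
}

#' Subdomain identifiers of a table set
#' @param tables a `table_set`.
#' @return Character vector of subdomain names.
#' @export
subdomains <- function(tables) {
  sort(unique(as.character(tables$gsv$subdomain)))
}

#' Extract single-subdomain lookup tables
#'
#' @param tables a `table_set`.
#' @param subdomain subdomain identifier.
#' @return A data.frame restricted to the subdomain, classed so the
#'   conversion operations ([gsv_from_raw()] etc.) can check what they
#'   were handed.
#' @export
gsv_table <- function(tables, subdomain) {
  d <- tables$gsv[tables$gsv$subdomain == subdomain, , drop = FALSE]
  assert_that(nrow(d) > 0, "no GSV table for subdomain '%s'", subdomain)
  d <- d[order(d$raw), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("gsv_table", "data.frame")
  d
}

#' @rdname gsv_table
#' @export
vscale_table <- function(tables, subdomain) {
  d <- tables$vscale[tables$vscale$subdomain == subdomain, , drop = FALSE]
  assert_that(nrow(d) > 0, "no V-scale table for subdomain '%s'", subdomain)
  d <- d[order(d$age_min_months, d$vscale), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("vscale_table", "data.frame")
  d
}

#' @rdname gsv_table
#' @export
sem_table <- function(tables, subdomain) {
  d <- tables$sem[tables$sem$subdomain == subdomain, , drop = FALSE]
  assert_that(nrow(d) > 0, "no SEM table for subdomain '%s'", subdomain)
  d <- d[order(d$age_min_months), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("sem_table", "data.frame")
  d
}

## ---------------------------------------------------------------- lookups

#' Convert a raw score to its growth scale value
#'
#' Exact table lookup: each raw score of a subdomain has one tabulated GSV.
#'
#' @param table a `gsv_table` (see [gsv_table()]).
#' @param raw integer raw score(s), `0 <= raw <= max(table$raw)`.
#' @return Integer GSV value(s).
#' @export
gsv_from_raw <- function(table, raw) {
  assert_that(inherits(table, "gsv_table"), "`table` must be a gsv_table")
  assert_that(all(raw == as.integer(raw)), "`raw` must be integer-valued")
  bad <- raw < 0 | raw > max(table$raw)
  assert_that(!any(bad), "raw score out of range [0, %d]: %s",
              max(table$raw), paste(raw[bad], collapse = ", "))
  table$gsv[match(raw, table$raw)]
}

#' Convert a growth scale value back to a raw score
#'
#' Several raw scores can share one tabulated GSV (plateaus in the Rasch
#' map).  Following the scoring convention used for simulated trials, the
#' median raw score of the set is returned; for an even-sized set the lower
#' of the two central values is taken, keeping the result an attainable
#' integer count.
#'
#' @param table a `gsv_table`.
#' @param gsv tabulated GSV value(s).
#' @return Integer raw score(s).
#' @export
raw_from_gsv <- function(table, gsv) {
  assert_that(inherits(table, "gsv_table"), "`table` must be a gsv_table")
  med <- median_raw_by_gsv(table)
  idx <- match(gsv, med$gsv)
  assert_that(!anyNA(idx), "GSV value(s) not tabulated: %s",
              paste(gsv[is.na(idx)], collapse = ", "))
  med$raw[idx]
}

# one row per distinct tabulated gsv, carrying the lower-median raw score
median_raw_by_gsv <- function(table) {
  raws <- split(table$raw, table$gsv)
  data.frame(gsv = as.numeric(names(raws)),
             raw = as.integer(vapply(raws, function(r) {
               r <- sort(r)
               r[ceiling(length(r) / 2)]   # lower of two central values
             }, 0)))
}

#' Convert a raw score to a V-scale score at a given age
#'
#' Selects the normative age band containing `age_months` (bands are
#' half-open `[min, max)`), then returns the V-scale value whose raw band
#' contains `raw`.
#'
#' @param table a `vscale_table`.
#' @param age_months integer age in months.
#' @param raw integer raw score(s).
#' @return Integer V-scale score(s) in `[1, 24]`.
#' @export
vscale_from_raw <- function(table, age_months, raw) {
  assert_that(inherits(table, "vscale_table"), "`table` must be a vscale_table")
  band <- table[table$age_min_months <= age_months &
                  age_months < table$age_max_months, , drop = FALSE]
  assert_that(nrow(band) > 0, "age %d months not covered by any age band",
              as.integer(age_months))
  band <- band[order(band$raw_min), , drop = FALSE]
  bad <- raw < min(band$raw_min) | raw > max(band$raw_max)
  assert_that(!any(bad), "raw score out of range [%d, %d]: %s",
              min(band$raw_min), max(band$raw_max),
              paste(raw[bad], collapse = ", "))
  band$vscale[findInterval(raw, band$raw_min)]
}

#' Mean raw score of a V-scale band
#'
#' The midpoint of the raw-score band associated with a V-scale value in
#' the age band containing `age_months`, rounded half-up to the nearest
#' integer.  This is the "average raw score" used when anchoring a
#' generative mean at a target impairment level.
#'
#' @param table a `vscale_table`.
#' @param age_months integer age in months.
#' @param vscale target V-scale value.
#' @return Integer raw score.  Signals a condition of class
#'   `abilitysim_infeasible` when the band is absent at this age (the
#'   scenario cannot be anchored and should be skipped).
#' @export
mean_raw_for_vscale <- function(table, age_months, vscale) {
  assert_that(inherits(table, "vscale_table"), "`table` must be a vscale_table")
  band <- table[table$age_min_months <= age_months &
                  age_months < table$age_max_months, , drop = FALSE]
  assert_that(nrow(band) > 0, "age %d months not covered by any age band",
              as.integer(age_months))
  row <- band[band$vscale == vscale, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop_infeasible(
      "V-scale %d has no raw-score band at age %d months (subdomain '%s')",
      as.integer(vscale), as.integer(age_months), band$subdomain[1])
  }
  as.integer(round_half_up((row$raw_min[1] + row$raw_max[1]) / 2))
}

## ---------------------------------------------------------------- I/O

#' Read a table set from the three CSV schemas
#'
#' All files are UTF-8 CSV with a header row; integer columns are strict.
#' Every structural invariant is checked on load and violations are
#' reported with the offending subdomain and row.
#'
#' @param gsv_path CSV with columns `subdomain,raw,gsv`.
#' @param vscale_path CSV with columns
#'   `subdomain,age_min_months,age_max_months,vscale,raw_min,raw_max`.
#' @param sem_path CSV with columns
#'   `subdomain,age_min_months,age_max_months,sem_gsv,reliability`.
#' @return A validated `table_set` with provenance `"user-supplied"`.
#' @export
load_table_set <- function(gsv_path, vscale_path, sem_path) {
  read_strict <- function(path, cols, int_cols, num_cols = character()) {
    assert_that(file.exists(path), "file not found: %s", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
    missing <- setdiff(cols, names(d))
    assert_that(length(missing) == 0, "%s: missing column(s): %s",
                basename(path), paste(missing, collapse = ", "))
    d <- d[cols]
    for (cc in int_cols) {
      v <- d[[cc]]
      assert_that(is.numeric(v) && !anyNA(v) && all(v == as.integer(v)),
                  "%s: column '%s' must be integer with no missing values",
                  basename(path), cc)
      d[[cc]] <- as.integer(v)
    }
    for (cc in num_cols) {
      assert_that(is.numeric(d[[cc]]) && !anyNA(d[[cc]]),
                  "%s: column '%s' must be numeric with no missing values",
                  basename(path), cc)
    }
    d$subdomain <- as.character(d$subdomain)
    d
  }
  gsv <- read_strict(gsv_path, c("subdomain", "raw", "gsv"),
                     c("raw", "gsv"))
  vsc <- read_strict(vscale_path,
                     c("subdomain", "age_min_months", "age_max_months",
                       "vscale", "raw_min", "raw_max"),
                     c("age_min_months", "age_max_months", "vscale",
                       "raw_min", "raw_max"))
  sem <- read_strict(sem_path,
                     c("subdomain", "age_min_months", "age_max_months",
                       "sem_gsv", "reliability"),
                     c("age_min_months", "age_max_months"),
                     c("sem_gsv", "reliability"))
  table_set(gsv, vsc, sem, provenance = "user-supplied")
}

#' Write a table set to the three CSV schemas
#'
#' @param tables a `table_set`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths written
#'   (`gsv_table.csv`, `vscale_table.csv`, `sem_reliability.csv`).
#' @export
write_table_set <- function(tables, dir) {
  assert_that(inherits(tables, "table_set"), "`tables` must be a table_set")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gsv_table.csv", "vscale_table.csv",
                            "sem_reliability.csv"))
  utils::write.csv(tables$gsv, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$vscale, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$sem, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

## ---------------------------------------------------------------- validation

#' Validate the structural invariants of a table set
#'
#' Checks every invariant the simulator relies on and reports violations;
#' it never raises.  Checked are, per subdomain: raw scores unique and
#' contiguous from 0; GSV nondecreasing with minimum 10 and maximum in
#' [110, 197]; V-scale in [1, 24], raw bands disjoint, ordered and jointly
#' covering [0, max raw] within each age band; age bands half-open,
#' non-overlapping and gap-free; V-scale nonincreasing in age for fixed
#' raw; SEM positive and reliability in (0, 1); identical subdomain keys
#' across the three components.
#'
#' @param tables a `table_set`, or a bare list with elements `gsv`,
#'   `vscale`, `sem` (so that broken candidates can be inspected).
#' @return data.frame with columns `component`, `subdomain`, `message`;
#'   zero rows means the set is valid.
#' @export
validate_table_set <- function(tables) {
  bad <- list()
  note <- function(component, subdomain, msg, ...) {
    bad[[length(bad) + 1L]] <<- data.frame(
      component = component, subdomain = subdomain,
      message = sprintf(msg, ...), stringsAsFactors = FALSE)
  }

  gsv <- tables$gsv; vsc <- tables$vscale; sem <- tables$sem
  keys <- lapply(list(gsv, vsc, sem),
                 function(d) sort(unique(as.character(d$subdomain))))
  if (!identical(keys[[1]], keys[[2]]) || !identical(keys[[1]], keys[[3]])) {
    note("table_set", "*", "subdomain keys differ across components")
  }

  for (k in keys[[1]]) {
    g <- gsv[gsv$subdomain == k, , drop = FALSE]
    g <- g[order(g$raw), , drop = FALSE]
    if (!identical(as.integer(g$raw), seq(0L, nrow(g) - 1L))) {
      note("gsv", k, "raw scores are not unique and contiguous from 0")
      next
    }
    dg <- diff(g$gsv)
    if (any(dg < 0)) {
      note("gsv", k, "gsv decreases at raw=%d", g$raw[which(dg < 0)[1] + 1L])
    }
    if (min(g$gsv) != 10) note("gsv", k, "minimum gsv is %d, expected 10", min(g$gsv))
    if (max(g$gsv) < 110 || max(g$gsv) > 197) {
      note("gsv", k, "maximum gsv %d outside [110, 197]", max(g$gsv))
    }
    max_raw <- max(g$raw)

    v <- vsc[vsc$subdomain == k, , drop = FALSE]
    if (any(v$vscale < 1 | v$vscale > 24)) note("vscale", k, "vscale outside [1, 24]")
    band_key <- paste(v$age_min_months, v$age_max_months, sep = "-")
    bands <- unique(v[c("age_min_months", "age_max_months")])
    bands <- bands[order(bands$age_min_months), , drop = FALSE]
    if (any(bands$age_min_months >= bands$age_max_months)) {
      note("vscale", k, "degenerate age band (min >= max)")
    }
    if (nrow(bands) > 1) {
      gaps <- bands$age_min_months[-1] - bands$age_max_months[-nrow(bands)]
      if (any(gaps > 0)) note("vscale", k, "gap between age bands at %d months",
                              bands$age_max_months[which(gaps > 0)[1]])
      if (any(gaps < 0)) note("vscale", k, "overlapping age bands at %d months",
                              bands$age_min_months[-1][which(gaps < 0)[1]])
    }
    for (b in unique(band_key)) {
      vb <- v[band_key == b, , drop = FALSE]
      vb <- vb[order(vb$raw_min), , drop = FALSE]
      if (is.unsorted(vb$vscale)) {
        note("vscale", k, "band %s: vscale not nondecreasing in raw", b)
      }
      if (any(vb$raw_min > vb$raw_max)) {
        note("vscale", k, "band %s: raw_min > raw_max", b)
        next
      }
      cover_ok <- vb$raw_min[1] == 0 && vb$raw_max[nrow(vb)] == max_raw &&
        (nrow(vb) == 1 || all(vb$raw_min[-1] == vb$raw_max[-nrow(vb)] + 1L))
      if (!cover_ok) {
        hole <- if (vb$raw_min[1] != 0) 0L
        else if (nrow(vb) > 1 && any(vb$raw_min[-1] != vb$raw_max[-nrow(vb)] + 1L)) {
          i <- which(vb$raw_min[-1] != vb$raw_max[-nrow(vb)] + 1L)[1]
          vb$raw_max[i] + 1L
        } else max_raw
        note("vscale", k,
             "band %s: raw bands do not partition [0, %d] (problem near raw=%d)",
             b, max_raw, hole)
      }
    }
    # fixed raw, vscale nonincreasing across increasing age bands
    if (nrow(bands) > 1 && length(bad) == 0) {
      probe <- unique(round(seq(0, max_raw, length.out = 25)))
      vmat <- try(vapply(seq_len(nrow(bands)), function(i) {
        vt <- v; class(vt) <- c("vscale_table", "data.frame")
        vscale_from_raw(vt, bands$age_min_months[i], probe)
      }, numeric(length(probe))), silent = TRUE)
      if (!inherits(vmat, "try-error") &&
          any(apply(vmat, 1, function(r) any(diff(r) > 0)))) {
        note("vscale", k, "vscale increases with age for a fixed raw score")
      }
    }

    s <- sem[sem$subdomain == k, , drop = FALSE]
    if (any(s$sem_gsv <= 0)) note("sem", k, "sem_gsv must be > 0")
    if (any(s$reliability <= 0 | s$reliability >= 1)) {
      note("sem", k, "reliability must lie in (0, 1)")
    }
    sb <- s[order(s$age_min_months), , drop = FALSE]
    if (nrow(sb) > 1 &&
        any(sb$age_min_months[-1] != sb$age_max_months[-nrow(sb)])) {
      note("sem", k, "SEM age bands do not partition the age support")
    }
  }

  if (length(bad) == 0) {
    data.frame(component = character(), subdomain = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}
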