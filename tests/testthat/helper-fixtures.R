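# Hand-built fixture tables used across test files.
#
# chain_fixture(): one-age-band table set with two subdomains whose
# conversion chain can be traced by hand:
#   X: gsv(raw) = 10 + floor(2.5 * raw), raw 0..60, so gsv(12) = 40;
#      V-scale band 6 covers raws 10..14 at any age in [36, 84).
#   Y: like X but the V-scale 1 band is the single raw 0 (degenerate
#      floor band), gsv(raw) = 10 + 2 * raw, raw 0..55.
chain_fixture <- function() {
  raw_x <- 0:60
  gsv_x <- data.frame(subdomain = "X", raw = raw_x,
                      gsv = 10L + as.integer(floor(2.5 * raw_x)))
  raw_y <- 0:55
  gsv_y <- data.frame(subdomain = "Y", raw = raw_y, gsv = 10L + 2L * raw_y)

  vband <- function(sub, v, lo, hi) {
    data.frame(subdomain = sub, age_min_months = 36L, age_max_months = 90L,
               vscale = v, raw_min = lo, raw_max = hi)
  }
  # X: v1..v5 two raws each up to 9, v6 = [10, 14], v7..v23 two raws,
  # v24 takes the remainder.
  vx <- rbind(
    do.call(rbind, lapply(1:5, function(v) {
      vband("X", v, 2L * (v - 1L), 2L * v - 1L)
    })),
    vband("X", 6L, 10L, 14L),
    do.call(rbind, lapply(7:23, function(v) {
      vband("X", v, 15L + 2L * (v - 7L), 16L + 2L * (v - 7L))
    })),
    vband("X", 24L, 49L, 60L))
  # Y: v1 = [0, 0], v2..v23 two raws each, v24 remainder.
  vy <- rbind(
    vband("Y", 1L, 0L, 0L),
    do.call(rbind, lapply(2:23, function(v) {
      vband("Y", v, 1L + 2L * (v - 2L), 2L + 2L * (v - 2L))
    })),
    vband("Y", 24L, 45L, 55L))

  sem <- data.frame(subdomain = c("X", "Y"),
                    age_min_months = 36L, age_max_months = 90L,
                    sem_gsv = c(3, 4), reliability = c(0.75, 0.84))
  table_set(rbind(gsv_x, gsv_y), rbind(vx, vy), sem,
            provenance = "user-supplied")
}

# A gsv_table (single subdomain) classed directly, bypassing table_set
# validation, for unit tests of the lookup operations alone.
mini_gsv_table <- function(raw, gsv, subdomain = "mini") {
  structure(data.frame(subdomain = subdomain, raw = as.integer(raw),
                       gsv = as.integer(gsv)),
            class = c("gsv_table", "data.frame"))
}

mini_vscale_table <- function(rows, subdomain = "mini") {
  d <- do.call(rbind, lapply(rows, function(r) {
    data.frame(subdomain = subdomain, age_min_months = r[[1]],
               age_max_months = r[[2]], vscale = r[[3]],
               raw_min = r[[4]], raw_max = r[[5]])
  }))
  structure(d, class = c("vscale_table", "data.frame"))
}

# Table set in which every raw score maps to V-scale 1 at every age
# (the saturating-floor construction).
floor_fixture <- function() {
  raw <- 0:60
  gsv <- data.frame(subdomain = "F", raw = raw, gsv = 10L + 2L * raw)
  vsc <- data.frame(subdomain = "F", age_min_months = 36L,
                    age_max_months = 90L, vscale = 1L,
                    raw_min = 0L, raw_max = 60L)
  sem <- data.frame(subdomain = "F", age_min_months = 36L,
                    age_max_months = 90L, sem_gsv = 3, reliability = 0.75)
  table_set(gsv, vsc, sem, provenance = "user-supplied")
}

# Independent normal-equations ANCOVA oracle: explicit 3x3 solve.
ancova_oracle <- function(endpoint, baseline, arm) {
  X <- cbind(1, arm, baseline)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% endpoint)
  res <- endpoint - X %*% beta
  df <- length(endpoint) - 3L
  s2 <- sum(res^2) / df
  covb <- s2 * solve(XtX)
  t_stat <- beta[2] / sqrt(covb[2, 2])
  list(beta = beta[2], t = t_stat, p = 2 * pt(-abs(t_stat), df))
}
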