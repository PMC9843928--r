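# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("abilitysim_infeasible", "abilitysim_error")))
}

is_infeasible_error <- function(e) inherits(e, "abilitysim_infeasible")

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-scenario seed below 2^31 from a root seed so that scenarios
# can be simulated in any order (or in isolation) with identical results.
derive_seed <- function(root_seed, scenario_index, condition_flag = 0L) {
  root <- as.numeric(root_seed) %% 1048576       # keep products < 2^31
  s <- (root * 1789 + as.numeric(scenario_index) * 613 +
          as.numeric(condition_flag) * 307) %% 2147483647
  as.integer(s) + 1L
}

# Smallest even integer >= x (balanced two-arm sample sizes).
even_ceiling <- function(x) {
  n <- as.integer(ceiling(x - 1e-9))
  if (n %% 2L == 1L) n + 1L else n
}

round_half_up <- function(x) floor(x + 0.5)
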