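# Internal helpers shared across modules.

#' Evaluate code under a local RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call. All generators in this package route
#' their randomness through this helper so that a fixed seed gives
#' bit-identical output and no caller-visible RNG state is disturbed.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic, order-independent per-label seed derived from a master seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(master_seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (k in seq_along(codes)) {
    h <- (h * 131 + codes[k]) %% 1000000007
  }
  as.integer((as.numeric(master_seed) %% 1000000007 + h) %% 2147483647L)
}

# Validate a single positive finite scalar.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("invalid config: '%s' must be a positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("invalid config: '%s' must be a non-negative finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Median sampling interval of a (close to uniform) time grid.
grid_dt <- function(time_s) {
  if (length(time_s) < 2L) stop("need at least two samples to infer a sampling interval")
  stats::median(diff(time_s))
}
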