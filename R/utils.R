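# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state locally for a generator
#'
#' Generators take an explicit `seed`; `NULL` leaves the caller's RNG
#' stream untouched so generators can be composed inside a larger seeded
#' computation.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# nearest integer with a tolerance check; used where a real parameter must
# resolve to a whole number of samples
as_count <- function(x, what, tol = 1e-8) {
  n <- round(x)
  if (abs(x - n) > tol * max(1, abs(x))) {
    stop(sprintf("%s must resolve to an integer (got %g)", what, x), call. = FALSE)
  }
  as.integer(n)
}

stop_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# robust noise scale: median absolute value / 0.6745 (consistent for a
# Gaussian); insensitive to embedded spikes
robust_sigma <- function(x) stats::median(abs(x)) / 0.6745
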