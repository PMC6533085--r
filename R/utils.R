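# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}

# Deterministic sub-seed derivation: keeps all derived seeds inside the 32-bit
# integer range so they can be passed back to set.seed().
#' @keywords internal
#' @noRd
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629
  as.integer(s) + 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Centered moving average with edge shrinkage (window truncated at the ends);
# used to stabilize peak detection against sample-wise noise excursions.
#' @keywords internal
#' @noRd
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
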