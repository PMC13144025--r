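# Internal helpers: seeding, argument checks, small numerics.

# Faraday constant, C/mol. Ca2+ carries 2 elementary charges per ion.
.FARADAY <- 96485.33212

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_arg(sprintf("`%s` must be a single %s number", name,
                     if (strict) "positive" else "non-negative"))
  }
  as.numeric(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-trial seed from a base seed and condition/trial indices
#'
#' Deterministic integer mixing (multiplicative hashing modulo the Mersenne
#' prime 2^31 - 1) so batch protocols have no hidden global random state and
#' any single trial can be reproduced in isolation.
#'
#' @param base_seed integer base seed of the run.
#' @param ... further non-negative integers (condition index, trial index,
#'   stream tag, ...) folded into the hash in order.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(base_seed, ...) {
  parts <- c(base_seed, ...)
  m <- 2147483647
  h <- 2166136261 %% m
  for (v in parts) {
    v <- as.numeric(v) %% m
    h <- (h * 48271) %% m
    h <- (h + v * 69621 + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Trapezoidal integral of y(x); used for spark mass (pA * ms = fC).
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Round-half-up to the nearest integer (documented rounding contract for
# fractional channel counts; base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)
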