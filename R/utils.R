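## internal helpers shared across modules

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic component (mixing weights, odor draws, glomerular noise,
#' reward noise) draws from its own sub-stream so that any one component can
#' be regenerated in isolation.  Sub-seeds are derived deterministically from
#' the master seed and a text label, and stay below 2^31.
#'
#' @param seed integer master seed.
#' @param label character label of the sub-stream.
#' @return an integer seed.
#' @export
#' @examples
#' subSeed(1, "weights")
subSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

## parameter validation helper: scalar, finite, optionally bounded
.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g is outside its admissible range (%g, %g)",
                 name, x, lower, upper), call. = FALSE)
  invisible(TRUE)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
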