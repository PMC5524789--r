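#' Inverse-logit (logistic) transform
#'
#' Maps a log-odds value to a probability. Numerically stable for large
#' arguments: computed as `exp(x)/(1+exp(x))` for negative `x` and
#' `1/(1+exp(-x))` otherwise, so it does not overflow for |x| up to ~700.
#'
#' @param x Numeric vector of log-odds; must be finite.
#' @return Probabilities in (0, 1).
#' @examples
#' inverse_logit(0)      # 0.5
#' inverse_logit(-0.2)   # ~0.45017
#' @export
inverse_logit <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out
}

#' Logit transform
#' @param p Probabilities in (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p), all(p > 0), all(p < 1))
  log(p / (1 - p))
}

# Derive a child seed from a master seed and a stage counter.
# Stages are numbered so that adding a later pipeline stage never perturbs
# the streams of earlier ones. Result kept strictly below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stopifnot(is.numeric(stage), length(stage) == 1, stage >= 0)
  (abs(as.double(seed)) * 101 + 1013904223 * (stage + 1)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
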