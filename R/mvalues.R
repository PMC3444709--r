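#' Convert paired signal intensities to M-values
#'
#' Summarises Infinium probe-level methylation as
#' `M = log2((max(signal_b, 0) + 1) / (max(signal_a, 0) + 1))`, where signal A
#' is the unmethylated-channel intensity and signal B the methylated-channel
#' intensity. Background-corrected intensities may be negative; they are
#' clamped at zero before the +1 offset, so the transform is defined for any
#' finite input.
#'
#' @param signal_a Numeric vector or matrix of unmethylated-channel
#'   intensities.
#' @param signal_b Numeric vector or matrix of methylated-channel
#'   intensities, same shape as `signal_a`.
#' @return M-values, same shape as the inputs.
#' @seealso [beta2m()], [m2beta()]
#' @examples
#' signals2m(100, 100)   # equal channels -> 0
#' signals2m(0, 1023)    # log2(1024/1) = 10
#' @export
signals2m <- function(signal_a, signal_b) {
  if (!is.numeric(signal_a) || !is.numeric(signal_b))
    stop("signal intensities must be numeric", call. = FALSE)
  if (!identical(dim(signal_a), dim(signal_b)) ||
      length(signal_a) != length(signal_b))
    stop("signal_a and signal_b must have identical shape", call. = FALSE)
  if (any(!is.finite(signal_a)) || any(!is.finite(signal_b)))
    stop("non-finite signal intensity", call. = FALSE)
  m <- log2((pmax(signal_b, 0) + 1) / (pmax(signal_a, 0) + 1))
  if (is.matrix(signal_a)) dimnames(m) <- dimnames(signal_a)
  m
}

#' Convert beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[eps, 1 - eps]`; the clip keeps M finite at the extremes with negligible
#' distortion at array precision.
#'
#' @param beta Numeric vector or matrix of beta-values in `[0, 1]`.
#' @param eps Clipping constant (default `1e-6`).
#' @return M-values on the log2-ratio scale.
#' @export
beta2m <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) stop("beta must be numeric", call. = FALSE)
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad))
    stop("beta-values outside [0, 1]: e.g. ", beta[bad][1], call. = FALSE)
  bc <- pmin(pmax(beta, eps), 1 - eps)
  log2(bc / (1 - bc))
}

#' Convert M-values to beta-values
#'
#' Inverse of [beta2m()] (for beta away from the clipping boundary):
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in `(0, 1)`.
#' @export
m2beta <- function(m) {
  if (!is.numeric(m)) stop("m must be numeric", call. = FALSE)
  stats::plogis(m * log(2))
}
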