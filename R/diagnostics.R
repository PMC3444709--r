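#' Variance inflation factors
#'
#' Multicollinearity diagnostic for the covariates of a fitted model:
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the ordinary least-squares
#' regression of covariate `j` on the other non-intercept covariates (with
#' intercept). A constant covariate, or one exactly reproduced by the
#' others, reports `Inf`. With a single non-intercept covariate the VIF is
#' trivially 1. The result carries a `flag` attribute, `TRUE` when the
#' largest VIF exceeds `threshold` — the convention used here to reject a
#' model as multicollinear.
#'
#' @param X Design matrix of the fit; an intercept column (constant) is
#'   detected and excluded from the covariate set.
#' @param threshold Flagging threshold (default 5).
#' @return Named numeric vector of VIFs, with attribute `flag`.
#' @export
vif <- function(X, threshold = 5) {
  X <- as.matrix(X)
  is_const <- apply(X, 2, function(v) stats::sd(v) == 0)
  Z <- X[, !is_const, drop = FALSE]
  p <- ncol(Z)
  if (p == 0) return(structure(numeric(0), flag = FALSE))
  out <- setNames(numeric(p), colnames(Z))
  for (j in seq_len(p)) {
    xj <- Z[, j]
    sst <- sum((xj - mean(xj))^2)
    if (sst == 0) { out[j] <- Inf; next }
    if (p == 1) { out[j] <- 1; next }
    others <- cbind(1, Z[, -j, drop = FALSE])
    qr_o <- qr(others)
    res <- qr.resid(qr_o, xj)
    r2 <- 1 - sum(res^2) / sst
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  structure(out, flag = any(out > threshold))
}
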