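# Maximum-likelihood logistic regression by iteratively reweighted least
# squares (Newton-Raphson on the log-likelihood), with the diagnostics the
# calibration pipeline needs: observed-information covariance, a
# gradient-norm convergence flag, and detection of complete separation so
# that screening loops over degenerate probes survive.

.log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

.binom_loglik <- function(y, eta) sum(y * eta - .log1pexp(eta))

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit of a binary response on a design matrix
#' that already contains its intercept column. Convergence is declared when
#' the maximum absolute score (gradient) falls below `tol`; the coefficient
#' covariance is the inverse observed information at the final iterate.
#' Complete or quasi-complete separation (fitted probabilities pinned at 0
#' or 1 with diverging coefficients) is flagged — not an error — and the
#' coefficients of the last iterate are returned, so probe-screening loops
#' can continue past degenerate predictors.
#'
#' @param X Numeric design matrix, n x k, including an intercept column
#'   (conventionally the first, named `(Intercept)`).
#' @param y Binary response (0/1 or logical), both classes present.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @return A `logit_fit` list: `coefficients` (named, intercept included),
#'   `intercept`, `probe_ids` (non-intercept column names), `covariance`,
#'   `fitted`, `loglik`, `k` (parameter count including intercept), `n`,
#'   `converged`, `separation`, `aicc` (NA when n <= k+1).
#' @seealso [lrt()], [aicc()], [stepwise_aicc()]
#' @export
fit_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present in y", call. = FALSE)
  if (n < k + 2)
    stop("need n >= k + 2 observations to fit ", k, " parameters",
         call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))[seq_len(k)]

  beta <- numeric(k)
  beta[1] <- qlogis(mean(y))          # start at the prevalence logit
  eta <- drop(X %*% beta)
  ll <- .binom_loglik(y, eta)
  converged <- FALSE
  separation <- FALSE
  H <- NULL
  for (iter in seq_len(max_iter)) {
    mu <- plogis(eta)
    grad <- crossprod(X, y - mu)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    H <- crossprod(X * w, X)
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) { separation <- TRUE; break }
    step <- 1
    repeat {                          # step-halving keeps the ascent monotone
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(X %*% beta_new)
      ll_new <- .binom_loglik(y, eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; eta_new <- eta; ll_new <- ll
                          break }
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
  }
  # quasi/complete separation: fitted probabilities pinned at 0/1 while
  # the likelihood climbs towards its supremum (at the gradient tolerance
  # the pinned residuals are O(tol), hence the matching threshold)
  mu <- plogis(eta)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) separation <- TRUE
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  H <- crossprod(X * w, X)
  covariance <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, k, k))
  dimnames(covariance) <- list(colnames(X), colnames(X))
  if (separation)
    warning(sprintf("possible complete separation (fit on %d samples); %s",
                    n, "coefficients are the last iterate"),
            call. = FALSE)
  fit <- structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    intercept = unname(beta[1]),
    probe_ids = colnames(X)[-1],
    covariance = covariance,
    fitted = mu,
    loglik = ll,
    k = k, n = n,
    converged = converged,
    separation = separation,
    aicc = NA_real_), class = "logit_fit")
  if (n > k + 1) fit$aicc <- aicc(fit)
  fit
}

# Convenience: fit intercept + selected probe rows of a probes-x-samples
# M matrix against binary labels.
.fit_probes <- function(m, labels, probes) {
  X <- cbind("(Intercept)" = 1,
             t(m[probes, , drop = FALSE]))
  fit_logistic(X, labels)
}

# Closed-form intercept-only fit (logit of the prevalence).
.fit_null <- function(labels) {
  y <- as.numeric(labels)
  n <- length(y)
  p <- mean(y)
  structure(list(
    coefficients = c("(Intercept)" = qlogis(p)),
    intercept = qlogis(p),
    probe_ids = character(0),
    covariance = matrix(1 / (n * p * (1 - p)), 1, 1,
                        dimnames = list("(Intercept)", "(Intercept)")),
    fitted = rep(p, n),
    loglik = n * (p * log(p) + (1 - p) * log(1 - p)),
    k = 1L, n = n, converged = TRUE, separation = FALSE,
    aicc = NA_real_), class = "logit_fit") -> fit
  if (n > 2) fit$aicc <- aicc(fit)
  fit
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)` with `k` counting the
#' intercept; undefined (error) when `n <= k + 1`.
#'
#' @param fit A `logit_fit` object.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  k <- fit$k; n <- fit$n
  if (n <= k + 1)
    stop("AICc undefined for n <= k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Log-likelihood ratio test between nested logistic fits
#'
#' `stat = 2 (loglik_full - loglik_null)` referred to a chi-squared
#' distribution with `df = k_full - k_null` degrees of freedom. The two
#' fits must be on the same samples with the null nested in the full model;
#' a materially negative statistic indicates broken nesting and is an
#' error (tiny negative values from round-off are clamped to zero).
#'
#' @param full,null `logit_fit` objects.
#' @return List with `stat`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  if (full$n != null$n)
    stop("LRT requires fits on the same samples", call. = FALSE)
  df <- full$k - null$k
  if (df < 0) stop("null model must be nested in the full model",
                   call. = FALSE)
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -1e-8)
    stop("negative LRT statistic (", format(stat),
         "): models are not nested", call. = FALSE)
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit: n =", x$n, ", k =", x$k,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$coefficients)
  cat("loglik =", format(x$loglik), " AICc =", format(x$aicc),
      if (x$separation) " [separation]" else "", "\n")
  invisible(x)
}
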