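#' Univariate probe screen with Bonferroni correction
#'
#' First step of the two-step model construction: every candidate probe is
#' tested alone (intercept + probe vs intercept-only) by the log-likelihood
#' ratio test, and p-values are Bonferroni-adjusted with the family size
#' equal to the number of candidate probes supplied. A probe is selected
#' when its adjusted p-value is below `alpha`. Separation in an individual
#' probe fit is recorded in the `separation` column and does not abort the
#' screen.
#'
#' @param m Probe-by-sample M-value matrix restricted to candidate probes.
#' @param labels Binary response (1/TRUE = methylated by MSP), no missing
#'   values, both classes present.
#' @param alpha Familywise significance level (default 0.05).
#' @return A `screen_result` data frame with columns `probe_id`,
#'   `lrt_stat`, `df`, `p`, `p_bonferroni`, `selected`, `separation`.
#' @export
univariate_screen <- function(m, labels, alpha = 0.05) {
  if (nrow(m) < 1) stop("need at least one candidate probe", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  labels <- as.numeric(labels)
  null <- .fit_null(labels)
  m_tests <- nrow(m)
  rows <- lapply(rownames(m), function(pid) {
    sep <- FALSE
    fit <- withCallingHandlers(
      .fit_probes(m, labels, pid),
      warning = function(w) {
        if (grepl("separation", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    test <- lrt(fit, null)
    data.frame(probe_id = pid, lrt_stat = test$stat, df = test$df,
               p = test$p, stringsAsFactors = FALSE, separation = sep)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, m_tests * out$p)
  out$selected <- out$p_bonferroni < alpha
  out <- out[, c("probe_id", "lrt_stat", "df", "p", "p_bonferroni",
                 "selected", "separation")]
  class(out) <- c("screen_result", "data.frame")
  out
}
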