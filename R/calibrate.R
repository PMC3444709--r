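#' Calibrate a methylation classifier from training data
#'
#' Runs the complete two-step construction on a training cohort:
#'
#' 1. univariate LRT screen of every candidate probe against the MSP
#'    labels with Bonferroni correction ([univariate_screen()]);
#' 2. bidirectional stepwise logistic selection among the surviving probes
#'    under AICc ([stepwise_aicc()]);
#' 3. VIF multicollinearity diagnostic on the selected design ([vif()]);
#' 4. probability-cutoff optimization by sensitivity + specificity
#'    ([optimize_cutoff()]) and a full performance report at that cutoff.
#'
#' @param m Probe-by-sample M-value matrix of candidate probes.
#' @param labels Binary MSP reference (1/TRUE = methylated), aligned with
#'   the columns of `m`, no missing values.
#' @param manifest Optional `probe_manifest`; with `platform` set, the
#'   candidates are restricted to probes on that platform before
#'   screening.
#' @param platform Optional `"hm27"` or `"hm450"`.
#' @param alpha Familywise level of the screen (default 0.05).
#' @param model_id Identifier for the resulting model.
#' @return A `calibration` list: `model` (an `mgmt_logistic` with
#'   covariance and optimized cutoff), `fit` (the selected `logit_fit`),
#'   `screen`, `trace` (AICc path), `vif` (with `flag` attribute),
#'   `performance` (a `performance_report`).
#' @export
calibrate_model <- function(m, labels, manifest = NULL, platform = NULL,
                            alpha = 0.05, model_id = "custom") {
  if (!is.null(platform)) {
    if (is.null(manifest))
      stop("platform selection requires a manifest", call. = FALSE)
    m <- select_probes(m, manifest, platform = platform)
  }
  labels <- as.numeric(labels)
  screen <- univariate_screen(m, labels, alpha = alpha)
  selected <- screen$probe_id[screen$selected]
  if (!length(selected))
    stop("no probe passed the Bonferroni screen at alpha = ", alpha,
         call. = FALSE)
  fit <- stepwise_aicc(m, labels, candidates = selected)
  probes <- attr(fit, "selected_probes")
  if (!length(probes))
    stop("stepwise selection kept no probe (intercept-only model); ",
         "no classifier calibrated", call. = FALSE)
  v <- vif(t(m[probes, , drop = FALSE]))
  p <- .fit_prob(fit, m)
  cutoff <- optimize_cutoff(p, labels)
  perf <- performance_report(p, labels, cutoff)
  model <- logistic_model(probes,
                          intercept = fit$intercept,
                          coefficients = fit$coefficients[probes],
                          covariance = fit$covariance,
                          cutoff = cutoff, model_id = model_id)
  structure(list(model = model, fit = fit, screen = screen,
                 trace = attr(fit, "trace"), vif = v,
                 performance = perf),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  print(x$model)
  cat("Screen:", sum(x$screen$selected), "of", nrow(x$screen),
      "probes passed Bonferroni\n")
  if (length(x$vif))
    cat("max VIF:", format(max(x$vif)),
        if (isTRUE(attr(x$vif, "flag"))) "[multicollinearity flag]", "\n")
  print(x$performance)
  invisible(x)
}
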