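# Cutoff optimization and classification performance.

#' Optimal probability cutoff by sensitivity + specificity
#'
#' Scans the candidate cutoffs formed by the midpoints of adjacent sorted
#' unique probabilities plus the endpoints 0 and 1, classifying a sample as
#' positive when `p >= cutoff`, and returns the candidate maximizing
#' sensitivity + specificity. Ties are broken by the smallest cutoff
#' (favouring sensitivity). The candidate set depends only on the ranks of
#' the probabilities, so any strictly increasing transform of `p` yields
#' the same classification at the returned cutoff.
#'
#' @param p Numeric vector of predicted probabilities (any scores work).
#' @param y Binary reference (1 = positive), both classes present.
#' @return The selected cutoff. If all probabilities are identical the
#'   cutoff is 0 with a warning (degenerate score).
#' @export
optimize_cutoff <- function(p, y) {
  y <- as.numeric(y)
  if (length(p) != length(y)) stop("p and y must align", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present in y", call. = FALSE)
  u <- sort(unique(p))
  if (length(u) == 1) {
    warning("all probabilities identical; cutoff degenerate at 0",
            call. = FALSE)
    return(0)
  }
  cand <- c(0, (u[-1] + u[-length(u)]) / 2, 1)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  score <- vapply(cand, function(ct) {
    call_pos <- p >= ct
    sum(call_pos & y == 1) / npos + sum(!call_pos & y == 0) / nneg
  }, numeric(1))
  cand[which.max(score)]          # which.max takes the first (smallest) tie
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity, specificity, predictive values, proportion correct and
#' Cohen's kappa for binary calls against a binary reference. Kappa uses
#' the standard chance-correction `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products; it is symmetric in the two
#' classifications.
#'
#' @param calls Binary predicted status (1/TRUE/"methylated" = positive).
#' @param y Binary reference, both classes present.
#' @param cutoff Optional cutoff recorded in the report (not used in the
#'   computation).
#' @return A `performance_report` list with `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `kappa` and the confusion
#'   counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_metrics <- function(calls, y, cutoff = NA_real_) {
  as_bin <- function(v) {
    if (is.character(v) || is.factor(v)) as.character(v) == "methylated"
    else as.logical(v)
  }
  calls <- as_bin(calls); y <- as_bin(y)
  if (length(calls) != length(y)) stop("calls and y must align",
                                       call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present in the reference", call. = FALSE)
  tp <- sum(calls & y); fn <- sum(!calls & y)
  fp <- sum(calls & !y); tn <- sum(!calls & !y)
  n <- tp + fn + fp + tn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  structure(list(cutoff = cutoff,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 accuracy = p_o,
                 kappa = kappa,
                 tp = tp, fn = fn, fp = fp, tn = tn),
            class = "performance_report")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive sample scores higher, ties counting one half; this
#' equals trapezoidal integration of the empirical ROC curve.
#'
#' @param p Numeric scores.
#' @param y Binary reference (1 = positive), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(p, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present in y", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full performance report at a cutoff
#'
#' Convenience wrapper combining [confusion_metrics()] at
#' `calls = (p >= cutoff)` with the cutoff-free [roc_auc()].
#'
#' @inheritParams roc_auc
#' @param cutoff Probability cutoff.
#' @return A `performance_report` with an `auc` element.
#' @export
performance_report <- function(p, y, cutoff) {
  rep <- confusion_metrics(p >= cutoff, y, cutoff = cutoff)
  rep$auc <- roc_auc(p, y)
  rep
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Classification performance",
      if (!is.na(x$cutoff)) paste0("(cutoff = ", format(x$cutoff), ")"),
      "\n")
  cat(sprintf("  sens %.3f  spec %.3f  ppv %s  npv %s\n",
              x$sensitivity, x$specificity,
              formatC(x$ppv, format = "f", digits = 3),
              formatC(x$npv, format = "f", digits = 3)))
  cat(sprintf("  accuracy %.3f  kappa %.3f%s\n", x$accuracy, x$kappa,
              if (!is.null(x$auc)) sprintf("  auc %.3f", x$auc) else ""))
  invisible(x)
}
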