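#' Internal validation by the optimism-corrected bootstrap
#'
#' Validates the *process* used to build a classifier, not just the final
#' fit: for each of `reps` bootstrap resamples (n samples drawn with
#' replacement) the full model-building procedure — fitting plus cutoff
#' choice — is re-run on the resample, and each performance index is
#' evaluated both on the resample (`apparent_b`) and on the original data
#' (`test_b`). The optimism of an index is `mean(apparent_b - test_b)` over
#' replicates, and the corrected estimate is
#' `apparent_original - optimism`, which holds as an exact identity in the
#' returned report. A resample containing a single class is redrawn (up to
#' 10 times, then the replicate is skipped and counted).
#'
#' @param m Probe-by-sample M-value matrix of the training data.
#' @param labels Binary response (1 = methylated), aligned with columns of
#'   `m`.
#' @param procedure Function `(m, labels) -> list(fit =, cutoff =)`
#'   implementing the whole pipeline on a training set; `fit` must be a
#'   `logit_fit` (its probes are looked up in `m` by ID). See
#'   [calibration_procedure()] for the standard pipeline.
#' @param indices Character subset of `c("accuracy", "kappa", "auc")`.
#' @param reps Number of bootstrap repetitions (default 200).
#' @param seed Integer seed; mandatory, the report is bit-reproducible
#'   given the seed.
#' @return A `bootstrap_report`: `reps`, `seed`, `skipped`, and a data
#'   frame `indices` with columns `index`, `apparent`, `mean_resample`,
#'   `optimism`, `corrected`.
#' @export
bootstrap_optimism <- function(m, labels,
                               procedure,
                               indices = c("accuracy", "kappa", "auc"),
                               reps = 200, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  indices <- match.arg(indices, several.ok = TRUE)
  labels <- as.numeric(labels)
  n <- ncol(m)
  if (length(labels) != n) stop("labels must align with columns of m",
                                call. = FALSE)
  set.seed(seed)

  eval_indices <- function(result, m_eval, y_eval) {
    p <- .fit_prob(result$fit, m_eval)
    calls <- p >= result$cutoff
    out <- c(accuracy = NA_real_, kappa = NA_real_, auc = NA_real_)
    cm <- confusion_metrics(calls, y_eval)
    out["accuracy"] <- cm$accuracy
    out["kappa"] <- cm$kappa
    out["auc"] <- roc_auc(p, y_eval)
    out[indices]
  }

  apparent <- eval_indices(procedure(m, labels), m, labels)
  boot_app <- boot_test <- matrix(NA_real_, nrow = reps,
                                  ncol = length(indices),
                                  dimnames = list(NULL, indices))
  skipped <- 0L
  for (b in seq_len(reps)) {
    idx <- NULL
    for (try in seq_len(10)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[cand])) == 2) { idx <- cand; break }
    }
    if (is.null(idx)) { skipped <- skipped + 1L; next }
    res_b <- suppressWarnings(
      procedure(m[, idx, drop = FALSE], labels[idx]))
    boot_app[b, ] <- eval_indices(res_b, m[, idx, drop = FALSE],
                                  labels[idx])
    boot_test[b, ] <- eval_indices(res_b, m, labels)
  }
  optimism <- colMeans(boot_app - boot_test, na.rm = TRUE)
  report <- data.frame(index = indices,
                       apparent = unname(apparent),
                       mean_resample = unname(colMeans(boot_app,
                                                       na.rm = TRUE)),
                       optimism = unname(optimism),
                       corrected = unname(apparent - optimism),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(reps = reps, seed = seed, skipped = skipped,
                 indices = report),
            class = "bootstrap_report")
}

# Probability of the positive class from a logit_fit on a probes-x-samples
# matrix (intercept-only fits give a constant probability).
.fit_prob <- function(fit, m) {
  if (length(fit$probe_ids)) {
    mm <- m[fit$probe_ids, , drop = FALSE]
    plogis(drop(fit$intercept +
                  crossprod(mm, fit$coefficients[fit$probe_ids])))
  } else {
    rep(plogis(fit$intercept), ncol(m))
  }
}

#' Standard calibration procedure for the bootstrap
#'
#' Returns a procedure function (for [bootstrap_optimism()]) that runs the
#' full pipeline on a training set: univariate Bonferroni screen, stepwise
#' AICc selection among the surviving probes (all candidates if none
#' survive the screen — the search then still starts from the intercept),
#' and cutoff optimization on the training probabilities. Wrapping the
#' entire selection inside the resampling loop is what prevents
#' selection-leakage optimism estimates that are too small.
#'
#' @param candidates Candidate probe IDs; default all rows of the matrix
#'   handed to the procedure.
#' @param alpha Screen significance level.
#' @param screen Logical; run the univariate screen before stepwise
#'   (default TRUE).
#' @return Function `(m, labels) -> list(fit, cutoff)`.
#' @export
calibration_procedure <- function(candidates = NULL, alpha = 0.05,
                                  screen = TRUE) {
  function(m, labels) {
    cand <- if (is.null(candidates)) rownames(m) else candidates
    if (screen) {
      sc <- univariate_screen(m[cand, , drop = FALSE], labels,
                              alpha = alpha)
      sel <- sc$probe_id[sc$selected]
      if (length(sel)) cand <- sel
    }
    fit <- stepwise_aicc(m, labels, candidates = cand)
    p <- .fit_prob(fit, m)
    cutoff <- if (length(unique(p)) == 1) 0.5
              else optimize_cutoff(p, labels)
    list(fit = fit, cutoff = cutoff)
  }
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("Optimism-corrected bootstrap:", x$reps, "repetitions, seed",
      x$seed, if (x$skipped) paste0("(", x$skipped, " skipped)"), "\n")
  print(x$indices, row.names = FALSE)
  invisible(x)
}
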