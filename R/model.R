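#' Construct a logistic methylation classifier
#'
#' A fixed logistic model mapping per-probe M-values to a methylation
#' probability: `logit(y) = intercept + sum(coefficients * M[probe_ids])`.
#' A sample is called `methylated` when its probability is greater than or
#' equal to `cutoff` (the boundary itself is on the methylated side; the
#' convention is recorded in the serialized model).
#'
#' @param probe_ids Character vector of predictor probe IDs (length k).
#' @param intercept Intercept on the logit scale.
#' @param coefficients Numeric vector of per-probe coefficients (length k).
#' @param covariance Optional (k+1)x(k+1) symmetric coefficient covariance
#'   matrix (intercept first); required for Wald confidence intervals.
#' @param cutoff Probability cutoff strictly inside (0, 1).
#' @param model_id Identifier stored with predictions.
#' @return An object of class `mgmt_logistic`.
#' @seealso [stp27_model()] for the shipped MGMT-STP27 constants.
#' @export
logistic_model <- function(probe_ids, intercept, coefficients,
                           covariance = NULL, cutoff = 0.5,
                           model_id = "custom") {
  probe_ids <- as.character(probe_ids)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(probe_ids))
    stop("one coefficient per probe required", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    k1 <- length(probe_ids) + 1L
    if (!identical(dim(covariance), c(k1, k1)))
      stop("covariance must be (k+1) x (k+1), intercept first",
           call. = FALSE)
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance must be symmetric", call. = FALSE)
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("covariance must be positive semi-definite", call. = FALSE)
  }
  structure(list(model_id = model_id, probe_ids = probe_ids,
                 intercept = as.numeric(intercept),
                 coefficients = setNames(coefficients, probe_ids),
                 covariance = covariance, cutoff = cutoff),
            class = "mgmt_logistic")
}

#' The MGMT-STP27 model
#'
#' Loads the shipped two-probe model:
#' `logit(y) = 4.3215 + 0.5271 * M(cg12434587) + 0.9265 * M(cg12981137)`
#' with probability cutoff 0.358 (the cutoff that maximised the sum of
#' sensitivity and specificity on the training cohort). The published
#' coefficient covariance is not part of the shipped constants, so
#' predictions from this object are point probabilities and calls without
#' confidence intervals; refit models from [calibrate_model()] carry a
#' covariance and do produce Wald intervals.
#'
#' @return An `mgmt_logistic` model.
#' @export
stp27_model <- function() {
  read_model(system.file("extdata", "stp27_model.json", package = "stp27",
                         mustWork = TRUE))
}

#' Read / write a model as JSON
#'
#' Serialization carries `model_id`, `probe_ids`, `intercept`,
#' `coefficients`, optional `covariance` (row-major), `cutoff`, and the
#' call-rule convention.
#'
#' @param path JSON file path.
#' @return `read_model`: an `mgmt_logistic` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covariance <- NULL
  if (!is.null(obj$covariance) && length(obj$covariance)) {
    k1 <- length(obj$probe_ids) + 1L
    covariance <- matrix(as.numeric(unlist(obj$covariance)), nrow = k1,
                         byrow = TRUE)
  }
  logistic_model(obj$probe_ids, obj$intercept, obj$coefficients,
                 covariance = covariance, cutoff = obj$cutoff,
                 model_id = obj$model_id)
}

#' @rdname read_model
#' @param model An `mgmt_logistic` object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mgmt_logistic"))
  obj <- list(model_id = model$model_id,
              probe_ids = model$probe_ids,
              intercept = model$intercept,
              coefficients = unname(model$coefficients),
              covariance = if (!is.null(model$covariance))
                as.numeric(t(model$covariance)),
              cutoff = model$cutoff,
              call_rule = "methylated iff probability >= cutoff")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Rows of the M matrix for the model probes, looked up by probe_id (never by
# position), as a k x n matrix. Errors when a probe row is absent.
.model_mrows <- function(model, m) {
  if (is.null(dim(m))) {
    if (is.null(names(m)))
      stop("per-probe M-values must be named by probe_id", call. = FALSE)
    m <- matrix(m, ncol = 1, dimnames = list(names(m), "sample_1"))
  }
  missing <- setdiff(model$probe_ids, rownames(m))
  if (length(missing))
    stop("M-value matrix lacks model probe(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m[model$probe_ids, , drop = FALSE]
}

#' Linear predictor of a logistic methylation model
#'
#' `intercept + sum(coefficients * M)` per sample on the logit scale.
#' Probes are looked up by ID; a missing probe is an error, never silently
#' imputed.
#'
#' @param model An `mgmt_logistic` model.
#' @param m Probe-by-sample M-value matrix (rownames = probe IDs), or a
#'   named numeric vector for one sample.
#' @return Numeric vector of logits, one per sample.
#' @export
linear_predictor <- function(model, m) {
  single <- is.null(dim(m))
  mm <- .model_mrows(model, m)
  out <- drop(model$intercept + crossprod(mm, model$coefficients))
  if (single) unname(out) else out
}

#' Methylation probability
#'
#' Inverse-logit of [linear_predictor()].
#'
#' @inheritParams linear_predictor
#' @return Probabilities in `(0, 1)`, one per sample.
#' @export
predict_probability <- function(model, m) {
  plogis(linear_predictor(model, m))
}

#' Wald confidence interval for the methylation probability
#'
#' Computes `logit +/- z * sqrt(x' V x)` with `x = (1, M)` and `V` the
#' coefficient covariance, then maps both ends through the inverse logit.
#' Requires a model with a covariance matrix.
#'
#' @inheritParams linear_predictor
#' @param level Confidence level (default 0.95).
#' @return Two-column matrix with `ci_low` and `ci_high`, one row per
#'   sample.
#' @export
wald_ci <- function(model, m, level = 0.95) {
  if (is.null(model$covariance))
    stop("model \"", model$model_id, "\" carries no coefficient ",
         "covariance; only point probabilities and calls are available. ",
         "Refit with calibrate_model() to obtain Wald intervals.",
         call. = FALSE)
  mm <- .model_mrows(model, m)
  x <- rbind(1, mm)                                   # (k+1) x n
  se <- sqrt(pmax(colSums(x * (model$covariance %*% x)), 0))
  z <- qnorm((1 + level) / 2)
  eta <- linear_predictor(model, m)
  cbind(ci_low = plogis(eta - z * se), ci_high = plogis(eta + z * se))
}

#' Classify samples with a logistic methylation model
#'
#' Computes the logit, probability, optional Wald interval and binary call
#' for every sample (column) of an M-value matrix. A sample with an `NA` at
#' a model probe receives `NA` outputs and a per-sample note instead of an
#' imputed value; a probe row missing from the matrix altogether is an
#' error.
#'
#' @param object An `mgmt_logistic` model.
#' @param m Probe-by-sample M-value matrix, or a named vector for a single
#'   sample.
#' @param level Confidence level for Wald intervals (used only when the
#'   model carries a covariance).
#' @param ... Unused.
#' @return Data frame with columns `sample_id`, `logit`, `probability`,
#'   `ci_low`, `ci_high`, `call`, `model_id` and `note` (NA when clean).
#' @export
predict.mgmt_logistic <- function(object, m, level = 0.95, ...) {
  mm <- .model_mrows(object, m)
  eta <- drop(object$intercept + crossprod(mm, object$coefficients))
  prob <- plogis(eta)
  ci <- if (!is.null(object$covariance)) wald_ci(object, mm, level)
        else cbind(ci_low = rep(NA_real_, ncol(mm)),
                   ci_high = rep(NA_real_, ncol(mm)))
  call <- ifelse(prob >= object$cutoff, "methylated", "unmethylated")
  note <- rep(NA_character_, ncol(mm))
  incomplete <- colSums(is.na(mm)) > 0
  note[incomplete] <- "missing M-value at a model probe; not classified"
  call[incomplete] <- NA_character_
  data.frame(sample_id = colnames(mm), logit = eta, probability = prob,
             ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
             call = call, model_id = object$model_id, note = note,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.mgmt_logistic <- function(x, ...) {
  cat("Logistic methylation classifier:", x$model_id, "\n")
  eq <- paste0(format(x$intercept), " + ",
               paste(paste0(format(x$coefficients), " * ", x$probe_ids),
                     collapse = " + "))
  cat("  logit(y) =", eq, "\n")
  cat("  cutoff   =", x$cutoff, "(methylated iff probability >= cutoff)\n")
  cat("  covariance:", if (is.null(x$covariance)) "absent (no Wald CIs)"
      else "present", "\n")
  invisible(x)
}
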