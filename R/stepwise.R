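#' Bidirectional stepwise logistic model selection under AICc
#'
#' Second step of the model construction: starting from the intercept-only
#' model, all single-probe additions and single-probe deletions are
#' evaluated at each step and the move with the lowest AICc is taken;
#' selection stops when no move improves the criterion by more than `1e-9`.
#' The procedure is deterministic: ties between moves are broken in favour
#' of the smaller model, then by lexicographic probe ID. Moves whose fit
#' would leave the AICc undefined (`n <= k + 1`) are not considered.
#' Separation warnings from candidate fits are muffled during the search
#' and re-checked on the returned fit.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param labels Binary response (1 = methylated), both classes present.
#' @param candidates Character vector of candidate probe IDs (normally the
#'   probes selected by [univariate_screen()]); defaults to all rows of
#'   `m`.
#' @return A `logit_fit` for the selected model, with attributes
#'   `selected_probes` (character vector, possibly empty) and `trace`
#'   (data frame of accepted moves with the AICc after each).
#' @export
stepwise_aicc <- function(m, labels, candidates = rownames(m)) {
  labels <- as.numeric(labels)
  candidates <- sort(unique(as.character(candidates)))
  unknown <- setdiff(candidates, rownames(m))
  if (length(unknown))
    stop("candidate probe(s) missing from matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  quiet_fit <- function(probes) {
    fit <- withCallingHandlers(
      if (length(probes)) .fit_probes(m, labels, probes)
      else .fit_null(labels),
      warning = function(w) {
        if (grepl("separation", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    fit
  }

  current <- character(0)
  current_fit <- quiet_fit(current)
  trace <- data.frame(step = 0L, move = "start", probe = NA_character_,
                      k = current_fit$k, aicc = current_fit$aicc,
                      stringsAsFactors = FALSE)
  if (!length(candidates)) {
    attr(current_fit, "selected_probes") <- character(0)
    attr(current_fit, "trace") <- trace
    attr(current_fit, "note") <- "empty candidate set: intercept-only model"
    return(current_fit)
  }

  step <- 0L
  repeat {
    step <- step + 1L
    adds <- setdiff(candidates, current)
    moves <- rbind(
      if (length(adds)) data.frame(move = "add", probe = adds,
                                   stringsAsFactors = FALSE),
      if (length(current)) data.frame(move = "drop", probe = current,
                                      stringsAsFactors = FALSE))
    if (is.null(moves) || !nrow(moves)) break
    cand <- vector("list", nrow(moves))
    for (i in seq_len(nrow(moves))) {
      probes <- if (moves$move[i] == "add") sort(c(current, moves$probe[i]))
                else setdiff(current, moves$probe[i])
      if (nrow(m) && ncol(m) <= length(probes) + 2) { cand[[i]] <- NULL; next }
      fit <- quiet_fit(probes)
      cand[[i]] <- list(fit = fit, probes = probes, move = moves$move[i],
                        probe = moves$probe[i])
    }
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) break
    a <- vapply(cand, function(ci) ci$fit$aicc, numeric(1))
    kk <- vapply(cand, function(ci) ci$fit$k, numeric(1))
    pid <- vapply(cand, function(ci) ci$probe, character(1))
    ord <- order(a, kk, pid)
    best <- cand[[ord[1]]]
    if (!(current_fit$aicc - best$fit$aicc > 1e-9)) break
    current <- best$probes
    current_fit <- best$fit
    trace <- rbind(trace, data.frame(step = step, move = best$move,
                                     probe = best$probe, k = best$fit$k,
                                     aicc = best$fit$aicc,
                                     stringsAsFactors = FALSE))
  }
  # refit outside the muffler so a separating final model still warns
  final <- if (length(current)) .fit_probes(m, labels, current)
           else .fit_null(labels)
  attr(final, "selected_probes") <- current
  attr(final, "trace") <- trace
  final
}
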