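# Survival analysis of methylation calls: Kaplan-Meier/log-rank and Cox
# proportional hazards (survival package; Efron handling of ties).

#' Two-group Kaplan-Meier curves and log-rank test
#'
#' @param time Nonnegative follow-up times (e.g. months).
#' @param event Event indicator (TRUE/1 = death observed).
#' @param group Two-level grouping (e.g. methylated vs unmethylated call).
#' @return A `survival_result` list: `groups`, `logrank_stat`,
#'   `logrank_p` (chi-squared, df = 1), `n_events`, and `km` (a
#'   `survfit` object for plotting).
#' @export
km_logrank <- function(time, event, group) {
  event <- as.numeric(as.logical(event))
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("exactly two non-empty groups required", call. = FALSE)
  if (sum(event) < 1)
    stop("no events observed; log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  structure(list(groups = levels(group),
                 logrank_stat = stat,
                 logrank_p = pchisq(stat, df = 1, lower.tail = FALSE),
                 n_events = sum(event),
                 km = survival::survfit(
                   survival::Surv(time, event) ~ group)),
            class = "survival_result")
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood estimation with Efron handling of ties. Returns the
#' hazard ratio with its Wald 95% confidence interval and the
#' likelihood-ratio-test p-value against the null model. A monotone
#' partial likelihood (e.g. all events in one group) is flagged with a
#' warning and the bounded last-iterate estimate is returned.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (TRUE/1 = event observed).
#' @param covariate Binary or numeric covariate (for a binary methylation
#'   call, code methylated as 1 so HR < 1 means better survival when
#'   methylated).
#' @param ties Tie-handling method passed to [survival::coxph()]
#'   (default `"efron"`; `"breslow"` makes the estimate exactly invariant
#'   to duplicating every subject).
#' @return A `survival_result` list: `hr`, `hr_ci` (95% Wald), `coef`,
#'   `se`, `cox_lrt_p`, `n_events`, `monotone` (likelihood flag).
#' @export
cox_fit <- function(time, event, covariate, ties = "efron") {
  event <- as.numeric(as.logical(event))
  if (sum(event) < 2) stop("need at least two events", call. = FALSE)
  x <- if (is.character(covariate) || is.factor(covariate))
    as.numeric(factor(covariate)) - 1 else as.numeric(covariate)
  if (length(unique(x)) < 2) {
    # constant covariate: no information, HR 1 by convention
    return(structure(list(hr = 1, hr_ci = c(low = NA_real_,
                                            high = NA_real_),
                          coef = 0, se = NA_real_, cox_lrt_p = 1,
                          n_events = sum(event), monotone = FALSE),
                     class = "survival_result"))
  }
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (monotone)
    warning("monotone partial likelihood; hazard ratio is a bounded ",
            "last-iterate estimate", call. = FALSE)
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  z <- qnorm(0.975)
  lrt_stat <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(hr = exp(beta),
                 hr_ci = c(low = exp(beta - z * se),
                           high = exp(beta + z * se)),
                 coef = beta, se = se,
                 cox_lrt_p = pchisq(max(lrt_stat, 0), df = 1,
                                    lower.tail = FALSE),
                 n_events = sum(event), monotone = monotone),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  if (!is.null(x$hr))
    cat(sprintf("Cox HR = %.3f [%.3f, %.3f], LRT p = %.4g (%d events)\n",
                x$hr, x$hr_ci[1], x$hr_ci[2], x$cox_lrt_p, x$n_events))
  if (!is.null(x$logrank_stat))
    cat(sprintf("Log-rank chi2 = %.3f, p = %.4g (%d events)\n",
                x$logrank_stat, x$logrank_p, x$n_events))
  invisible(x)
}
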