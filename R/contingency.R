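#' Monte-Carlo chi-squared test for a 2x2 table
#'
#' Pearson chi-squared statistic without continuity correction, with the
#' p-value estimated by simulating tables under the null of independence
#' with both margins fixed (multivariate hypergeometric sampling via
#' [stats::r2dtable()]), as appropriate when expected cell counts are
#' small: `p = (1 + #{simulated chi2 >= observed}) / (reps + 1)`.
#'
#' @param table 2x2 matrix of nonnegative integer counts; all row and
#'   column margins must be positive.
#' @param reps Number of simulated tables (default 9999).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param keep_tables Return the simulated tables (for diagnostics).
#' @return A `contingency_test` list: `table`, `chi2`, `p_mc`, `reps`,
#'   `seed`, and optionally `sim_tables`.
#' @export
mc_chisq <- function(table, reps = 9999, seed, keep_tables = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  tab <- as.matrix(table)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be nonnegative integers", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero margin", call. = FALSE)
  n <- sum(tab)
  chi2_of <- function(t) {
    e <- outer(rowSums(t), colSums(t)) / n
    sum((t - e)^2 / e)
  }
  chi2 <- chi2_of(tab)
  set.seed(seed)
  sims <- r2dtable(reps, rs, cs)
  sim_chi2 <- vapply(sims, chi2_of, numeric(1))
  p_mc <- (1 + sum(sim_chi2 >= chi2 - 1e-9)) / (reps + 1)
  out <- structure(list(table = tab, chi2 = chi2, p_mc = p_mc,
                        reps = reps, seed = seed),
                   class = "contingency_test")
  if (keep_tables) out$sim_tables <- sims
  out
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo chi-squared: chi2 = %.3f, p = %.4g (%d reps)\n",
              x$chi2, x$p_mc, x$reps))
  invisible(x)
}

#' Methylation frequency by stratum
#'
#' Counts and proportions of methylated calls per stratum (e.g. CIMP
#' status or tumor grade); empty strata are dropped. The two-stratum
#' output feeds [mc_chisq()] directly.
#'
#' @param calls Binary methylation calls (1/TRUE/"methylated").
#' @param stratum Stratifying variable, aligned with `calls`.
#' @return Data frame with `stratum`, `n_methylated`, `n`, `proportion`.
#' @export
frequency_table <- function(calls, stratum) {
  if (length(calls) != length(stratum))
    stop("calls and stratum must align", call. = FALSE)
  pos <- if (is.character(calls) || is.factor(calls))
    as.character(calls) == "methylated" else as.logical(calls)
  ok <- !is.na(pos) & !is.na(stratum)
  pos <- pos[ok]; stratum <- as.character(stratum[ok])
  levels <- unique(stratum)
  out <- data.frame(
    stratum = levels,
    n_methylated = vapply(levels, function(s) sum(pos[stratum == s]),
                          numeric(1)),
    n = vapply(levels, function(s) sum(stratum == s), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n > 0, , drop = FALSE]
  out$proportion <- out$n_methylated / out$n
  out
}
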