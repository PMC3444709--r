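#' Per-probe promoter association scan
#'
#' For every probe (rows ordered by genomic position) computes, where the
#' annotations allow: the univariate logistic LRT p-value of the probe
#' M-value against the binary MSP status, the univariate Cox LRT p-value of
#' the M-value against overall survival, and the Spearman and Pearson
#' correlations with gene expression. An annotation that is absent, has
#' fewer than three complete samples, or a constant probe, yields `NA`
#' fields for that probe — never a failure.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param cohort A `cohort_table` (needs `sample_id`; optionally
#'   `msp_status`, `os_time`/`os_event`, `expression`).
#' @param manifest A `probe_manifest` supplying probe positions.
#' @return Data frame with columns `probe_id`, `position`,
#'   `logistic_lrt_p`, `cox_lrt_p`, `spearman_expr`, `pearson_expr`,
#'   ordered by position.
#' @export
promoter_scan <- function(m, cohort, manifest) {
  common <- intersect(colnames(m), cohort$sample_id)
  if (length(common) < 3)
    stop("fewer than 3 samples shared between matrix and annotations",
         call. = FALSE)
  m <- m[, common, drop = FALSE]
  ann <- cohort[match(common, cohort$sample_id), , drop = FALSE]
  has <- function(col) col %in% names(ann)
  if (!has("msp_status") && !has("os_time") && !has("expression"))
    stop("cohort supplies none of msp_status, survival, expression",
         call. = FALSE)

  probes <- intersect(manifest$probe_id, rownames(m))
  pos <- manifest$position[match(probes, manifest$probe_id)]
  ord <- order(pos)
  probes <- probes[ord]; pos <- pos[ord]

  msp <- if (has("msp_status")) as.numeric(ann$msp_status == "methylated")
  expr <- if (has("expression")) ann$expression

  one_probe <- function(pid) {
    mv <- m[pid, ]
    row <- list(logistic_lrt_p = NA_real_, cox_lrt_p = NA_real_,
                spearman_expr = NA_real_, pearson_expr = NA_real_)
    if (!is.null(msp)) {
      ok <- complete.cases(mv, msp)
      if (sum(ok) >= 3 && length(unique(msp[ok])) == 2 &&
          sd(mv[ok]) > 0) {
        fit <- suppressWarnings(
          fit_logistic(cbind("(Intercept)" = 1, m = mv[ok]), msp[ok]))
        row$logistic_lrt_p <- lrt(fit, .fit_null(msp[ok]))$p
      }
    }
    if (has("os_time")) {
      ok <- complete.cases(mv, ann$os_time, ann$os_event)
      if (sum(ok) >= 3 && sum(ann$os_event[ok]) >= 2 && sd(mv[ok]) > 0)
        row$cox_lrt_p <- suppressWarnings(
          cox_fit(ann$os_time[ok], ann$os_event[ok], mv[ok])$cox_lrt_p)
    }
    if (!is.null(expr)) {
      ok <- complete.cases(mv, expr)
      if (sum(ok) >= 3 && sd(mv[ok]) > 0 && sd(expr[ok]) > 0) {
        row$spearman_expr <- cor(mv[ok], expr[ok], method = "spearman")
        row$pearson_expr <- cor(mv[ok], expr[ok], method = "pearson")
      }
    }
    row
  }
  rows <- lapply(probes, one_probe)
  data.frame(probe_id = probes, position = pos,
             logistic_lrt_p = vapply(rows, `[[`, 1, "logistic_lrt_p"),
             cox_lrt_p = vapply(rows, `[[`, 1, "cox_lrt_p"),
             spearman_expr = vapply(rows, `[[`, 1, "spearman_expr"),
             pearson_expr = vapply(rows, `[[`, 1, "pearson_expr"),
             row.names = NULL, stringsAsFactors = FALSE)
}
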