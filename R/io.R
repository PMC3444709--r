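# Delimited-text I/O for matrices, annotations and predictions.
# Dialect: tab-separated, probes in rows, samples in columns, first column
# "probe_id"; paired signals travel as two parallel files (*_unmeth.tsv for
# signal A, *_meth.tsv for signal B).

.read_num_matrix <- function(path, what = "matrix") {
  nf <- count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1)
    stop(what, " file has ragged rows: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop(what, " file needs a probe_id column plus >=1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(what, " file contains non-numeric entries", call. = FALSE)
  rownames(m) <- ids
  m
}

.write_num_matrix <- function(m, path, digits = 10) {
  df <- data.frame(probe_id = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation matrix
#'
#' Reads a probe-by-sample matrix of M-values, beta-values, or paired signal
#' intensities from tab-separated text. Probes are rows (first column
#' `probe_id`), samples are columns; row and column order is preserved as in
#' the file. Beta-values are range-checked into `[0, 1]`; signal intensities
#' may be negative (post background-correction) and are not clamped here —
#' clamping happens in [signals2m()].
#'
#' @param path For `kind = "signals"`, a character vector of two paths
#'   `c(unmeth, meth)` (signal A, then signal B); otherwise a single path.
#' @param kind One of `"mvalue"`, `"beta"`, `"signals"`.
#' @return For `"mvalue"` and `"beta"`, a numeric matrix with a `"kind"`
#'   attribute; for `"signals"`, a `signal_matrix` list with elements
#'   `signal_a` and `signal_b`.
#' @export
read_matrix <- function(path, kind = c("mvalue", "beta", "signals")) {
  kind <- match.arg(kind)
  if (kind == "signals") {
    if (length(path) != 2)
      stop("kind = \"signals\" needs two paths: c(unmeth, meth)",
           call. = FALSE)
    a <- .read_num_matrix(path[1], "signal")
    b <- .read_num_matrix(path[2], "signal")
    if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b)) ||
        !identical(colnames(a), colnames(b)))
      stop("signal files must share probe and sample ids in the same order",
           call. = FALSE)
    return(structure(list(signal_a = a, signal_b = b),
                     class = "signal_matrix"))
  }
  m <- .read_num_matrix(path, kind)
  if (kind == "beta" && any(m < 0 | m > 1, na.rm = TRUE))
    stop("beta-values outside [0, 1] in ", path, call. = FALSE)
  attr(m, "kind") <- kind
  m
}

#' Write a methylation matrix
#'
#' Writes a probe-by-sample numeric matrix as tab-separated text in the
#' dialect read by [read_matrix()]; values are written with 10 significant
#' digits so a write/read round-trip agrees within 1e-6.
#'
#' @param m Numeric matrix with probe IDs as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m))) stop("matrix needs probe ids as rownames",
                                 call. = FALSE)
  .write_num_matrix(m, path)
}

#' Select probes from a matrix
#'
#' Subsets a probe-by-sample matrix (or a `signal_matrix` pair) by explicit
#' probe IDs, by genomic window, or by platform membership, using a probe
#' manifest. The subset preserves manifest order regardless of the order of
#' the selector. An empty selection is an error, never a silent empty
#' matrix.
#'
#' @param m Matrix with probe IDs as rownames, or a `signal_matrix`.
#' @param manifest A `probe_manifest` from [read_manifest()].
#' @param ids Character vector of probe IDs (all must exist in the
#'   manifest).
#' @param window Numeric `c(start, end)` on chromosome `chromosome`
#'   (1-based, both ends inclusive).
#' @param chromosome Chromosome for `window` (default "10").
#' @param platform `"hm27"` or `"hm450"` to keep probes flagged on that
#'   platform.
#' @return Subset of `m`, rows in manifest order.
#' @export
select_probes <- function(m, manifest, ids = NULL, window = NULL,
                          chromosome = "10", platform = NULL) {
  if (!inherits(manifest, "probe_manifest"))
    stop("manifest must come from read_manifest()", call. = FALSE)
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(ids)) {
    unknown <- setdiff(ids, manifest$probe_id)
    if (length(unknown))
      stop("probe id(s) not in manifest: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    keep <- keep & manifest$probe_id %in% ids
  }
  if (!is.null(window)) {
    keep <- keep & .norm_chrom(manifest$chromosome) ==
      .norm_chrom(chromosome) &
      manifest$position >= window[1] & manifest$position <= window[2]
  }
  if (!is.null(platform)) {
    platform <- match.arg(platform, c("hm27", "hm450"))
    keep <- keep &
      if (platform == "hm27") manifest$on_hm27 else manifest$on_hm450
  }
  wanted <- manifest$probe_id[keep]
  rn <- if (inherits(m, "signal_matrix")) rownames(m$signal_a) else rownames(m)
  wanted <- wanted[wanted %in% rn]
  if (!length(wanted))
    stop("probe selection is empty", call. = FALSE)
  if (inherits(m, "signal_matrix")) {
    structure(list(signal_a = m$signal_a[wanted, , drop = FALSE],
                   signal_b = m$signal_b[wanted, , drop = FALSE]),
              class = "signal_matrix")
  } else {
    m[wanted, , drop = FALSE]
  }
}

#' Read a sample annotation table
#'
#' Reads per-sample annotations (MSP status, survival, treatment, grade,
#' CIMP call, expression) from tab-separated text. Only `sample_id` is
#' required; any other column may be missing or contain empty/NA entries,
#' which propagate as `NA` and are skipped per-analysis downstream.
#'
#' @param path Path to a tab-separated file with a `sample_id` column and
#'   any of: `msp_status` (`methylated`/`unmethylated`), `os_time` (months),
#'   `os_event` (0/1 or logical), `treatment`, `grade`
#'   (`II`, `III`, `IV`, `non_tumoral`), `cimp` (`pos`/`neg`),
#'   `expression`.
#' @return A `cohort_table` data frame.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df))
    stop("annotation file needs a sample_id column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotations", call. = FALSE)
  if ("os_event" %in% names(df)) df$os_event <- as.logical(df$os_event)
  if ("os_time" %in% names(df)) {
    df$os_time <- as.numeric(df$os_time)
    if (any(df$os_time < 0, na.rm = TRUE))
      stop("os_time must be nonnegative", call. = FALSE)
    if (any(!is.na(df$os_time) & is.na(df$os_event)))
      stop("os_event must be present wherever os_time is present",
           call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a sample annotation table
#' @param cohort A `cohort_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table
#'
#' Writes per-sample predictions as tab-separated text with columns
#' `sample_id`, `probability`, `ci_low`, `ci_high`, `call`, `model_id`.
#' Probabilities and interval bounds are written with six decimal places so
#' the table round-trips bit-identically at that precision.
#'
#' @param predictions Data frame as returned by
#'   [predict.mgmt_logistic()] (a `model_id` column is added if absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("sample_id", "probability", "ci_low", "ci_high", "call",
            "model_id")
  if (!"model_id" %in% names(predictions)) predictions$model_id <- NA
  for (col in c("ci_low", "ci_high"))
    if (!col %in% names(predictions)) predictions[[col]] <- NA_real_
  missing <- setdiff(cols, names(predictions))
  if (length(missing))
    stop("predictions lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- predictions$probability
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  bad <- !is.na(predictions$call) &
    !predictions$call %in% c("methylated", "unmethylated")
  if (any(bad)) stop("call must be methylated or unmethylated",
                     call. = FALSE)
  out <- predictions[, cols]
  fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  for (col in c("probability", "ci_low", "ci_high"))
    out[[col]] <- fmt6(out[[col]])
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing", call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path Input path.
#' @return Data frame with numeric probability/CI columns.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("probability", "ci_low", "ci_high"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
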