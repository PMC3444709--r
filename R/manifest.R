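# Genomic anchors (GRCh37 / genome build 37, 1-based, both ends inclusive).
# The promoter window is the CpG-island region around the MGMT transcription
# start site used for probe selection; the gene span is used only to tag
# gene-body probes in manifests.
.mgmt_promoter_window <- c(start = 131264700, end = 131266300)
.mgmt_gene_span <- c(start = 131265454, end = 131565783)

.norm_chrom <- function(chromosome) {
  sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
}

#' MGMT promoter window coordinates
#'
#' The CHR10 promoter-island window (genome build 37, 1-based, closed on both
#' ends) used to tag probes as `promoter_island` and to select promoter
#' probes by genomic window.
#'
#' @return Named numeric vector with elements `start` and `end`.
#' @export
mgmt_promoter_window <- function() .mgmt_promoter_window

#' Tag probes by genomic region
#'
#' Pure function of chromosome and position: `promoter_island` for chr10
#' positions inside the MGMT promoter window (both ends inclusive),
#' `gene_body` for chr10 positions elsewhere inside the MGMT gene span,
#' `other` otherwise.
#'
#' @param chromosome Character vector ("10" or "chr10" style accepted).
#' @param position Integer vector of 1-based build-37 coordinates.
#' @return Character vector of region tags.
#' @export
tag_region <- function(chromosome, position) {
  chrom <- .norm_chrom(chromosome)
  tag <- rep("other", length(position))
  on10 <- chrom == "10"
  tag[on10 & position >= .mgmt_promoter_window["start"] &
        position <= .mgmt_promoter_window["end"]] <- "promoter_island"
  body <- on10 & tag != "promoter_island" &
    position >= .mgmt_gene_span["start"] & position <= .mgmt_gene_span["end"]
  tag[body] <- "gene_body"
  tag
}

#' Read a probe manifest
#'
#' Reads a tab-separated probe manifest with columns `probe_id`,
#' `chromosome`, `position`, `on_hm27`, `on_hm450` and derives the
#' `region_tag` column via [tag_region()]. Probe IDs must be unique,
#' positions must be positive integers, and every probe flagged as present
#' on the HM-27K platform must also be flagged on the HM-450K (the 27K probe
#' set is a subset of the 450K content).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `probe_manifest` data frame (one row per probe) with the five
#'   input columns plus `region_tag`.
#' @seealso [bundled_manifest()] for the small manifest shipped with the
#'   package.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("probe_id", "chromosome", "position", "on_hm27", "on_hm450")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in manifest: ",
         df$probe_id[duplicated(df$probe_id)][1], call. = FALSE)
  pos <- suppressWarnings(as.numeric(df$position))
  if (any(is.na(pos)) || any(pos != round(pos)))
    stop("manifest positions must be integers", call. = FALSE)
  if (any(pos <= 0))
    stop("manifest positions must be positive", call. = FALSE)
  df$position <- as.integer(pos)
  for (col in c("on_hm27", "on_hm450")) {
    v <- df[[col]]
    if (is.character(v)) v <- toupper(trimws(v)) %in% c("TRUE", "T", "1", "YES")
    df[[col]] <- as.logical(v) %in% TRUE
  }
  if (any(df$on_hm27 & !df$on_hm450))
    stop("probes flagged on_hm27 must also be flagged on_hm450",
         call. = FALSE)
  df$chromosome <- as.character(df$chromosome)
  df$region_tag <- tag_region(df$chromosome, df$position)
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Bundled probe manifest
#'
#' Loads the small manifest shipped with the package. It contains the four
#' probes named by the MGMT-STP27 workflow (cg12434587, cg12981137,
#' cg02022136, cg23998405) plus synthetic filler probes, constructed so that
#' the promoter window holds 18 probes as on the full HM-450K array. Only
#' cg12434587 (131265519, Illumina annotation) and cg12981137 (131265575)
#' carry real coordinates; all other coordinates are synthetic placeholders
#' for testing, as the file name indicates. Full-array manifests are
#' user-supplied.
#'
#' @return A `probe_manifest` data frame.
#' @export
bundled_manifest <- function() {
  read_manifest(system.file("extdata", "mgmt_manifest_synthetic.tsv",
                            package = "stp27", mustWork = TRUE))
}
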