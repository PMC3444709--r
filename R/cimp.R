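#' CIMP clustering of a methylation cohort
#'
#' Unsupervised two-group classification into CpG island methylator
#' phenotype (CIMP) positive / negative: autosomal probes are ranked by
#' variance across samples, the `n_top` most variable are kept, each probe
#' is centered and scaled to unit variance, samples are clustered by Ward's
#' minimum-variance algorithm on Euclidean distances (the `ward.D2`
#' dialect, i.e. the variance update on squared Euclidean input), and the
#' tree is cut into `k` clusters. The cluster with the higher mean raw
#' methylation over the probes used is labelled CIMP-positive — a
#' deterministic stand-in for the visual identification used in practice.
#'
#' @param m Full-array probe-by-sample M-value matrix.
#' @param manifest A `probe_manifest`; probes on chromosomes X, Y or MT
#'   are excluded.
#' @param n_top Number of most-variable probes to keep (default 1000; if
#'   fewer autosomal probes are available, all are used with a warning).
#' @param k Number of clusters (default 2: CIMP+/-).
#' @return A `cimp_result` list: `assignments` (named character vector
#'   `"pos"`/`"neg"` per sample), `linkage_height_at_cut` (height of the
#'   merge undone by the cut), `n_probes_used`, `probe_ids_used`,
#'   `tree` (the `hclust` object).
#' @export
cimp_cluster <- function(m, manifest, n_top = 1000, k = 2) {
  n_top <- as.integer(n_top)
  chrom <- .norm_chrom(manifest$chromosome)
  autosomal <- manifest$probe_id[chrom %in% as.character(1:22)]
  probes <- intersect(rownames(m), autosomal)
  if (!length(probes)) stop("no autosomal probes in matrix", call. = FALSE)
  if (ncol(m) < 2 * k)
    stop("need at least ", 2 * k, " samples for k = ", k, call. = FALSE)
  if (length(probes) < n_top) {
    warning("only ", length(probes), " autosomal probes available; ",
            "using all of them", call. = FALSE)
    n_top <- length(probes)
  }
  sub <- m[probes, , drop = FALSE]
  v <- apply(sub, 1, var)
  ord <- order(-v, rownames(sub))          # deterministic under ties
  used <- rownames(sub)[ord[seq_len(n_top)]]
  z <- t(scale(t(sub[used, , drop = FALSE])))   # per-probe mean 0, sd 1
  z <- z[apply(z, 1, function(r) all(is.finite(r))), , drop = FALSE]
  tree <- hclust(dist(t(z)), method = "ward.D2")
  cl <- cutree(tree, k = k)
  mean_meth <- tapply(colMeans(sub[used, , drop = FALSE]), cl, mean)
  pos_cluster <- as.integer(names(which.max(mean_meth)))
  assignments <- ifelse(cl == pos_cluster, "pos", "neg")
  names(assignments) <- colnames(m)
  ns <- length(tree$height)
  structure(list(assignments = assignments,
                 linkage_height_at_cut = tree$height[ns - k + 2],
                 n_probes_used = n_top,
                 probe_ids_used = used,
                 tree = tree),
            class = "cimp_result")
}

#' @export
print.cimp_result <- function(x, ...) {
  cat("CIMP clustering on", x$n_probes_used, "most-variable autosomal",
      "probes (Ward / Euclidean)\n")
  print(table(x$assignments))
  invisible(x)
}
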