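#' Two-sample distribution comparison (Kolmogorov-Smirnov + QQ pairs)
#'
#' Two-sided two-sample Kolmogorov-Smirnov test
#' (`D = sup |F_x - F_y|`, asymptotic p-value) together with matched
#' empirical quantile pairs at the plotting positions of the smaller
#' sample, ready for a QQ-plot.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A `dist_comparison` list: `ks_d`, `ks_p`, and `qq_pairs` (a
#'   two-column matrix of matched quantiles).
#' @export
ks_compare <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must contain at least 2 values", call. = FALSE)
  kt <- suppressWarnings(ks.test(x, y))   # ties warning irrelevant to D
  probs <- ppoints(min(length(x), length(y)))
  qq <- cbind(x = unname(quantile(x, probs)),
              y = unname(quantile(y, probs)))
  structure(list(ks_d = unname(kt$statistic), ks_p = kt$p.value,
                 qq_pairs = qq),
            class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov: D = %.4f, p = %.4g\n", x$ks_d, x$ks_p))
  invisible(x)
}
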