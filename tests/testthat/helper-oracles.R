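# Shared fixtures and independent oracles.
# The glm-based helpers deliberately route through stats::glm.fit so that
# stepwise/fit checks compare the package's own IRLS against an
# independent implementation.

# AICc of a logistic fit computed from glm.fit's deviance.
glm_aicc <- function(X, y) {
  g <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  k <- ncol(X)
  n <- nrow(X)
  g$deviance + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Global AICc minimum over every subset of candidate probes (exhaustive
# enumeration; independent of stepwise_aicc).
exhaustive_aicc_min <- function(m, y, candidates = rownames(m)) {
  p <- length(candidates)
  tm <- t(m[candidates, , drop = FALSE])
  best <- Inf
  best_set <- character(0)
  for (mask in 0:(2^p - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(p) - 1)) > 0
    X <- cbind(1, tm[, sel, drop = FALSE])
    a <- glm_aicc(X, y)
    if (a < best) { best <- a; best_set <- candidates[sel] }
  }
  list(aicc = best, set = best_set)
}

# AICc of every single-move neighbour (add or drop one candidate) of a set.
neighbour_aiccs <- function(m, y, set, candidates = rownames(m)) {
  moves <- c(lapply(setdiff(candidates, set), function(p) union(set, p)),
             lapply(set, function(p) setdiff(set, p)))
  vapply(moves, function(s) {
    X <- cbind(1, t(m[s, , drop = FALSE]))
    if (length(s) == 0) X <- matrix(1, ncol(m), 1)
    glm_aicc(X, y)
  }, numeric(1))
}

# Probe-by-sample matrix of pure-noise probes.
noise_matrix <- function(n_probes, n_samples, mean = 0, sd = 1) {
  matrix(rnorm(n_probes * n_samples, mean, sd), nrow = n_probes,
         dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                         sprintf("s%04d", seq_len(n_samples))))
}

# Default-condition synthetic training cohort, returning the pieces the
# calibration tests need.
training_cohort <- function(n, seed, ...) {
  co <- simulate_cohort(simulation_config(n_samples = n, seed = seed, ...))
  list(m = co$m_truth,
       labels = as.numeric(co$cohort$msp_status == "methylated"),
       truth = as.numeric(co$latent_state),
       cohort = co$cohort,
       co = co)
}

# Tiny manifest file writer for I/O tests.
write_manifest_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
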