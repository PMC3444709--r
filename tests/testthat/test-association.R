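test_that("log-rank test is null on duplicated groups and powered at a
           strong hazard ratio", {
  t0 <- c(3, 6, 9, 12, 18, 24)
  e0 <- c(1, 1, 0, 1, 1, 0)
  km <- km_logrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 6))
  expect_equal(km$logrank_stat, 0, tolerance = 1e-10)
  expect_equal(km$logrank_p, 1, tolerance = 1e-10)

  expect_error(km_logrank(t0, rep(0, 6), rep(c("a", "b"), 3)),
               "no events")
  expect_error(km_logrank(t0, e0, rep("a", 6)), "two non-empty groups")

  set.seed(101)
  power <- replicate(60, {
    s <- simulate_survival(rep(c(1, 0), each = 300), hr = 0.28,
                           baseline = 0.046, censoring_rate = 0.2)
    km_logrank(s$time, s$event, rep(c("m", "u"), each = 300))$logrank_p <
      0.001
  })
  expect_gte(mean(power), 0.95)
})

test_that("Cox fits handle constants, duplication and monotone
           likelihoods", {
  t0 <- c(3, 6, 9, 12, 18, 24, 30, 36)
  e0 <- c(1, 1, 1, 0, 1, 1, 0, 1)

  const <- cox_fit(t0, e0, rep(1, 8))
  expect_equal(const$hr, 1)
  expect_equal(const$cox_lrt_p, 1)

  # Breslow ties: duplicating every subject leaves the estimate unchanged
  # (score contributions double but the estimating equation's root does not)
  x <- c(0, 1, 0, 1, 0, 1, 0, 1)
  f1 <- cox_fit(t0, e0, x, ties = "breslow")
  f2 <- cox_fit(c(t0, t0), c(e0, e0), c(x, x), ties = "breslow")
  expect_equal(f1$hr, f2$hr, tolerance = 1e-6)
  # Efron remains the default for analysis fits
  expect_true(is.finite(cox_fit(t0, e0, x)$hr))

  # all events in one arm: monotone likelihood flagged, estimate bounded
  expect_warning(
    mono <- cox_fit(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                    c(1, 1, 1, 0, 0, 0)),
    "monotone")
  expect_true(mono$monotone)
  expect_true(is.finite(mono$hr))
})

test_that("log-rank and Cox LRT p-values agree for a binary covariate", {
  set.seed(103)
  s <- simulate_survival(rep(c(1, 0), each = 250), hr = 0.6,
                         baseline = 0.046, censoring_rate = 0.2)
  g <- rep(c(1, 0), each = 250)
  p_lr <- km_logrank(s$time, s$event, g)$logrank_p
  p_cox <- cox_fit(s$time, s$event, g)$cox_lrt_p
  expect_lt(abs(p_lr - p_cox), 0.01)
})

test_that("promoter scan attributes signal to the informative probes", {
  set.seed(107)
  hit <- replicate(30, {
    tr <- training_cohort(100, seed = sample.int(1e6, 1))
    mani <- bundled_manifest()
    # noise probes are not in the bundled manifest; add them
    extra <- data.frame(probe_id = grep("noise", rownames(tr$m),
                                        value = TRUE),
                        chromosome = "10",
                        position = 131264700 + 1:9,
                        on_hm27 = FALSE, on_hm450 = TRUE,
                        region_tag = "promoter_island")
    mani <- structure(rbind(as.data.frame(mani), extra),
                      class = class(mani))
    scan <- promoter_scan(tr$m, tr$cohort, mani)
    bonf <- 0.05 / nrow(tr$m)
    inf <- scan$probe_id %in% c("cg12434587", "cg12981137")
    all(scan$logistic_lrt_p[inf] < bonf) &&
      all(scan$logistic_lrt_p[!inf] > bonf)
  })
  expect_gte(mean(hit), 0.9)

  # expression anticorrelates with methylation at the first model probe
  tr <- training_cohort(60, seed = 109)
  mani <- bundled_manifest()
  scan <- promoter_scan(tr$m, tr$cohort, mani)
  expect_lt(scan$spearman_expr[scan$probe_id == "cg12434587"], -0.4)
  expect_true(all(diff(scan$position) >= 0))

  # a constant probe yields absent fields, not an error
  m2 <- tr$m
  m2["cg12981137", ] <- 0
  scan2 <- promoter_scan(m2, tr$cohort, mani)
  expect_true(is.na(
    scan2$logistic_lrt_p[scan2$probe_id == "cg12981137"]))
  expect_true(is.na(scan2$pearson_expr[scan2$probe_id == "cg12981137"]))

  # annotations lacking survival produce NA columns, not failures
  scan3 <- promoter_scan(tr$m, tr$cohort[, c("sample_id", "msp_status")],
                         mani)
  expect_true(all(is.na(scan3$cox_lrt_p)))
  expect_false(anyNA(scan3$logistic_lrt_p[
    scan3$probe_id %in% c("cg12434587", "cg12981137")]))
})

test_that("CIMP clustering recovers planted sample blocks", {
  set.seed(113)
  n_probes <- 1500; n <- 60
  shift <- c(rep(2, 30), rep(0, 30))
  m <- matrix(rnorm(n_probes * n), n_probes, n) +
    matrix(shift, n_probes, n, byrow = TRUE)
  rownames(m) <- sprintf("cg%05d", seq_len(n_probes))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  mani <- structure(data.frame(probe_id = rownames(m),
                               chromosome = rep(as.character(1:22),
                                                length.out = n_probes),
                               position = seq_len(n_probes),
                               on_hm27 = FALSE, on_hm450 = TRUE,
                               region_tag = "other"),
                    class = c("probe_manifest", "data.frame"))
  res <- cimp_cluster(m, mani, n_top = 1000, k = 2)
  expect_identical(unname(res$assignments),
                   rep(c("pos", "neg"), each = 30))
  expect_identical(res$n_probes_used, 1000L)
  expect_gt(res$linkage_height_at_cut, 0)

  # invariance to probe and sample permutations (labels content-based)
  perm <- sample(n)
  res2 <- cimp_cluster(m[sample(n_probes), perm], mani)
  expect_identical(res2$assignments[colnames(m)], res$assignments)

  # determinism on rerun
  res3 <- cimp_cluster(m, mani)
  expect_identical(res3$assignments, res$assignments)

  # non-autosomal probes are excluded; short panels warn and use all
  mani_xy <- mani
  mani_xy$chromosome[1:600] <- "X"
  expect_warning(res4 <- cimp_cluster(m, mani_xy, n_top = 1000),
                 "using all")
  expect_identical(res4$n_probes_used, 900L)
})

test_that("Monte-Carlo chi-squared reproduces printed contingency
           results", {
  t1 <- mc_chisq(rbind(c(15, 5), c(105, 116)), reps = 9999, seed = 1)
  expect_equal(t1$chi2, 5.543, tolerance = 1e-3)
  expect_lt(abs(t1$p_mc - 0.023), 0.01)

  t2 <- mc_chisq(rbind(c(10, 10), c(10, 10)), reps = 999, seed = 1)
  expect_equal(t2$chi2, 0)
  expect_equal(t2$p_mc, 1)

  # near-degenerate table: the MC estimate must agree with the exact
  # conditional p from full enumeration of margin-fixed tables
  obs <- rbind(c(32, 0), c(15, 5))
  chi2_of <- function(t) {
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - e)^2 / e)
  }
  b <- 0:5    # col-2 count in row 1 indexes every margin-fixed table
  chi2_all <- vapply(b, function(i)
    chi2_of(rbind(c(32 - i, i), c(15 + i, 5 - i))), numeric(1))
  p_exact <- sum(dhyper(b, 5, 47, 32)[chi2_all >= chi2_of(obs) - 1e-9])
  t3 <- mc_chisq(obs, reps = 9999, seed = 1)
  expect_lt(abs(t3$p_mc - p_exact), 0.005)

  expect_error(mc_chisq(rbind(c(0, 0), c(5, 5)), seed = 1), "margin")
  expect_error(mc_chisq(rbind(c(1.5, 2), c(3, 4)), seed = 1), "integers")

  # determinism
  expect_identical(mc_chisq(t1$table, reps = 999, seed = 9)$p_mc,
                   mc_chisq(t1$table, reps = 999, seed = 9)$p_mc)
})

test_that("simulated tables keep both margins fixed, and the MC p is
           consistent with exact enumeration and asymptotics", {
  tab <- rbind(c(3, 7), c(9, 2))
  res <- mc_chisq(tab, reps = 2000, seed = 5, keep_tables = TRUE)
  expect_true(all(vapply(res$sim_tables, function(t)
    identical(rowSums(t), rowSums(tab)) &&
      identical(colSums(t), colSums(tab)), logical(1))))

  # tiny table: exact enumeration over margin-fixed tables gives p = 1
  tiny <- mc_chisq(rbind(c(2, 1), c(1, 2)), reps = 9999, seed = 3)
  expect_gt(tiny$p_mc, 0.98)

  # large counts: MC p approaches the analytic chi-squared tail
  big <- rbind(c(150, 50), c(1050, 1160))
  res_big <- mc_chisq(big, reps = 99999, seed = 7)
  p_asym <- stats::chisq.test(big, correct = FALSE)$p.value
  expect_lt(abs(res_big$p_mc - p_asym), 0.005)
})

test_that("KS comparison behaves at the extremes and under the null", {
  x <- c(1.2, 3.4, 2.2, 0.1, 5.5)
  same <- ks_compare(x, x)
  expect_equal(same$ks_d, 0)
  expect_equal(same$ks_p, 1)

  disj <- ks_compare(runif(30, 0, 0.1), runif(40, 5, 5.1))
  expect_equal(disj$ks_d, 1)
  expect_equal(nrow(disj$qq_pairs), 30)

  # D is invariant under a strictly increasing transform of both samples
  set.seed(127)
  a <- rnorm(80); b <- rnorm(90, 0.5)
  expect_equal(ks_compare(a, b)$ks_d,
               ks_compare(exp(a), exp(b))$ks_d)

  reject <- replicate(1000, {
    ks_compare(rnorm(200), rnorm(200))$ks_p < 0.05
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)

  expect_error(ks_compare(numeric(0), a), "at least 2")
})

test_that("frequency tables stratify calls and drop empty strata", {
  calls <- rep(c("methylated", "unmethylated"), c(120, 121))
  ft <- frequency_table(calls, rep("TCGA", 241))
  expect_equal(ft$proportion, 120 / 241, tolerance = 1e-12)
  expect_equal(sprintf("%.0f%%", 100 * ft$proportion), "50%")

  ft2 <- frequency_table(c(1, 1, 0, NA), c("a", "a", "b", NA))
  expect_identical(ft2$stratum, c("a", "b"))
  expect_equal(ft2$n, c(2, 1))
})
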