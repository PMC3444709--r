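test_that("IRLS logistic fit reaches the closed-form solutions", {
  # uninformative, balanced pairing: fitted probabilities all 0.5
  X <- cbind(1, x = c(1, 1, 0, 0))
  y <- c(1, 0, 1, 0)
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_equal(fit$loglik, 4 * log(0.5), tolerance = 1e-8)
  null <- fit_logistic(matrix(1, 4, 1), y)
  expect_equal(lrt(fit, null)$stat, 0, tolerance = 1e-8)

  # intercept-only: the prevalence logit
  fit31 <- fit_logistic(matrix(1, 4, 1), c(1, 1, 1, 0))
  expect_equal(unname(fit31$coefficients[1]), log(3), tolerance = 1e-6)
})

test_that("IRLS agrees with glm on estimates and covariance", {
  set.seed(11)
  n <- 150
  X <- cbind("(Intercept)" = 1, a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + X[, 2] - 0.7 * X[, 3]))
  fit <- fit_logistic(X, y)
  g <- glm(y ~ X[, 2] + X[, 3], family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(fit$covariance), unname(vcov(g)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("perfect separation is flagged, not fatal", {
  X <- cbind(1, x = c(2, 1.9, -2, -2.1))
  y <- c(1, 1, 0, 0)
  expect_warning(fit <- fit_logistic(X, y), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("LRT statistic is chi-squared calibrated under the null", {
  set.seed(23)
  n <- 200
  reject <- replicate(2000, {
    y <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    fit <- suppressWarnings(fit_logistic(cbind(1, x), y))
    null <- fit_logistic(matrix(1, n, 1), y)
    lrt(fit, null)$p < 0.05
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)

  # identical models: zero statistic, p = 1
  y <- rbinom(50, 1, 0.5)
  f <- fit_logistic(matrix(1, 50, 1), y)
  expect_equal(lrt(f, f), list(stat = 0, df = 0L, p = 1))
})

test_that("AICc follows the small-sample formula and its limits", {
  fit <- fit_logistic(matrix(1, 4, 1), c(1, 0, 1, 0))
  expect_equal(aicc(fit), -2 * 4 * log(0.5) + 2 + 2)   # 9.5452

  # converges to AIC as n grows with the fit held fixed
  big <- structure(list(loglik = -2.772589, k = 3L, n = 1e8),
                   class = "logit_fit")
  expect_equal(aicc(big), -2 * big$loglik + 2 * 3, tolerance = 1e-6)

  # a parameter with zero likelihood gain strictly raises AICc
  small <- structure(list(loglik = -10, k = 2L, n = 50),
                     class = "logit_fit")
  bigger <- structure(list(loglik = -10, k = 3L, n = 50),
                      class = "logit_fit")
  expect_gt(aicc(bigger), aicc(small))

  tiny <- structure(list(loglik = -1, k = 3L, n = 4), class = "logit_fit")
  expect_error(aicc(tiny), "undefined")
})

test_that("univariate screen keeps informative probes and controls noise", {
  set.seed(31)
  hits <- replicate(60, {
    n <- 300
    state <- rbinom(n, 1, 0.5)
    m <- rbind(
      inf1 = ifelse(state == 1, 0, -4) + rnorm(n),
      inf2 = ifelse(state == 1, 0, -4) + rnorm(n),
      noise_matrix(9, n))
    colnames(m) <- paste0("s", 1:n)
    sc <- univariate_screen(m, state)
    setequal(sc$probe_id[sc$selected], c("inf1", "inf2"))
  })
  expect_gte(mean(hits), 0.90)

  # single candidate: Bonferroni is the identity
  set.seed(32)
  m1 <- noise_matrix(1, 100)
  sc1 <- univariate_screen(m1, rbinom(100, 1, 0.5))
  expect_identical(sc1$p_bonferroni, sc1$p)
})

test_that("stepwise AICc matches the exhaustive oracle on small panels", {
  set.seed(41)
  n_match <- 0L
  reps <- 25
  for (r in seq_len(reps)) {
    tr <- training_cohort(300, seed = 500 + r, n_noise_probes = 6)
    fit <- suppressWarnings(stepwise_aicc(tr$m, tr$labels))
    oracle <- exhaustive_aicc_min(tr$m, tr$labels)
    if (fit$aicc <= oracle$aicc + 1e-6) n_match <- n_match + 1L
    # strict single-move local optimum, every replicate
    nb <- neighbour_aiccs(tr$m, tr$labels, attr(fit, "selected_probes"))
    expect_true(all(nb >= fit$aicc - 1e-6))
  }
  expect_gte(n_match / reps, 0.9)
})

test_that("screen-then-stepwise recovers exactly the informative probes", {
  # overlap regime: with full 5-sigma separation a single probe can carry
  # the whole likelihood, and parsimony correctly stops at one probe
  set.seed(43)
  exact <- replicate(40, {
    tr <- training_cohort(300, seed = sample.int(1e6, 1),
                          mean_unmeth = -2.5)
    sc <- univariate_screen(tr$m, tr$labels)
    fit <- suppressWarnings(
      stepwise_aicc(tr$m, tr$labels,
                    candidates = sc$probe_id[sc$selected]))
    setequal(attr(fit, "selected_probes"),
             c("cg12434587", "cg12981137"))
  })
  expect_gte(mean(exact), 0.9)
})

test_that("stepwise prefers the null model when candidates are noise", {
  set.seed(47)
  kept <- replicate(80, {
    m <- noise_matrix(2, 300)
    y <- rbinom(300, 1, 0.5)
    fit <- suppressWarnings(stepwise_aicc(m, y))
    length(attr(fit, "selected_probes"))
  })
  expect_gt(mean(kept == 0), 0.5)

  # a single strong candidate is always taken and beats the null AICc
  tr <- training_cohort(200, seed = 99)
  fit1 <- stepwise_aicc(tr$m, tr$labels, candidates = "cg12434587")
  expect_identical(attr(fit1, "selected_probes"), "cg12434587")
  expect_lt(fit1$aicc, aicc(fit_logistic(matrix(1, 200, 1), tr$labels)))

  # empty candidate set falls back to intercept-only with a note
  fit0 <- stepwise_aicc(tr$m, tr$labels, candidates = character(0))
  expect_length(attr(fit0, "selected_probes"), 0)
  expect_match(attr(fit0, "note"), "intercept-only")
})

test_that("VIF diagnoses collinearity quantitatively", {
  set.seed(53)
  X <- cbind(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  v <- vif(X)
  expect_true(all(v < 1.2))
  expect_false(attr(v, "flag"))

  dup <- cbind(X, d = X[, "a"])
  vd <- vif(dup)
  expect_true(is.infinite(vd["a"]) && is.infinite(vd["d"]))
  expect_true(attr(vd, "flag"))

  x1 <- rnorm(10000)
  x2 <- x1 + rnorm(10000, sd = 0.1)
  vc <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(vc["x1"]), 101, tolerance = 0.2)
})

test_that("cutoff optimization maximizes sensitivity + specificity", {
  expect_equal(optimize_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)

  # perfectly anti-ordered: ties at the extremes, smallest cutoff wins
  expect_equal(optimize_cutoff(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)

  expect_warning(ct <- optimize_cutoff(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)),
                 "degenerate")
  expect_equal(ct, 0)

  # rank invariance: classification identical under increasing transforms
  set.seed(61)
  p <- runif(60); y <- rbinom(60, 1, p)
  c1 <- optimize_cutoff(p, y)
  c2 <- optimize_cutoff(qlogis(p), y)
  expect_identical(p >= c1, qlogis(p) >= c2)
})

test_that("confusion metrics reproduce the worked glioblastoma table", {
  # TP = 31, FN = 1, FP = 4, TN = 32 (n = 68)
  calls <- rep(c(TRUE, FALSE, TRUE, FALSE), c(31, 1, 4, 32))
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(31, 1, 4, 32))
  cm <- confusion_metrics(calls, truth, cutoff = 0.358)
  # printed at three decimals: agree to within half a unit in the last place
  expect_lt(abs(cm$sensitivity - 0.969), 5e-4)
  expect_lt(abs(cm$specificity - 0.889), 5e-4)
  expect_lt(abs(cm$accuracy - 0.926), 5e-4)
  expect_lt(abs(cm$kappa - 0.853), 5e-4)

  # perfect balanced agreement
  expect_equal(confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$kappa, 1)

  # chance-level agreement with identical marginals
  cc <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 25)
  yy <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 25)
  expect_equal(confusion_metrics(cc, yy)$kappa, 0)
})

test_that("confusion metrics satisfy accounting identities", {
  set.seed(67)
  for (r in 1:20) {
    n <- 80
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    calls <- rbinom(n, 1, 0.5)
    cm <- confusion_metrics(calls, y)
    prev <- mean(y)
    expect_equal(cm$accuracy,
                 prev * cm$sensitivity + (1 - prev) * cm$specificity)
    # kappa is symmetric in the two raters
    if (length(unique(calls)) == 2)
      expect_equal(cm$kappa, confusion_metrics(y, calls)$kappa)
  }
})

test_that("AUC matches the pairwise concordance definition and pROC", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)

  set.seed(71)
  p <- runif(100); y <- rbinom(100, 1, p)
  expect_equal(roc_auc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("bootstrap optimism is null for data-ignoring classifiers", {
  tr <- training_cohort(100, seed = 77)
  constant <- function(m, labels) {
    list(fit = structure(list(probe_ids = character(0), intercept = 0.85,
                              coefficients = c("(Intercept)" = 0.85)),
                         class = "logit_fit"),
         cutoff = 0.5)
  }
  rep <- bootstrap_optimism(tr$m, tr$labels, constant, reps = 60,
                            seed = 4242)
  idx <- rep$indices
  expect_equal(idx$optimism[idx$index == "kappa"], 0)
  expect_equal(idx$optimism[idx$index == "auc"], 0)
  expect_lt(abs(idx$optimism[idx$index == "accuracy"]), 0.03)
  # corrected = apparent - optimism holds exactly
  expect_identical(idx$corrected, idx$apparent - idx$optimism)
})

test_that("bootstrap reports are bit-reproducible given the seed", {
  tr <- training_cohort(80, seed = 79)
  proc <- calibration_procedure(screen = FALSE)
  r1 <- suppressWarnings(bootstrap_optimism(tr$m, tr$labels, proc,
                                            reps = 25, seed = 7))
  r2 <- suppressWarnings(bootstrap_optimism(tr$m, tr$labels, proc,
                                            reps = 25, seed = 7))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(bootstrap_optimism(tr$m, tr$labels, proc,
                                            reps = 25, seed = 8))
  expect_false(identical(r1$indices, r3$indices))
})

test_that("the full calibration pipeline assembles a usable model", {
  tr <- training_cohort(300, seed = 83)
  cal <- suppressWarnings(calibrate_model(tr$m, tr$labels,
                                          model_id = "refit"))
  expect_s3_class(cal$model, "mgmt_logistic")
  expect_true(all(c("cg12434587", "cg12981137") %in%
                    cal$model$probe_ids))
  expect_gt(cal$performance$auc, 0.95)
  expect_false(is.null(cal$model$covariance))
  # the calibrated model produces Wald intervals bracketing the estimate
  pred <- predict(cal$model, tr$m)
  ok <- !is.na(pred$ci_low)
  expect_true(all(pred$ci_low[ok] <= pred$probability[ok] &
                    pred$probability[ok] <= pred$ci_high[ok]))
})
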