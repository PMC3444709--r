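---
title: "Methods: the MGMT-STP27 classifier and its calibration workflow"
author: "stp27 package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MGMT-STP27 classifier and its calibration workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stp27)
```

## The model

*MGMT* promoter methylation silences a DNA-repair gene whose activity blunts
alkylating-agent chemotherapy; its status is therefore a treatment-relevant
biomarker in glioblastoma. The MGMT-STP27 classifier estimates the
probability that a tumor would be scored methylated by the reference assay
(methylation-specific PCR, MSP) from two Infinium array probes that sit in
the promoter CpG island on chromosome 10 (window 131,264,700–131,266,300,
genome build 37, both ends inclusive):

$$\mathrm{logit}(y) = 4.3215 + 0.5271\,M_{cg12434587} +
  0.9265\,M_{cg12981137}$$

Methylation is summarised on the M-value scale,
$M = \log_2\!\big((\max(B,0)+1)/(\max(A,0)+1)\big)$, where $A$ and $B$ are
the unmethylated- and methylated-channel intensities. The clamp at zero
admits negative background-corrected intensities; the $+1$ offsets keep the
ratio finite. Beta-values convert through $M = \log_2(\beta/(1-\beta))$
after clipping $\beta$ into $[10^{-6}, 1-10^{-6}]$ — the clip bounds
$|M|$ at about 19.9, far outside the biological range, so the distortion is
negligible at array precision.

A sample is called **methylated** when $y \ge 0.358$. Whether the original
cutoff was applied with $\ge$ or $>$ is not documented anywhere we know of;
this package fixes $\ge$ (so the cutoff value itself classifies as
methylated) and records the convention inside the serialized model JSON.
The shipped model object carries **no coefficient covariance** — the
published covariance is not part of the printed constants — so its
predictions are point probabilities and calls. Models refit with
`calibrate_model()` carry the observed-information covariance and produce
Wald 95% intervals on the probability scale:
$\mathrm{logit}(y) \pm z_{0.975}\sqrt{x^\top V x}$ with $x = (1, M)$,
mapped through the inverse logit. We never fabricate uncertainty for the
shipped constants.

Missing M-values at a model probe abort classification *for that sample*
with a per-sample note; a two-probe model has no redundancy to impute from.
Probe lookup is always by ID, never by row position.

## The calibration procedure

`calibrate_model()` reproduces the two-step construction used to build such
classifiers:

1. **Univariate screen.** Every candidate probe is tested alone against
   the binary MSP labels by the likelihood-ratio test (intercept + probe vs
   intercept-only), with Bonferroni correction. The family size is the
   number of candidate probes supplied — the source workflow does not state
   its family explicitly, so we make it exactly the candidate set and keep
   `alpha` (default 0.05) configurable.
2. **Stepwise AICc.** Bidirectional stepwise logistic selection starting
   from the intercept-only model: at each step all single additions and
   single deletions are evaluated and the move with the lowest
   $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ (with $k$ counting the
   intercept) is taken; the search stops when no move improves the
   criterion by more than $10^{-9}$. Ties break toward the smaller model,
   then lexicographically by probe ID, making the procedure deterministic.
   Moves whose AICc would be undefined ($n \le k+1$) are never considered.
   The tests verify against exhaustive enumeration of all candidate subsets
   that this greedy search attains the global AICc minimum in the large
   majority of simulated cohorts and a strict single-move local optimum in
   all of them.
3. **Collinearity check.** Variance inflation factors,
   $\mathrm{VIF}_j = 1/(1-R^2_j)$, flag the fit when any exceeds 5. Probes
   driven by a common latent methylation state are strongly collinear even
   when their noise is only moderately correlated, which is why larger
   probe panels get rejected; the threshold 5 is this package's convention
   (the usual rule-of-thumb range is 5–10).
4. **Cutoff optimization.** Candidate cutoffs are the midpoints of adjacent
   sorted unique fitted probabilities plus the endpoints 0 and 1; the
   returned cutoff maximizes sensitivity + specificity, with ties broken
   toward the smallest cutoff (clinically conservative: favours calling
   methylated). The candidate grid depends only on ranks, so any strictly
   increasing transform of the scores yields the same classification.

**Logistic fitting** is by Newton–Raphson/IRLS with step-halving,
convergence declared when the maximum absolute score drops below $10^{-8}$
(at most 100 iterations), and covariance taken as the inverse observed
information. Complete or quasi-complete separation — fitted probabilities
pinned within $10^{-8}$ of 0 or 1 — is flagged with a warning rather than
an error, and the last-iterate coefficients are returned, so screening
loops survive degenerate probes. Unit tests pin coefficients, covariance
and log-likelihood against `stats::glm` as an independent implementation.

**Internal validation** uses the optimism bootstrap: the *entire* pipeline
(selection and cutoff choice included) is re-run on each of `reps`
(default 200) resamples drawn with replacement; each index (accuracy,
kappa, AUC) is evaluated on the resample and on the original data, optimism
is the mean difference, and the corrected index is
`apparent - optimism` — an identity that holds exactly in the report.
Re-running the whole selection inside the loop is what prevents the
leakage that makes naive bootstrap validation too optimistic. A resample
containing a single class is redrawn up to 10 times, then skipped and
counted. Two details worth knowing:

* For a classifier that ignores the data, the optimism is *exactly* zero
  only for kappa (single-class calls give kappa 0 on any dataset) and AUC
  (all-tied scores give 0.5); for accuracy it is zero only in expectation,
  because resample prevalence fluctuates.
* Detecting overfitting requires a scenario where apparent performance can
  exceed the truth: with the generator's default 5-sigma class separation,
  apparent accuracy is often exactly 1 on both resample and original data
  and optimism degenerates to 0. The overfitting checks therefore use an
  overlapping regime (unmethylated mean M of −2.5, about 10% Bayes error),
  where the pipeline genuinely overfits and the corrected accuracy falls
  below the apparent one in essentially every meta-replicate.

## Association analyses

* **Survival.** Kaplan–Meier curves and the two-group log-rank test via
  the survival package; univariate Cox proportional-hazards fits with
  Efron tie handling (default), hazard ratio with Wald 95% interval and a
  likelihood-ratio p-value. Monotone partial likelihoods (all events in
  one arm) are flagged and the bounded last-iterate estimate returned. One
  nuance: duplicating every subject leaves the Cox estimate exactly
  unchanged under Breslow ties (score contributions double, the root does
  not) but *not* under Efron, whose within-tie correction changes; the
  `ties` argument exposes both, and the invariance test uses Breslow.
* **Promoter scan.** Per probe, ordered by genomic position: univariate
  logistic LRT p against MSP status, univariate Cox LRT p of the M-value
  against overall survival, and Spearman/Pearson correlations with gene
  expression. Any annotation that is absent, has fewer than three complete
  samples, or meets a constant probe yields `NA` fields, never a failure.
* **CIMP clustering.** The CpG island methylator phenotype is identified
  by unsupervised clustering: autosomal probes only, ranked by variance
  (not sd or MAD — a documented choice, the source says only "most
  variable"), top 1000 kept, each probe centered and scaled, Euclidean
  distances between samples, Ward minimum-variance linkage in the
  `ward.D2` dialect (the variance-update on *squared* Euclidean input —
  the two historical Ward variants differ, so the dialect is pinned), tree
  cut at $k = 2$. The cluster with the higher mean raw methylation over
  the probes used is labelled CIMP-positive: a deterministic replacement
  for the visual identification used in practice.
* **Contingency tests.** For 2×2 tables with small expected counts,
  `mc_chisq()` computes the Pearson chi-squared statistic without
  continuity correction and estimates the p-value by simulating tables
  with *both margins fixed* (multivariate hypergeometric draws via
  `stats::r2dtable`), with
  $p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(reps+1)$. This
  conditional p-value can differ visibly from the asymptotic tail on
  near-degenerate tables: for `[[32,0],[15,5]]` full enumeration gives an
  exact conditional p of 0.005965 (and 0.006661 for `[[48,1],[15,5]]`),
  both above their asymptotic tails (0.0029, 0.0021), because the observed
  table's own hypergeometric mass counts toward the tail. The unit tests
  check the Monte-Carlo estimate against these enumeration values, and the
  test suite verifies on every simulated draw that the margins are
  preserved and that the MC p converges to the asymptotic tail on a
  large-count table.
* **Distribution comparison.** Two-sample Kolmogorov–Smirnov test plus
  matched empirical quantile pairs at the plotting positions of the
  smaller sample, for QQ-plots across cohorts and platforms.

## The synthetic-cohort generator

`simulate_cohort()` draws cohorts with known ground truth so that every
operation above is testable offline. What it emulates, with defaults and
rationale:

| parameter | default | rationale |
|---|---|---|
| `prevalence_methylated` | 0.5 | glioblastoma training cohorts are roughly balanced (about half methylated) |
| `mean_meth`, `mean_unmeth`, `sd` | 0, −5, 1 | clear bimodal state-conditional M-values, mirroring the separation visible in fitted-probability plots; documented as defaults, not as measured facts |
| `inter_probe_corr` | 0.5 | residual correlation between the two island probes beyond the shared state |
| `n_noise_probes` | 9 | gives the 11-probe candidate panel the selection steps expect |
| `msp_flip_rate` | 0.02 | MSP is imperfect; a small label-noise rate keeps kappa below 1 |
| `prop_grade23`, `grade_shift` | 0, +1 | grade II/III gliomas show elevated M-values (two methylated gene copies rather than one methylated plus one lost); modelled as a scalar shift on all probes |
| `cimp_given_meth`, `cimp_given_unmeth` | 0.97, 0.05 | in grade II/III cohorts nearly all CIMP-positive tumors are methylated; supplying CIMP parameters for a pure-glioblastoma cohort is a config error |
| `hr_methylated`, `baseline_hazard` | 0.277, 0.046/month | the protective hazard ratio of methylation under temozolomide, on a baseline giving a median survival of about 15 months |
| `censoring_rate` | 0.2 | independent exponential censoring tuned to the target fraction |
| `expression_slope`, `expression_sd` | −2, 1 | methylation silences expression: negative coupling to the first model probe |
| `total_intensity` | 5000 | plausible summed per-probe intensity for the signal representation |

Signals are derived from M-values by the exact inversion
$A + 1 = (s+2)/(1+2^M)$, $B + 1 = 2^M (A+1)$, so
`signals2m(signal_a, signal_b)` reproduces `m_truth` to machine precision
(continuous intensities are legitimate post-background-correction values;
integer rounding would break the round-trip guarantee the tests rely on).
Everything is a deterministic function of the config, including the seed.

What the generator does **not** emulate — and hence what passing tests do
not certify about real arrays: Infinium type-I/type-II probe-chemistry
differences, batch and normalization effects, copy-number-driven intensity
changes beyond the scalar grade shift, administrative (non-exponential)
censoring, and spatial correlation along the CpG island beyond the single
inter-probe correlation. Tests passing on these cohorts demonstrate that
the algorithms are implemented correctly, not that the shipped constants
are optimal for any particular real cohort.

## Numerical conventions and degenerate inputs

* Genomic coordinates are 1-based with closed windows on both ends.
* Beta clipping constant $10^{-6}$; IRLS gradient tolerance $10^{-8}$,
  at most 100 iterations, step-halving to keep the likelihood monotone.
* Stepwise improvement threshold $10^{-9}$; ties by smaller $k$, then
  probe ID.
* Cutoff grid: midpoints plus $\{0, 1\}$; ties toward the smallest cutoff.
* All-identical probabilities make the cutoff degenerate at 0 with a
  warning; constant covariates give VIF $+\infty$ with a flag; constant
  Cox covariates return HR 1 with LRT p 1; empty strata are dropped from
  frequency tables with a note; zero-margin contingency tables error.
* Every stochastic routine (`mc_chisq`, `bootstrap_optimism`,
  `simulate_*`) takes a mandatory seed and is bit-reproducible given it.

A note on stepwise selection under pure noise: with a single handful of
noise candidates the AICc penalty dominates and the intercept-only model
wins most of the time, but with 11 noise candidates the chance that *some*
probe clears the roughly-2-unit AICc bar is already
$1-(1-0.15)^{11} \approx 0.84$ — stepwise selection without a preceding
screen is not a multiplicity control, which is exactly why the workflow
screens first.

## Problem sizes used in the checks

The shipped test-suite scenarios were sized to be decisive yet quick:
screening and selection properties at $n = 300$ with an 11-probe panel
(exhaustive-oracle comparisons over all $2^{11}$ subsets across 100
cohorts), parameter recovery at $n = 2000$ over 100 replicates, hazard
recovery at $n = 2000$ over 100 replicates with 2000 null calibration
replicates, overfitting detection at $n = 60$ with 50 meta-replicates of an
80-replicate bootstrap, and CIMP block recovery at 1500 probes × 60
samples. These are the package's chosen verification sizes; all thresholds
were fixed from the binomial/chi-squared arithmetic before the simulations
were run.

## Known limitations

* The shipped model cannot produce confidence intervals (no published
  covariance); refit models can.
* The classifier is calibrated for glioblastoma-like signal levels; in
  grade II/III cohorts the grade-dependent M-value elevation shifts
  probabilities upward, which inflates positive calls relative to other
  assays — visible here as the generator's `grade_shift`, and a caveat for
  applying the fixed constants across grades.
* The margin-fixed Monte-Carlo p-value is conditional; on near-degenerate
  tables it is intrinsically larger than the asymptotic tail (see the
  enumeration values above), so "p below x" statements can differ between
  the two conventions.
* No IDAT parsing, array normalization, or genome-build liftover: inputs
  are assumed normalized and on build 37.
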