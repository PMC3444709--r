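# Synthetic Infinium-like cohorts with known ground truth. The generator
# emulates the features the classifier workflow depends on: a latent
# methylation state with bimodal state-conditional M-values at two
# informative probes, state-independent noise probes, MSP label noise, a
# grade-dependent M-value elevation, a latent CIMP state in grade II/III
# cohorts, and exponential survival with a specified hazard ratio for
# methylated tumors.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults describe a glioblastoma-like training cohort: a clear bimodal
#' separation of the two informative probes (state-conditional M means 0
#' for methylated vs -5 for unmethylated, sd 1, correlation 0.5 between
#' the probes), a small MSP mislabelling rate, and survival with hazard
#' ratio 0.277 for methylated tumors under a baseline hazard of
#' 0.046/month (median around 15 months) with 20% independent exponential
#' censoring.
#'
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed; mandatory, the whole cohort is a
#'   deterministic function of the config.
#' @param prevalence_methylated P(latent methylated), in (0, 1).
#' @param mean_meth,mean_unmeth,sd State-conditional M-value mean
#'   (methylated / unmethylated) and sd of the informative probes.
#' @param inter_probe_corr Correlation of the two informative probes given
#'   the state, in \[-1, 1\].
#' @param informative_probes IDs of the two informative probes (defaults
#'   to the MGMT-STP27 probes so the shipped model applies directly).
#' @param n_noise_probes Number of state-independent noise probes.
#' @param noise_mean,noise_sd M-value distribution of the noise probes.
#' @param msp_flip_rate Probability that the observed MSP label flips the
#'   latent state, in \[0, 1).
#' @param prop_grade23 Proportion of grade II/III samples (0 gives a pure
#'   glioblastoma cohort).
#' @param grade_shift M-value shift added to all probes of grade II/III
#'   samples (copy-number-driven signal elevation; > 0).
#' @param cimp_given_meth P(CIMP+ given methylated) for grade II/III
#'   samples; only meaningful when `prop_grade23 > 0` (supplying it for a
#'   glioblastoma-only cohort is a config error). Defaults to 0.97 in
#'   grade II/III mode.
#' @param cimp_given_unmeth P(CIMP+ given unmethylated) for grade II/III
#'   samples (default 0.05).
#' @param hr_methylated Hazard ratio of methylated vs unmethylated
#'   (> 0, default 0.277).
#' @param baseline_hazard Event hazard of unmethylated samples, per month
#'   (> 0).
#' @param censoring_rate Target fraction censored, in \[0, 1).
#' @param expression_slope,expression_sd Expression is generated as
#'   `slope * M(first informative probe) + N(0, sd)` (negative slope:
#'   methylation silences expression).
#' @param total_intensity Total per-probe intensity used to derive the
#'   signal-pair representation.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples, seed,
                              prevalence_methylated = 0.5,
                              mean_meth = 0, mean_unmeth = -5, sd = 1,
                              inter_probe_corr = 0.5,
                              informative_probes = c("cg12434587",
                                                     "cg12981137"),
                              n_noise_probes = 9,
                              noise_mean = -2.5, noise_sd = 1.5,
                              msp_flip_rate = 0.02,
                              prop_grade23 = 0, grade_shift = 1,
                              cimp_given_meth = NULL,
                              cimp_given_unmeth = 0.05,
                              hr_methylated = 0.277,
                              baseline_hazard = 0.046,
                              censoring_rate = 0.2,
                              expression_slope = -2, expression_sd = 1,
                              total_intensity = 5000) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  chk01 <- function(x, name, open = TRUE) {
    if (x < 0 || x > 1 || (open && (x == 0 || x == 1)))
      stop(name, " out of range", call. = FALSE)
  }
  chk01(prevalence_methylated, "prevalence_methylated")
  if (msp_flip_rate < 0 || msp_flip_rate >= 1)
    stop("msp_flip_rate must be in [0, 1)", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  if (abs(inter_probe_corr) > 1)
    stop("inter_probe_corr must be in [-1, 1]", call. = FALSE)
  if (sd <= 0 || noise_sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (hr_methylated <= 0) stop("hr_methylated must be > 0", call. = FALSE)
  if (baseline_hazard <= 0)
    stop("baseline_hazard must be > 0", call. = FALSE)
  if (prop_grade23 < 0 || prop_grade23 > 1)
    stop("prop_grade23 out of range", call. = FALSE)
  if (prop_grade23 == 0 && !is.null(cimp_given_meth))
    stop("cimp_given_meth is meaningless in a glioblastoma-only cohort ",
         "(prop_grade23 = 0)", call. = FALSE)
  if (prop_grade23 > 0 && is.null(cimp_given_meth))
    cimp_given_meth <- 0.97
  if (length(informative_probes) != 2)
    stop("exactly two informative probes are modelled", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 prevalence_methylated = prevalence_methylated,
                 mean_meth = mean_meth, mean_unmeth = mean_unmeth, sd = sd,
                 inter_probe_corr = inter_probe_corr,
                 informative_probes = informative_probes,
                 n_noise_probes = as.integer(n_noise_probes),
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 msp_flip_rate = msp_flip_rate,
                 prop_grade23 = prop_grade23, grade_shift = grade_shift,
                 cimp_given_meth = cimp_given_meth,
                 cimp_given_unmeth = cimp_given_unmeth,
                 hr_methylated = hr_methylated,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 expression_slope = expression_slope,
                 expression_sd = expression_sd,
                 total_intensity = total_intensity),
            class = "simulation_config")
}

#' Simulate survival times
#'
#' Exponential event times with hazard `baseline * hr^state` (state 1 =
#' methylated) and independent exponential censoring whose hazard is tuned
#' so the expected censored fraction approximates `censoring_rate`.
#'
#' @param states Binary vector (1 = methylated).
#' @param hr Hazard ratio for methylated samples (> 0).
#' @param baseline Baseline event hazard (> 0).
#' @param censoring_rate Target censored fraction in \[0, 1); 0 means no
#'   censoring.
#' @param seed Optional integer seed (omit to draw from the current RNG
#'   stream).
#' @return List with `time` (observed follow-up) and `event` (logical,
#'   TRUE = event observed).
#' @export
simulate_survival <- function(states, hr, baseline, censoring_rate = 0,
                              seed = NULL) {
  if (baseline <= 0) stop("baseline hazard must be > 0", call. = FALSE)
  if (hr <= 0) stop("hr must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  states <- as.numeric(states)
  n <- length(states)
  hazard <- baseline * ifelse(states == 1, hr, 1)
  t_event <- rexp(n, rate = hazard)
  if (censoring_rate > 0) {
    hbar <- baseline * mean(ifelse(states == 1, hr, 1))
    hc <- hbar * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n, rate = hc)
  } else {
    t_cens <- rep(Inf, n)
  }
  list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

# Exact signal-pair representation of an M-value: with u = B + 1 and
# t = A + 1, requiring u / t = 2^M and A + B = s gives
# t = (s + 2) / (1 + 2^M), so signals2m() recovers M exactly.
.m_to_signals <- function(m, s) {
  r <- 2^m
  t <- (s + 2) / (1 + r)
  a <- t - 1
  b <- r * t - 1
  if (any(a < 0) || any(b < 0))
    stop("M-value outside the representable range for total intensity ",
         s, call. = FALSE)
  list(signal_a = a, signal_b = b)
}

#' Simulate a synthetic Infinium-like cohort
#'
#' Draws a full cohort from a [simulation_config()]: latent methylation
#' state, state-conditional bivariate-normal M-values at the two
#' informative probes, state-independent noise probes, grade assignment
#' with an M-value shift for grade II/III samples, noisy MSP labels, a
#' latent CIMP state (grade II/III mode only), MGMT expression negatively
#' coupled to promoter methylation, survival times, and an exact
#' signal-pair representation of every M-value (so
#' `signals2m(signal_a, signal_b)` reproduces `m_truth` to machine
#' precision).
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_cohort` list: `signals` (a `signal_matrix`),
#'   `m_truth` (probe-by-sample matrix), `cohort` (a `cohort_table` with
#'   `msp_status`, `os_time`, `os_event`, `grade`, `cimp`, `expression`),
#'   `latent_state` (logical, the ground truth), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples
  sample_ids <- sprintf("s%04d", seq_len(n))

  latent <- rbinom(n, 1, cf$prevalence_methylated) == 1

  # grades: grade II/III split evenly, remainder glioblastoma (IV)
  n23 <- round(cf$prop_grade23 * n)
  grade <- rep("IV", n)
  if (n23 > 0) {
    idx23 <- sample.int(n, n23)
    grade[idx23] <- rep(c("II", "III"), length.out = n23)
  }
  is23 <- grade != "IV"

  # informative probes: state-conditional bivariate normal
  mu <- ifelse(latent, cf$mean_meth, cf$mean_unmeth)
  z1 <- rnorm(n)
  z2 <- cf$inter_probe_corr * z1 +
    sqrt(1 - cf$inter_probe_corr^2) * rnorm(n)
  m1 <- mu + cf$sd * z1
  m2 <- mu + cf$sd * z2

  noise <- if (cf$n_noise_probes > 0)
    matrix(rnorm(cf$n_noise_probes * n, cf$noise_mean, cf$noise_sd),
           nrow = cf$n_noise_probes,
           dimnames = list(sprintf("noise%02d", seq_len(cf$n_noise_probes)),
                           sample_ids))
  m_truth <- rbind(matrix(c(m1, m2), nrow = 2, byrow = TRUE,
                          dimnames = list(cf$informative_probes,
                                          sample_ids)),
                   noise)
  m_truth[, is23] <- m_truth[, is23, drop = FALSE] + cf$grade_shift

  msp <- xor(latent, runif(n) < cf$msp_flip_rate)

  cimp <- rep(NA_character_, n)
  if (any(is23)) {
    p_pos <- ifelse(latent[is23], cf$cimp_given_meth, cf$cimp_given_unmeth)
    cimp[is23] <- ifelse(runif(sum(is23)) < p_pos, "pos", "neg")
  }

  expression <- cf$expression_slope * m_truth[cf$informative_probes[1], ] +
    rnorm(n, 0, cf$expression_sd)

  surv <- simulate_survival(latent, cf$hr_methylated, cf$baseline_hazard,
                            cf$censoring_rate)

  sig <- .m_to_signals(m_truth, cf$total_intensity)
  signals <- structure(list(signal_a = sig$signal_a,
                            signal_b = sig$signal_b),
                       class = "signal_matrix")

  cohort <- data.frame(
    sample_id = sample_ids,
    msp_status = ifelse(msp, "methylated", "unmethylated"),
    os_time = surv$time, os_event = surv$event,
    treatment = NA_character_, grade = grade, cimp = cimp,
    expression = unname(expression),
    row.names = NULL, stringsAsFactors = FALSE)
  class(cohort) <- c("cohort_table", "data.frame")

  structure(list(signals = signals, m_truth = m_truth, cohort = cohort,
                 latent_state = setNames(latent, sample_ids),
                 config = cf),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to files
#'
#' Emits `<prefix>_unmeth.tsv` / `<prefix>_meth.tsv` (signal A / B),
#' `<prefix>_mvalues.tsv`, `<prefix>_annotations.tsv` and
#' `<prefix>_truth.tsv` (latent state) in the dialects read by
#' [read_matrix()] and [read_annotations()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_prefix Path prefix for the output files.
#' @return Named character vector of the written paths, invisibly.
#' @export
cohort_to_files <- function(cohort, out_prefix) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paths <- c(unmeth = paste0(out_prefix, "_unmeth.tsv"),
             meth = paste0(out_prefix, "_meth.tsv"),
             mvalues = paste0(out_prefix, "_mvalues.tsv"),
             annotations = paste0(out_prefix, "_annotations.tsv"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_matrix(cohort$signals$signal_a, paths["unmeth"])
  write_matrix(cohort$signals$signal_b, paths["meth"])
  write_matrix(cohort$m_truth, paths["mvalues"])
  write_annotations(cohort$cohort, paths["annotations"])
  write.table(data.frame(sample_id = names(cohort$latent_state),
                         latent_methylated = as.integer(
                           cohort$latent_state)),
              paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
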