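# Synthetic cohorts: an NHANES-like clinical table with age-trending
# biomarkers and Gompertz event times, plus methylation studies with a
# planted linear clock signal. Everything is seeded and reproducible, so the
# training pipeline and the validation statistics can be exercised without
# any restricted cohort download.

# Fixed generator constants: marginal mean at age 60, per-year linear trend
# and residual SD for each named biomarker. CRP is generated on the log
# scale (lognormal marginal). Dispersion is population-representative (a
# national survey including chronic disease, not a healthy reference range):
# e.g. glucose spread covers diabetics, creatinine covers renal impairment.
# Biomarkers are independent by default.
biomarker_generator_config <- function() {
  data.frame(
    variable = c("albumin", "creatinine", "glucose", "lncrp", "lymphocyte_pct",
                 "mcv", "rdw", "alp", "wbc"),
    mean60 = c(42, 80, 5.8, log(0.25), 30, 90, 13.2, 75, 7.0),
    trend = c(-0.06, 0.30, 0.020, 0.012, -0.10, 0.06, 0.025, 0.20, 0.012),
    sd = c(3.2, 25, 2.0, 1.1, 9, 5.5, 1.3, 26, 2.1),
    stringsAsFactors = FALSE
  )
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label, so
# sub-generators draw from effectively independent streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2017L + h * 7919L
}

#' Specification of a synthetic clinical cohort
#'
#' @param n_subjects Number of subjects, at least 1.
#' @param seed Integer master seed.
#' @param age_range Length-2 numeric, years (low < high).
#' @param n_biomarkers_total Total candidate biomarkers; the 9 named panel
#'   markers plus `n_biomarkers_total - 9` pure-noise nuisance markers.
#' @param true_weights Named per-unit log-hazard weights defining the true
#'   linear predictor; defaults to the published panel weights
#'   ([phenoage_weights()]), all nuisance markers weight 0. The name `crp`
#'   applies to ln(CRP).
#' @param gompertz_gamma Gompertz slope per month, positive.
#' @param gompertz_intercept Model intercept; if `NULL`, calibrated so that
#'   a 60-year-old with mean biomarkers has a 10% 120-month mortality risk.
#' @param followup_months Administrative censoring time, months.
#' @param aging_cause_prob Probability an event is labelled aging-related.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1L, age_range = c(30, 90),
                        n_biomarkers_total = 42,
                        true_weights = phenoage_weights(),
                        gompertz_gamma = 0.0077,
                        gompertz_intercept = NULL,
                        followup_months = 276,
                        aging_cause_prob = 0.63) {
  if (n_subjects < 1) stop("`n_subjects` must be at least 1", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("`age_range` must be (low, high) with low < high", call. = FALSE)
  if (gompertz_gamma <= 0) stop("`gompertz_gamma` must be positive", call. = FALSE)
  if (aging_cause_prob < 0 || aging_cause_prob > 1)
    stop("`aging_cause_prob` must lie in [0, 1]", call. = FALSE)
  if (length(true_weights) == 0L)
    stop("`true_weights` must not be empty", call. = FALSE)
  if (n_biomarkers_total < 9) stop("need at least the 9 named biomarkers", call. = FALSE)
  if (is.null(gompertz_intercept))
    gompertz_intercept <- calibrate_intercept(true_weights, gompertz_gamma)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 age_range = age_range,
                 n_biomarkers_total = as.integer(n_biomarkers_total),
                 true_weights = true_weights,
                 gompertz_gamma = gompertz_gamma,
                 gompertz_intercept = gompertz_intercept,
                 followup_months = followup_months,
                 aging_cause_prob = aging_cause_prob),
            class = "cohort_spec")
}

# Intercept such that the reference subject (age 60, all biomarkers at their
# generator means) has `target_risk` mortality risk by `horizon` months.
calibrate_intercept <- function(true_weights, gamma, target_risk = 0.10,
                                horizon = 120, ref_age = 60) {
  cfg <- biomarker_generator_config()
  means <- stats::setNames(cfg$mean60, cfg$variable)
  names(means)[names(means) == "lncrp"] <- "crp" # weight applies to ln(CRP)
  means <- c(means, age = ref_age)
  common <- intersect(names(true_weights), names(means))
  xb_ref <- sum(true_weights[common] * means[common])
  log(-log1p(-target_risk) * gamma / expm1(gamma * horizon)) - xb_ref
}

#' Generate a synthetic clinical cohort
#'
#' Ages are uniform on the spec's range; each named biomarker is normal with
#' a fixed linear age trend; nuisance markers are age-independent standard
#' normals. The true linear predictor `xb` drives Gompertz event times drawn
#' by inverse-CDF, administratively censored at the follow-up horizon, and
#' events are labelled aging-related with the spec's probability.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `clinical_cohort` with columns `id`, `age`,
#'   the 9 named biomarkers (CRP on the raw scale), nuisance markers
#'   `nuis01...`, `time` (months), `event` (0/1), `cause`
#'   (`"aging-related"`/`"other"`/`NA` for censored) and the hidden truth
#'   `true_xb`.
#' @export
generate_clinical_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "clinical"))
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  cfg <- biomarker_generator_config()
  biom <- list()
  for (i in seq_len(nrow(cfg))) {
    v <- cfg$variable[i]
    x <- stats::rnorm(n, cfg$mean60[i] + cfg$trend[i] * (age - 60), cfg$sd[i])
    if (v == "lncrp") {
      biom[["crp"]] <- exp(x)
    } else if (v == "lymphocyte_pct") {
      biom[[v]] <- pmin(pmax(x, 1), 99)
    } else {
      biom[[v]] <- pmax(x, 0.01 * cfg$mean60[i]) # keep concentrations positive
    }
  }
  n_nuis <- spec$n_biomarkers_total - 9L
  nuis <- matrix(stats::rnorm(n * n_nuis), n, n_nuis,
                 dimnames = list(NULL, sprintf("nuis%02d", seq_len(n_nuis))))
  cohort <- data.frame(id = sprintf("s%05d", seq_len(n)), age = age,
                       biom, nuis, check.names = FALSE,
                       stringsAsFactors = FALSE)
  # truth: weights apply to ln(CRP), everything else raw
  xb <- rep(spec$gompertz_intercept, n)
  for (v in names(spec$true_weights)) {
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    if (v == "crp") x <- log(x)
    xb <- xb + spec$true_weights[[v]] * x
  }
  tt <- rgompertz_time(n, xb, spec$gompertz_gamma)
  event <- as.integer(tt <= spec$followup_months)
  cohort$time <- pmin(tt, spec$followup_months)
  cohort$event <- event
  cause <- rep(NA_character_, n)
  aging <- stats::runif(n) < spec$aging_cause_prob
  cause[event == 1] <- ifelse(aging[event == 1], "aging-related", "other")
  cohort$cause <- cause
  cohort$true_xb <- xb
  class(cohort) <- c("clinical_cohort", "data.frame")
  attr(cohort, "spec") <- spec
  cohort
}

#' Specification of a synthetic methylome
#'
#' @param n_cpgs Total CpGs.
#' @param n_signal_cpgs CpGs whose betas track phenotypic age (at most
#'   `n_cpgs`).
#' @param noise_sd Residual SD of betas, beta units (default 0.02).
#' @param seed Integer seed.
#' @return An object of class `methylome_spec`.
#' @export
methylome_spec <- function(n_cpgs = 2000, n_signal_cpgs = 50,
                           noise_sd = 0.02, seed = 1L) {
  if (n_signal_cpgs > n_cpgs)
    stop("`n_signal_cpgs` must not exceed `n_cpgs`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(n_cpgs = as.integer(n_cpgs),
                 n_signal_cpgs = as.integer(n_signal_cpgs),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "methylome_spec")
}

#' Generate a methylation study with planted clock signal
#'
#' Signal CpG betas are `clip(b0_j + slope_j * z + noise, 0, 1)` where `z`
#' is the standardized phenotypic age; the remaining CpGs are
#' age-independent noise around a fixed baseline. The true inverting clock
#' (weights `sd(phenoage) / (slope_j * k)` over the k signal CpGs, intercept
#' chosen so the clock reproduces phenotypic age exactly in the noise-free
#' unclipped construction) is retained as ground truth.
#'
#' @param cohort A `clinical_cohort` (supplies sample ids, ages, survival).
#' @param phenoages Phenotypic age in years, one per cohort row.
#' @param mspec A [methylome_spec()].
#' @return A [methylation_matrix()] with attribute `truth` (a list with the
#'   true `clock_coefficients` and the signal CpG ids).
#' @export
generate_methylation_study <- function(cohort, phenoages, mspec) {
  stopifnot(inherits(mspec, "methylome_spec"))
  n <- nrow(cohort)
  if (length(phenoages) != n)
    stop("`phenoages` must align with the cohort (one value per subject)",
         call. = FALSE)
  set.seed(derive_seed(mspec$seed, "methylome"))
  p <- mspec$n_cpgs
  s <- mspec$n_signal_cpgs
  cpg_ids <- sprintf("cg%08d", sample.int(9999999L, p))
  mu <- mean(phenoages)
  sdp <- stats::sd(phenoages)
  z <- if (sdp > 0) (phenoages - mu) / sdp else rep(0, n)
  signal_idx <- sort(sample.int(p, s))
  b0 <- stats::runif(p, 0.05, 0.95)
  b0[signal_idx] <- stats::runif(s, 0.35, 0.65)
  slope <- numeric(p)
  if (s > 0)
    slope[signal_idx] <- sample(c(-1, 1), s, replace = TRUE) *
      stats::runif(s, 0.03, 0.08)
  betas <- matrix(rep(b0, each = n), n, p) + outer(z, slope)
  if (mspec$noise_sd > 0)
    betas <- betas + matrix(stats::rnorm(n * p, 0, mspec$noise_sd), n, p)
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(cohort$id, cpg_ids)
  truth_clock <- NULL
  if (s > 0 && sdp > 0) {
    w <- sdp / (slope[signal_idx] * s)
    truth_clock <- clock_coefficients(
      intercept = mu - sum(w * b0[signal_idx]),
      weights = stats::setNames(w, cpg_ids[signal_idx]),
      training_means = stats::setNames(colMeans(betas), cpg_ids))
  }
  m <- methylation_matrix(betas, ages = cohort$age, time = cohort$time,
                          event = cohort$event, cause = cohort$cause)
  attr(m, "truth") <- list(clock = truth_clock,
                           signal_cpgs = cpg_ids[signal_idx],
                           phenoage = phenoages)
  m
}

#' Generate several independent studies sharing one true effect
#'
#' Simulates `k` cohorts in which an age-acceleration covariate (years,
#' normal with SD `accel_sd`) multiplies the Gompertz hazard by
#' `exp(effect)` per year, on top of a chronological-age term. Fixtures for
#' testing hazard-ratio estimation and fixed-effect meta-analysis.
#'
#' @param k Number of studies, at least 1.
#' @param spec A [cohort_spec()]; supplies sample size, age range, gamma,
#'   follow-up and the age weight (`true_weights["age"]`, default 0.0804).
#' @param effect True log hazard ratio per year of acceleration.
#' @param accel_sd SD of the acceleration covariate, years (default 5).
#' @return List of `k` data frames (`age`, `accel`, `time`, `event`) with
#'   attribute `truth = list(effect = effect)`.
#' @export
generate_multistudy <- function(k, spec, effect, accel_sd = 5) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  stopifnot(inherits(spec, "cohort_spec"))
  w_age <- if ("age" %in% names(spec$true_weights)) spec$true_weights[["age"]] else 0.0804
  # intercept giving a mid-age subject ~15% risk over follow-up
  mid <- mean(spec$age_range)
  b0 <- log(-log1p(-0.15) * spec$gompertz_gamma /
              expm1(spec$gompertz_gamma * spec$followup_months)) - w_age * mid
  set.seed(derive_seed(spec$seed, "multistudy"))
  seeds <- sample.int(2^31 - 1, k)
  studies <- vector("list", k)
  for (j in seq_len(k)) {
    set.seed(seeds[j])
    n <- spec$n_subjects
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    accel <- stats::rnorm(n, 0, accel_sd)
    xb <- b0 + w_age * age + effect * accel
    tt <- rgompertz_time(n, xb, spec$gompertz_gamma)
    studies[[j]] <- data.frame(age = age, accel = accel,
                               time = pmin(tt, spec$followup_months),
                               event = as.integer(tt <= spec$followup_months))
  }
  attr(studies, "truth") <- list(effect = effect, w_age = w_age, b0 = b0)
  studies
}
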