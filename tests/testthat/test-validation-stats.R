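# Validation battery: Cox hazard ratios, meta-analysis, survival curves,
# horizon ROC, robust correlation and overlap enrichment.

test_that("age-adjusted Cox estimate matches direct partial-likelihood maximization", {
  d <- survival_fixture(n = 12, seed = 41)
  est <- cox_hr_per_year(d$x1, NULL, d$time, d$event, covariates = d["x2"])
  b <- maximize_breslow(as.matrix(d[, c("x1", "x2")]), d$time, d$event)
  expect_equal(est$log_hr, b[1], tolerance = 1e-6)
  expect_equal(est$hr, exp(est$log_hr))
  expect_equal(est$events, sum(d$event), ignore_attr = TRUE)
})

test_that("rank-deficient designs and degenerate inputs are rejected", {
  d <- survival_fixture(n = 30, seed = 43)
  expect_error(cox_hr_per_year(d$x1, NULL, d$time, d$event,
                               covariates = data.frame(dup = d$x1)),
               "rank deficient")
  expect_error(cox_hr_per_year(d$x1, NULL, rep(c(1, 2), 15),
                               c(1, rep(0, 29))), "distinct event times")
})

test_that("cause-specific hazards recode competing events as censored", {
  coh <- small_cohort(500, seed = 52)
  score <- coh$true_xb + rnorm(nrow(coh), 0, 0.3)
  est <- cause_specific_hr(score, coh$age, coh$time, coh$event, coh$cause,
                           target_cause = "aging-related")
  # manual recode oracle
  ev2 <- as.integer(coh$event == 1 & !is.na(coh$cause) & coh$cause == "aging-related")
  est2 <- cox_hr_per_year(score, coh$age, coh$time, ev2)
  expect_equal(est$log_hr, est2$log_hr, tolerance = 1e-12)
  expect_equal(est$se, est2$se, tolerance = 1e-12)
  # single-cause data reduce to the all-cause model
  coh$cause[coh$event == 1] <- "aging-related"
  est3 <- cause_specific_hr(score, coh$age, coh$time, coh$event, coh$cause,
                            target_cause = "aging-related")
  est4 <- cox_hr_per_year(score, coh$age, coh$time, coh$event)
  expect_equal(est3$log_hr, est4$log_hr, tolerance = 1e-12)
  expect_error(cause_specific_hr(score, coh$age, coh$time, coh$event, coh$cause,
                                 target_cause = "no-such-cause"), "zero events")
})

test_that("fixed-effect pooling is exact inverse-variance arithmetic", {
  set.seed(61)
  ests <- lapply(1:5, function(i)
    list(log_hr = rnorm(1, 0.04, 0.02), se = runif(1, 0.005, 0.05)))
  meta <- fixed_effect_meta(ests)
  b <- sapply(ests, `[[`, "log_hr"); se <- sapply(ests, `[[`, "se")
  w <- 1 / se^2
  expect_equal(meta$log_hr, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(meta$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # pooled variance never exceeds any study variance; order-invariant
  expect_true(meta$se <= min(se))
  expect_equal(fixed_effect_meta(rev(ests))$log_hr, meta$log_hr, tolerance = 1e-15)
  # a single study passes through
  one <- fixed_effect_meta(ests[1])
  expect_equal(one$log_hr, ests[[1]]$log_hr)
  expect_equal(one$se, ests[[1]]$se)
  # equal-precision studies pool to the mean
  eq <- fixed_effect_meta(list(list(log_hr = 0.02, se = 0.01),
                               list(log_hr = 0.06, se = 0.01)))
  expect_equal(eq$log_hr, 0.04, tolerance = 1e-12)
})

test_that("Stouffer combination matches closed-form normal arithmetic", {
  # k = 1 returns the input p
  expect_equal(stouffer_meta(0.037, 1)$p, 0.037, tolerance = 1e-12)
  # two consistent one-sided-aligned p = 0.05
  z <- qnorm(1 - 0.05 / 2)
  got <- stouffer_meta(c(0.05, 0.05), c(1, 1))
  expect_equal(got$z, 2 * z / sqrt(2), tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-2 * z / sqrt(2)), tolerance = 1e-12)
  # opposite directions cancel exactly
  opp <- stouffer_meta(c(0.01, 0.01), c(1, -1))
  expect_equal(opp$z, 0)
  expect_equal(opp$p, 1)
  # sqrt(n) weighting
  wtd <- stouffer_meta(c(0.05, 0.5), c(1, 1), n = c(100, 400))
  expect_equal(wtd$z, (10 * z + 20 * qnorm(0.75)) / sqrt(100 + 400), tolerance = 1e-12)
  expect_error(stouffer_meta(c(0, 0.5), c(1, 1)), "0, 1")
  expect_error(stouffer_meta(0.5, 2), "direction")
})

test_that("Kaplan-Meier matches hand arithmetic and brute-force risk sets", {
  km <- kaplan_meier(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
  expect_equal(surv_at(km, 1), 0.8)
  expect_equal(surv_at(km, 2), 0.6)
  expect_equal(surv_at(km, 4), 0.3, tolerance = 1e-12)
  expect_equal(surv_at(km, 0), 1)

  set.seed(71)
  time <- round(rexp(200, 0.02), 1) + 0.1
  event <- rbinom(200, 1, 0.6)
  km2 <- kaplan_meier(time, event)
  bf <- km_brute_force(time, event)
  expect_equal(surv_at(km2, bf$time), bf$surv, tolerance = 1e-12)
  # no events: survival identically 1
  km3 <- kaplan_meier(time, rep(0, 200))
  expect_true(all(km3$surv == 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "positive")
})

test_that("hazard contrasts exponentiate the per-year ratio", {
  expect_equal(round(hazard_contrast(1.045, 11.0, 0), 2), 1.62)
  expect_equal(round(hazard_contrast(1.045, 11.0, -10.5), 2), 2.58)
  for (h in c(0.8, 1, 1.3)) expect_equal(hazard_contrast(h, 7, 7), 1)
  expect_error(hazard_contrast(-1, 1, 0), "positive")
})

test_that("predicted survival curves respect proportional hazards and the data", {
  set.seed(81)
  n <- 5000
  x <- cbind(z = rnorm(n))
  tt <- rgompertz_time(n, -6.2 + 0.5 * x[, 1], 0.009)
  event <- as.integer(tt <= 400); time <- pmin(tt, 400)
  fit <- fit_gompertz_ph(x, time, event)
  grid <- seq(0, 400, by = 1)
  s_avg <- predicted_survival(fit, c(z = 0), grid)
  s_hi <- predicted_survival(fit, c(z = 1), grid)
  expect_equal(s_avg$surv[1], 1)
  expect_true(all(s_hi$surv <= s_avg$surv)) # positive coefficient: lower survival
  # predicted median for z = 0 close to the empirical median of fresh truth draws
  meds <- replicate(30, {
    t2 <- rgompertz_time(5000, -6.2, 0.009)
    median(t2)
  })
  expect_lt(abs(s_avg$median - mean(meds)), 3 * sd(meds))
  # a subject too healthy to cross 0.5 in the window is right-censored
  s_never <- predicted_survival(fit, c(z = -40), seq(0, 50, 1))
  expect_true(is.na(s_never$median))
  expect_true(isTRUE(attr(s_never$median, "censored")))
})

test_that("horizon AUC matches the pairwise oracle and its complement identity", {
  set.seed(91)
  n <- 50
  score <- rnorm(n)
  time <- rexp(n, 0.02 * exp(0.5 * score))
  event <- rbinom(n, 1, 0.8)
  auc <- roc_auc_at_horizon(score, time, event, horizon = 40)
  case <- event == 1 & time <= 40
  ctrl <- time > 40
  expect_equal(as.numeric(auc), auc_brute_force(score[case], score[ctrl]),
               tolerance = 1e-12)
  expect_identical(attr(auc, "n_excluded"), as.integer(sum(!case & !ctrl)))
  # complement identity (no score ties)
  auc_neg <- roc_auc_at_horizon(-score, time, event, horizon = 40)
  expect_equal(as.numeric(auc) + as.numeric(auc_neg), 1, tolerance = 1e-12)
  # perfectly separating scores
  sep <- ifelse(case, 100, 0) + runif(n)
  expect_equal(as.numeric(roc_auc_at_horizon(sep, time, event, 40)), 1)
  expect_error(roc_auc_at_horizon(score, time, rep(0, n), 1e6), "controls")
})

test_that("biweight midcorrelation is exact on monotone data and robust to outliers", {
  set.seed(101)
  x <- rnorm(30)
  expect_equal(bicor(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  # one gross outlier: bicor stays closer to the clean Pearson correlation
  y <- x + rnorm(30, 0, 0.4)
  r_clean <- cor(x, y)
  xo <- c(x, 10); yo <- c(y, -10)
  expect_lt(abs(bicor(xo, yo) - r_clean), abs(cor(xo, yo) - r_clean))
  expect_warning(r0 <- bicor(c(1, 1, 1, 1, 2), c(1, 2, 3, 4, 5)), "MAD")
  expect_equal(r0, cor(c(1, 1, 1, 1, 2), c(1, 2, 3, 4, 5)))
})

test_that("overlap enrichment matches exhaustive enumeration", {
  # universe 10, |A| = 5, |B| = 4: enumerate all C(10,4) draws of B
  universe <- 1:10; A <- 1:5
  draws <- utils::combn(10, 4)
  overlaps <- apply(draws, 2, function(b) length(intersect(A, b)))
  for (k in c(2, 4)) {
    res <- overlap_enrichment(10, 5, 4, k)
    expect_equal(res$p, mean(overlaps >= k), tolerance = 1e-12)
    expect_equal(res$fold, k / (5 * 4 / 10), tolerance = 1e-12)
  }
  # observed equal to expected gives fold exactly 1
  expect_equal(overlap_enrichment(10, 5, 4, 2)$fold, 1)
  expect_error(overlap_enrichment(10, 5, 4, 5), "impossible")
  expect_error(overlap_enrichment(10, 12, 4, 2), "impossible")
})
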