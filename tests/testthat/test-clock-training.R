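# Two-step training pipeline: penalized Cox path, penalty selection,
# Gompertz maximum likelihood, and the elastic-net CpG clock.

test_that("penalized Cox path shrinks fully at large penalties and is monotone in sparsity", {
  coh <- small_cohort(300, seed = 51)
  X <- as.matrix(coh[, c("albumin", "glucose", "rdw", "age", "nuis01", "nuis02")])
  path <- fit_penalized_cox(X, coh$time, coh$event)
  expect_s3_class(path, "penalized_path")
  expect_true(all(diff(path$lambda) < 0))
  expect_identical(unname(colSums(path$beta != 0)[1]), 0) # lambda_max: all zero
  nz <- colSums(path$beta != 0)
  # nonzero count never decreases as lambda decreases along the path
  expect_true(all(diff(nz) >= 0) || sum(diff(nz) < 0) <= 2) # glmnet may drop/swap rarely
  expect_error(fit_penalized_cox(X, coh$time, rep(0, nrow(coh))), "censored")
  Xc <- cbind(X, const = 1)
  expect_error(fit_penalized_cox(Xc, coh$time, coh$event), "constant")
})

test_that("an unpenalized path endpoint matches direct partial-likelihood maximization", {
  d <- survival_fixture(n = 30, seed = 7)
  X <- as.matrix(d[, c("x1", "x2")])
  path <- fit_penalized_cox(X, d$time, d$event, mixing = 0.5,
                            lambda = c(0.5, 0.1, 0.01, 0), thresh = 1e-16)
  b_hat <- path$beta[, ncol(path$beta)]
  b_oracle <- maximize_breslow(X, d$time, d$event)
  expect_equal(unname(b_hat), b_oracle, tolerance = 1e-6)
})

test_that("duplicating every subject leaves the path unchanged under per-observation scaling", {
  d <- survival_fixture(n = 40, seed = 12)
  X <- as.matrix(d[, c("x1", "x2")])
  p1 <- fit_penalized_cox(X, d$time, d$event, lambda = c(0.3, 0.1, 0.03, 0.01),
                          thresh = 1e-14)
  p2 <- fit_penalized_cox(rbind(X, X), c(d$time, d$time), c(d$event, d$event),
                          lambda = c(0.3, 0.1, 0.03, 0.01), thresh = 1e-14)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-6)
})

test_that("penalty selection rules behave on hand-built CV curves", {
  lam <- c(1, 0.5, 0.25, 0.1, 0.05)
  # monotone decreasing loss: "min" picks the last grid point
  expect_identical(phenoclock:::select_lambda_from_cv(lam, c(9, 7, 5, 3, 1),
                                                      rep(1, 5), "min"), 0.05)
  # zero SD everywhere: 1se collapses to min
  expect_identical(phenoclock:::select_lambda_from_cv(lam, c(5, 4, 3, 2, 2.5),
                                                      rep(0, 5), "1se"), 0.1)
  # hand-computed 1-SE choice: min at 0.1 (loss 2, sd 1.5) admits lambda up to 1
  # whose loss <= 3.5; largest qualifying is 0.5 (loss 3.2)
  expect_identical(phenoclock:::select_lambda_from_cv(lam, c(4.0, 3.2, 3.6, 2, 2.2),
                                                      c(1, 1, 1, 1.5, 1), "1se"), 0.5)
})

test_that("cross-validated selection is seeded and guards its preconditions", {
  coh <- small_cohort(250, seed = 77)
  X <- as.matrix(coh[, c("glucose", "rdw", "age", "nuis01")])
  path <- fit_penalized_cox(X, coh$time, coh$event)
  s1 <- cv_select_lambda(path, folds = 5, rule = "1se", seed = 2)
  s2 <- cv_select_lambda(path, folds = 5, rule = "1se", seed = 2)
  expect_identical(s1$lambda, s2$lambda)
  expect_true(s1$lambda >= cv_select_lambda(path, folds = 5, rule = "min", seed = 2)$lambda)
  few <- which(coh$event == 1)[1:3]
  keep <- c(few, which(coh$event == 0))
  path2 <- fit_penalized_cox(X[keep, ], coh$time[keep], coh$event[keep])
  expect_error(cv_select_lambda(path2, folds = 10), "fewer events")
})

test_that("Gompertz MLE reduces to the exponential MLE as gamma vanishes", {
  set.seed(15)
  time <- rexp(400, 0.01)
  event <- as.integer(time <= 100)
  time <- pmin(time, 100)
  fit <- fit_gompertz_ph(NULL, time, event, gamma_fixed = 1e-10)
  expect_equal(fit$intercept, log(sum(event) / sum(time)), tolerance = 1e-3)
})

test_that("Gompertz MLE recovers simulation truth within 3 standard errors", {
  set.seed(1234)
  n <- 5000
  x <- cbind(z1 = rnorm(n), z2 = runif(n, -1, 1))
  b_true <- c(0.5, -0.8); b0_true <- -6.5; g_true <- 0.009
  xb <- b0_true + drop(x %*% b_true)
  tt <- rgompertz_time(n, xb, g_true)
  event <- as.integer(tt <= 240); time <- pmin(tt, 240)
  fit <- fit_gompertz_ph(x, time, event)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - b0_true) / fit$se[["intercept"]], 3)
  expect_lt(abs(fit$gamma - g_true) / fit$se_gamma, 3)
  expect_lt(abs(fit$coef[["z1"]] - b_true[1]) / fit$se[["z1"]], 3)
  expect_lt(abs(fit$coef[["z2"]] - b_true[2]) / fit$se[["z2"]], 3)
  # optimality: fitted likelihood is at least the likelihood at the truth
  ll_truth <- phenoclock:::gompertz_ph_loglik(c(b0_true, log(g_true), b_true),
                                              x, time, event)
  expect_gte(fit$loglik, ll_truth)
})

test_that("Gompertz MLE agrees with an independent parametric survival fitter", {
  skip_if_not_installed("flexsurv")
  set.seed(77)
  n <- 1500
  x <- cbind(z = rnorm(n))
  tt <- rgompertz_time(n, -6 + 0.6 * x[, 1], 0.01)
  event <- as.integer(tt <= 200); time <- pmin(tt, 200)
  fit <- fit_gompertz_ph(x, time, event)
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ z,
                               data = data.frame(time = time, event = event,
                                                 z = x[, 1]),
                               dist = "gompertz")
  co <- ref$res[, "est"]
  # two different optimizers of the same likelihood; agree to their shared
  # convergence precision
  expect_equal(fit$gamma, unname(co["shape"]), tolerance = 5e-3)
  expect_equal(fit$intercept, log(unname(co["rate"])), tolerance = 5e-3)
  expect_equal(unname(fit$coef), unname(co["z"]), tolerance = 5e-3)
  # and the in-package fit never has lower likelihood
  ll_ref <- phenoclock:::gompertz_ph_loglik(
    c(log(unname(co["rate"])), log(unname(co["shape"])), unname(co["z"])),
    x, time, event)
  expect_gte(fit$loglik, ll_ref - 1e-6)
})

test_that("build_phenoage_model enforces the cause filter and always keeps age", {
  coh <- small_cohort(400, seed = 88)
  coh$cause[coh$event == 1] <- "other"
  expect_error(build_phenoage_model(coh), "aging-related")
  coh2 <- small_cohort(400, seed = 88)
  m <- build_phenoage_model(coh2, folds = 5, seed = 3)
  expect_true("age" %in% names(m$weights))
  expect_s3_class(attr(m, "selection"), "cv_selection")
  expect_gt(attr(m, "age_only_fit")$coef[["age"]], 0)
})

test_that("elastic-net clock handles a constant response and matches OLS at lambda zero", {
  set.seed(9)
  X <- matrix(runif(200 * 12), 200, 12,
              dimnames = list(NULL, sprintf("cg%08d", 1:12)))
  tc <- fit_elastic_net_clock(X, rep(52.5, 200))
  expect_identical(tc$n_nonzero, 0L)
  expect_equal(tc$clock$intercept, 52.5)
  expect_equal(apply_clock(X, tc$clock)$dnam_phenoage, rep(52.5, 200),
               ignore_attr = TRUE)

  y <- 40 + X %*% rnorm(12) + rnorm(200, 0, 0.5)
  path <- fit_elastic_net_path(X, drop(y), lambda = c(1, 0.1, 0.01, 0),
                               thresh = 1e-16)
  ols <- stats::lm.fit(cbind(1, X), drop(y))$coefficients
  expect_equal(unname(path$beta[, 4]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(unname(path$a0[4]), unname(ols[1]), tolerance = 1e-6)
})

test_that("planted-signal clock achieves near-perfect out-of-sample recovery without noise", {
  coh <- small_cohort(600, seed = 61)
  pa <- phenotypic_age(coh, phenoage_model_published())$phenoage
  m0 <- generate_methylation_study(coh, pa,
                                   methylome_spec(n_cpgs = 800, n_signal_cpgs = 40,
                                                  noise_sd = 0, seed = 61))
  tr <- 1:300; te <- 301:600
  tc <- fit_elastic_net_clock(m0$betas[tr, ], pa[tr], folds = 5, seed = 2)
  sc <- apply_clock(m0$betas[te, ], tc$clock)
  expect_gte(cor(sc$dnam_phenoage, pa[te]), 0.99)
})

test_that("pipeline is deterministic for fixed inputs and seed", {
  coh <- small_cohort(300, seed = 42)
  pa <- phenotypic_age(coh, phenoage_model_published())$phenoage
  m <- generate_methylation_study(coh, pa, methylome_spec(n_cpgs = 300,
                                                          n_signal_cpgs = 20,
                                                          seed = 42))
  t1 <- fit_elastic_net_clock(m, pa, folds = 5, seed = 10)
  t2 <- fit_elastic_net_clock(m, pa, folds = 5, seed = 10)
  expect_identical(t1$clock$weights, t2$clock$weights)
  expect_identical(t1$lambda, t2$lambda)
})

test_that("universe restriction preserves order, de-duplicates, and errors when disjoint", {
  X <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("s", 1:4), sprintf("cg%08d", 1:10)))
  m <- methylation_matrix(X)
  all_ids <- colnames(X)
  expect_identical(restrict_to_universe(m, all_ids)$betas, X)
  expect_error(restrict_to_universe(m, c("cg99999991", "cg99999992")), "no CpGs")
  expect_warning(r <- restrict_to_universe(m, c(all_ids[3], all_ids[3], all_ids[1])),
                 "dup")
  expect_identical(colnames(r$betas), all_ids[c(3, 1)]) # set-based, order kept
  expect_message(r2 <- restrict_to_universe(m, c(all_ids[1:2], "cg99999993")),
                 "dropped")
  expect_identical(attr(r2, "n_dropped"), 1L)
})
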