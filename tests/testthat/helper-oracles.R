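# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (quadrature, enumeration, direct optimization)
# and share no code with the implementation paths they check.

# Gompertz horizon risk by numerical quadrature of the hazard
# h(s) = exp(xb + gamma s), passed through S = exp(-H).
quadrature_risk <- function(xb, t, gamma) {
  H <- stats::integrate(function(s) exp(xb + gamma * s), 0, t,
                        rel.tol = 1e-12, abs.tol = 1e-14)$value
  1 - exp(-H)
}

# Closed-form Gompertz CDF for a constant linear predictor.
pgompertz_cdf <- function(q, xb, gamma) {
  1 - exp(-exp(xb) * (exp(gamma * q) - 1) / gamma)
}

# Breslow-tie Cox partial log-likelihood, written directly from the
# risk-set definition (O(n^2); fine for fixtures).
breslow_partial_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (tt in unique(time[event == 1])) {
    d <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Direct maximization of the Breslow partial likelihood (oracle for Cox
# fits; independent of survival::coxph).
maximize_breslow <- function(X, time, event) {
  stats::optim(rep(0, ncol(X)),
               function(b) -breslow_partial_loglik(b, X, time, event),
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# Product-limit estimator by explicit risk-set enumeration.
km_brute_force <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    d <- sum(time == ts[i] & event == 1)
    r <- sum(time >= ts[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# O(n^2) pairwise AUC with half-credit for ties.
auc_brute_force <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores)
    for (b in control_scores)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(case_scores) * length(control_scores))
}

# A small deterministic survival fixture with ties and censoring.
survival_fixture <- function(n = 12, seed = 99) {
  set.seed(seed)
  data.frame(x1 = rnorm(n), x2 = rnorm(n),
             time = sample(c(1, 2, 2, 3, 5, 8), n, replace = TRUE) + 0,
             event = rbinom(n, 1, 0.7))
}

# Default-condition synthetic cohort reused by several tests.
small_cohort <- function(n = 400, seed = 303, ...) {
  generate_clinical_cohort(cohort_spec(n_subjects = n, seed = seed, ...))
}
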