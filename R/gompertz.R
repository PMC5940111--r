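#' Gompertz cumulative mortality risk
#'
#' Probability of death by time `t` under a Gompertz proportional-hazards
#' model with hazard `h(t) = exp(xb) * exp(gamma * t)`:
#' `M = 1 - exp(-exp(xb) * (exp(gamma * t) - 1) / gamma)`.
#'
#' @param xb Linear predictor (dimensionless), any length.
#' @param t Time horizon in months, `t >= 0`. Recycled against `xb`.
#' @param gamma Gompertz slope per month, strictly positive.
#' @return Risk in `[0, 1)`, monotone increasing in both `xb` and `t`.
#' @examples
#' gompertz_mortality_risk(-7.5, 120, 0.0077)
#' @export
gompertz_mortality_risk <- function(xb, t, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  # cumulative hazard H(t) = exp(xb) * (exp(gamma t) - 1) / gamma
  -expm1(-exp(xb) * expm1(gamma * t) / gamma)
}

#' Convert a horizon mortality risk to an age in years
#'
#' Inverts an age-only Gompertz model: returns the chronological age at
#' which an average person has horizon risk `M`. Closed form:
#' `a = (log(gamma * (-log(1 - M)) / (exp(gamma * horizon) - 1)) - b0) / b_age`.
#'
#' @param M Mortality risk in the open interval (0, 1).
#' @param age_only An [age_only_gompertz()] model.
#' @return Age in years; strictly increasing in `M`.
#' @export
risk_to_phenoage <- function(M, age_only) {
  stopifnot(inherits(age_only, "age_only_gompertz"))
  if (any(!is.finite(M)) || any(M <= 0) || any(M >= 1))
    stop("`M` must lie strictly inside (0, 1)", call. = FALSE)
  g <- age_only$gamma
  (log(g * (-log1p(-M)) / expm1(g * age_only$horizon)) - age_only$b0) / age_only$b_age
}

#' Age-only Gompertz reference model
#'
#' The sub-model used to express a mortality risk in units of years: an
#' average person of age `a` has linear predictor `b0 + b_age * a`, so the
#' horizon risk is an increasing function of age that can be inverted.
#'
#' @param b0 Dimensionless intercept.
#' @param b_age Per-year log-hazard weight, strictly positive.
#' @param gamma Gompertz slope per month, strictly positive.
#' @param horizon Risk horizon in months (default 120).
#' @return An object of class `age_only_gompertz`.
#' @export
age_only_gompertz <- function(b0, b_age, gamma, horizon = 120) {
  stopifnot(is.numeric(b0), is.numeric(b_age), is.numeric(gamma))
  if (b_age <= 0) stop("`b_age` must be positive (risk increases with age)", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  structure(list(b0 = b0, b_age = b_age, gamma = gamma, horizon = horizon),
            class = "age_only_gompertz")
}

#' @export
print.age_only_gompertz <- function(x, ...) {
  cat("Age-only Gompertz model\n",
      sprintf("  b0 = %.6g, b_age = %.6g per year, gamma = %.6g per month, horizon = %g months\n",
              x$b0, x$b_age, x$gamma, x$horizon))
  invisible(x)
}

#' Sample Gompertz event times by inverse-CDF
#'
#' `T = log1p(gamma * (-log U) * exp(-xb)) / gamma` for `U ~ Uniform(0,1)`.
#' Used by the synthetic cohort generator; exported because it is also a
#' convenient simulation primitive for power calculations.
#'
#' @param n Number of draws (ignored if `xb` has length > 1).
#' @param xb Linear predictor, recycled to `n`.
#' @param gamma Gompertz slope per month, positive.
#' @return Event times in months, strictly positive.
#' @export
rgompertz_time <- function(n, xb, gamma) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (length(xb) > 1L) n <- length(xb)
  u <- stats::runif(n)
  log1p(gamma * (-log(u)) * exp(-xb)) / gamma
}
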