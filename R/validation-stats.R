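# Validation battery for biological-age measures: age-adjusted Cox hazard
# ratios, cause-specific hazards, fixed-effect and Stouffer meta-analysis,
# Kaplan-Meier curves, predicted survival, time-horizon ROC, biweight
# midcorrelation, and hypergeometric set-overlap enrichment.

new_hazard_estimate <- function(log_hr, se, p, n, events) {
  if (se <= 0) stop("standard error must be positive", call. = FALSE)
  structure(list(log_hr = log_hr, se = se, hr = exp(log_hr), p = p,
                 n = n, events = events),
            class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, ...) {
  cat(sprintf("HR = %.4f per unit (log HR %.4f, se %.4f, p = %.3g; n = %d, events = %d)\n",
              x$hr, x$log_hr, x$se, x$p, x$n, x$events))
  invisible(x)
}

#' Age-adjusted Cox hazard ratio per year of exposure
#'
#' Cox proportional-hazards regression of survival on the exposure (for
#' example a DNAm phenotypic age or its acceleration) adjusting for
#' chronological age and optional further covariates, with Breslow handling
#' of tied event times. The reported estimate is for the exposure.
#'
#' @param exposure Numeric per-sample exposure, years.
#' @param ages Chronological ages, years; set `NULL` to omit the adjustment.
#' @param time Follow-up, months.
#' @param event 0/1 event indicator.
#' @param covariates Optional numeric matrix or data frame of extra
#'   adjustment columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `hazard_estimate`: `log_hr`, `se`, `hr`, two-sided Wald `p`,
#'   `n`, `events`.
#' @export
cox_hr_per_year <- function(exposure, ages, time, event, covariates = NULL,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (length(unique(time[event == 1])) < 2)
    stop("need at least 2 distinct event times", call. = FALSE)
  dat <- data.frame(exposure = exposure)
  if (!is.null(ages)) dat$age <- ages
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  # guard against rank deficiency (e.g. exposure duplicated as a covariate)
  mm <- as.matrix(dat)
  if (qr(cbind(1, mm))$rank < ncol(mm) + 1L)
    stop("design matrix is rank deficient (collinear covariates)", call. = FALSE)
  dat$.time <- time
  dat$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(setdiff(names(dat), c(".time", ".event")),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (anyNA(stats::coef(fit)))
    stop("Cox fit failed (separation or collinearity)", call. = FALSE)
  s <- summary(fit)$coefficients
  new_hazard_estimate(log_hr = s["exposure", "coef"],
                      se = s["exposure", "se(coef)"],
                      p = s["exposure", "Pr(>|z|)"],
                      n = fit$n, events = fit$nevent)
}

#' Cause-specific hazard ratio
#'
#' Events of causes other than the target are treated as censored at their
#' event time (cause-specific hazard under competing risks), then the
#' age-adjusted Cox model of [cox_hr_per_year()] is fit.
#'
#' @inheritParams cox_hr_per_year
#' @param cause Cause label per sample (`NA` for censored).
#' @param target_cause The cause whose hazard is modelled.
#' @return A `hazard_estimate` for the exposure.
#' @export
cause_specific_hr <- function(exposure, ages, time, event, cause, target_cause,
                              covariates = NULL, ties = c("breslow", "efron")) {
  ev <- as.integer(event == 1 & !is.na(cause) & cause == target_cause)
  if (sum(ev) == 0) stop("zero events of cause `", target_cause, "`", call. = FALSE)
  cox_hr_per_year(exposure, ages, time, ev, covariates = covariates,
                  ties = match.arg(ties))
}

#' Fixed-effect (inverse-variance) meta-analysis of hazard estimates
#'
#' Pools log hazard ratios with weights `1/se^2`:
#' `pooled = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, two-sided normal p.
#'
#' @param estimates List of `hazard_estimate` objects (or lists with
#'   `log_hr` and `se`).
#' @return A list of class `meta_result`: pooled `log_hr`, `se`, `hr`, `p`,
#'   `k`, and the per-study inputs.
#' @export
fixed_effect_meta <- function(estimates) {
  if (length(estimates) < 1) stop("need at least one study", call. = FALSE)
  b <- vapply(estimates, function(e) e$log_hr, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("non-positive study standard error", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  structure(list(log_hr = pooled, se = pooled_se, hr = exp(pooled),
                 p = 2 * stats::pnorm(-abs(z)), k = length(b),
                 studies = data.frame(log_hr = b, se = se)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d studies: HR = %.4f (log HR %.4f, se %.4f), p = %.3g\n",
              x$k, x$hr, x$log_hr, x$se, x$p))
  invisible(x)
}

#' Stouffer weighted-Z combination of p-values
#'
#' Each two-sided p-value is converted to a signed z,
#' `z_i = qnorm(1 - p_i/2) * direction_i`, combined as
#' `Z = sum(w z) / sqrt(sum(w^2))`, and returned with the two-sided p of Z.
#' Weights default to `sqrt(n)` when sample sizes are supplied, else equal.
#'
#' @param p Two-sided p-values strictly inside (0, 1).
#' @param directions Effect signs, +1 or -1, per study.
#' @param weights Optional positive weights.
#' @param n Optional per-study sample sizes (used as `sqrt(n)` weights when
#'   `weights` is NULL).
#' @return List with `z` and `p`.
#' @export
stouffer_meta <- function(p, directions, weights = NULL, n = NULL) {
  if (any(p <= 0 | p >= 1)) stop("p-values must lie strictly inside (0, 1)", call. = FALSE)
  if (length(directions) != length(p) || !all(directions %in% c(-1, 1)))
    stop("`directions` must be +1/-1, one per p-value", call. = FALSE)
  if (is.null(weights)) weights <- if (is.null(n)) rep(1, length(p)) else sqrt(n)
  if (any(weights <= 0) || length(weights) != length(p))
    stop("`weights` must be positive, one per p-value", call. = FALSE)
  z <- stats::qnorm(1 - p / 2) * directions
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  list(z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()], returned as a
#' right-continuous step function with `S(0) = 1`.
#'
#' @param time Follow-up times, strictly positive.
#' @param event 0/1 event indicator.
#' @return A list of class `km_curve` with `time` and `surv` (including the
#'   origin), plus `n_risk`/`n_event` at each time.
#' @export
kaplan_meier <- function(time, event) {
  if (any(time <= 0)) stop("times must be strictly positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(length(time), fit$n.risk),
                 n_event = c(0, fit$n.event)),
            class = "km_curve")
}

#' Evaluate a survival step function
#'
#' @param curve A `km_curve` or `predicted_survival` object.
#' @param t Times at which to evaluate.
#' @return Survival probabilities (right-continuous interpolation).
#' @export
surv_at <- function(curve, t) {
  stats::approx(curve$time, curve$surv, xout = t, method = "constant",
                f = 0, yleft = 1, yright = min(curve$surv))$y
}

#' Hazard contrast between two levels of a per-year hazard ratio
#'
#' Ratio of hazards for subjects whose exposure differs from a reference by
#' `delta_a` versus `delta_b` years: `hr_per_year^(delta_a - delta_b)`.
#' For example, with a per-year hazard ratio of 1.045, a subject 11 years
#' above the average versus the average has `1.045^11 ~= 1.62`, and versus a
#' subject 10.5 years below the average `1.045^21.5 ~= 2.58`.
#'
#' @param hr_per_year Hazard ratio per year, positive.
#' @param delta_a,delta_b Offsets from the reference, years.
#' @return The hazard ratio contrast.
#' @export
hazard_contrast <- function(hr_per_year, delta_a, delta_b = 0) {
  if (any(hr_per_year <= 0)) stop("`hr_per_year` must be positive", call. = FALSE)
  hr_per_year^(delta_a - delta_b)
}

#' Predicted survival curve for a covariate pattern
#'
#' For a [fit_gompertz_ph()] model the curve is the closed form
#' `S(t | x) = exp(-exp(xb) (exp(gamma t) - 1)/gamma)`; for a
#' [survival::coxph()] fit the Breslow baseline raised to `exp(xb)` via
#' [survival::survfit()]. Median survival is the first time the curve
#' crosses 0.5; if it never does within the grid/follow-up it is reported
#' as right-censored (`NA` with attribute `censored`).
#'
#' @param model A `gompertz_ph` or `coxph` fit.
#' @param newdata One-row data frame (or named vector for `gompertz_ph`)
#'   with the covariate values.
#' @param times Evaluation grid, months.
#' @return A list of class `predicted_survival`: `time`, `surv`, `median`.
#' @export
predicted_survival <- function(model, newdata, times) {
  if (inherits(model, "gompertz_ph")) {
    x <- unlist(newdata)[names(model$coef)]
    if (length(model$coef) && anyNA(x))
      stop("`newdata` must supply: ", paste(names(model$coef), collapse = ", "),
           call. = FALSE)
    xb <- model$intercept + if (length(model$coef)) sum(model$coef * x) else 0
    surv <- exp(-exp(xb) * expm1(model$gamma * times) / model$gamma)
    tt <- times
  } else if (inherits(model, "coxph")) {
    sf <- survival::survfit(model, newdata = as.data.frame(newdata))
    tt <- c(0, sf$time)
    surv <- c(1, sf$surv)
    if (!missing(times) && !is.null(times)) {
      surv <- stats::approx(tt, surv, xout = times, method = "constant",
                            f = 0, yleft = 1, yright = min(surv))$y
      tt <- times
    }
  } else stop("`model` must be a gompertz_ph or coxph fit", call. = FALSE)
  below <- which(surv <= 0.5)
  med <- if (length(below)) tt[min(below)] else structure(NA_real_, censored = TRUE)
  structure(list(time = tt, surv = surv, median = med),
            class = "predicted_survival")
}

#' Time-horizon ROC AUC for a risk score
#'
#' Cases are subjects with an observed event by the horizon; controls are
#' subjects still under follow-up beyond the horizon; subjects censored
#' before the horizon are excluded. The AUC is the Wilcoxon rank statistic
#' with midrank tie correction.
#'
#' @param scores Risk scores (higher = higher risk).
#' @param time Follow-up, months.
#' @param event 0/1 event indicator.
#' @param horizon Horizon in months, positive.
#' @return AUC in `[0, 1]`, with attributes `n_cases`, `n_controls`,
#'   `n_excluded`.
#' @export
roc_auc_at_horizon <- function(scores, time, event, horizon) {
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  case <- event == 1 & time <= horizon
  control <- time > horizon
  excluded <- !(case | control)
  n1 <- sum(case); n0 <- sum(control)
  if (n1 == 0 || n0 == 0)
    stop("no cases or no controls at this horizon", call. = FALSE)
  r <- rank(c(scores[case], scores[control]))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, n_cases = n1, n_controls = n0, n_excluded = sum(excluded))
}

#' Biweight midcorrelation
#'
#' Robust correlation: deviations from the median are weighted by
#' `w = (1 - u^2)^2` for `u = (x - median) / (9 MAD)` (weight zero when
#' `|u| >= 1`), and the weighted deviations are correlated. When either
#' vector has zero median absolute deviation the function falls back to the
#' Pearson correlation with a warning.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must be equal-length vectors, n >= 3", call. = FALSE)
  mad_raw <- function(v) stats::median(abs(v - stats::median(v)))
  if (mad_raw(x) == 0 || mad_raw(y) == 0) {
    warning("zero MAD; falling back to Pearson correlation", call. = FALSE)
    return(stats::cor(x, y))
  }
  bw <- function(v) {
    u <- (v - stats::median(v)) / (9 * mad_raw(v))
    (v - stats::median(v)) * (1 - u^2)^2 * (abs(u) < 1)
  }
  a <- bw(x); b <- bw(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Overlap fold-enrichment and hypergeometric p-value
#'
#' For two sets of sizes `size_a` and `size_b` drawn from a universe of
#' `universe_size` items, the expected overlap is
#' `size_a * size_b / universe_size`; the fold enrichment is
#' `observed / expected` and the p-value the upper-tail hypergeometric
#' probability `P(X >= observed)`.
#'
#' @param universe_size,size_a,size_b,observed Non-negative counts with
#'   `observed <= min(size_a, size_b) <= universe_size`.
#' @return List with `fold`, `p`, `expected`.
#' @export
overlap_enrichment <- function(universe_size, size_a, size_b, observed) {
  if (observed > min(size_a, size_b) || max(size_a, size_b) > universe_size ||
      observed < 0 || min(size_a, size_b) < 0 ||
      observed < size_a + size_b - universe_size)
    stop("impossible overlap counts", call. = FALSE)
  expected <- size_a * size_b / universe_size
  list(fold = observed / expected,
       p = stats::phyper(observed - 1, size_a, universe_size - size_a, size_b,
                         lower.tail = FALSE),
       expected = expected)
}
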