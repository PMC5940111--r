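# Two-step clock training. Step 1: penalized Cox selection of clinical
# biomarkers for aging-related mortality, a parametric Gompertz
# proportional-hazards refit, and the age-only conversion model. Step 2: an
# elastic-net regression of phenotypic age on CpG beta values. The penalized
# paths are fitted with glmnet; the Gompertz full-likelihood fit is native.

#' Fit an elastic-net penalized Cox path
#'
#' For each penalty on a 100-point log-spaced grid (from the smallest value
#' giving an all-zero solution down by a factor 1e-4), coefficients maximize
#' the Breslow-tie partial log-likelihood minus
#' `lambda * (mixing * ||b||_1 + (1 - mixing)/2 * ||b||_2^2)`. Predictors
#' are standardized internally; coefficients are reported on the original
#' scale.
#'
#' @param X Numeric matrix, subjects x markers, with column names.
#' @param time Follow-up in months.
#' @param event 0/1 event indicator; at least one event required.
#' @param mixing Elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param lambda Optional explicit descending penalty grid.
#' @param nlambda,lambda_min_ratio Grid size and ratio when `lambda` is NULL.
#' @param penalty_factor Optional per-column penalty multipliers (0 forces a
#'   column into every model).
#' @param ... Further arguments to [glmnet::glmnet()] (e.g. `thresh`).
#' @return An object of class `penalized_path` holding the grid, the
#'   original-scale coefficient matrix and the training data (for
#'   cross-validation).
#' @export
fit_penalized_cox <- function(X, time, event, mixing = 0.5, lambda = NULL,
                              nlambda = 100, lambda_min_ratio = 1e-4,
                              penalty_factor = NULL, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1) stop("all observations censored: no events to fit", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  if (mixing < 0 || mixing > 1) stop("`mixing` must lie in [0, 1]", call. = FALSE)
  y <- survival::Surv(time, event)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, ncol(X))
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = mixing,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        penalty.factor = penalty_factor, standardize = TRUE, ...)
  structure(list(lambda = fit$lambda,
                 beta = as.matrix(fit$beta),
                 mixing = mixing, fit = fit,
                 penalty_factor = penalty_factor,
                 X = X, time = time, event = event,
                 family = "cox"),
            class = "penalized_path")
}

#' @export
print.penalized_path <- function(x, ...) {
  cat(sprintf("Penalized %s path: %d predictors, %d lambda values, mixing %.2f\n",
              x$family, nrow(x$beta), length(x$lambda), x$mixing))
  invisible(x)
}

# Rule application on a computed CV curve; exposed separately so the 1-SE
# logic is testable on hand-built curves.
select_lambda_from_cv <- function(lambda, cvm, cvsd, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  stopifnot(length(lambda) == length(cvm), length(cvm) == length(cvsd))
  i_min <- which.min(cvm)
  if (rule == "min") return(lambda[i_min])
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  max(lambda[ok])
}

# Seeded fold assignment, stratified by event status (or plain for gaussian).
make_foldid <- function(event, folds, seed) {
  set.seed(derive_seed(seed, "folds"))
  foldid <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' Cross-validate a penalized path and select the penalty
#'
#' Ten-fold (by default) cross-validation of the partial-likelihood deviance
#' (Cox) or mean squared error (gaussian) along the path's penalty grid,
#' with seeded fold assignment stratified by event status. `"min"` returns
#' the penalty minimizing the mean CV loss; `"1se"` the largest penalty
#' whose mean loss is within one standard error of that minimum.
#'
#' @param path A `penalized_path` from [fit_penalized_cox()] or
#'   [fit_elastic_net_path()].
#' @param folds Number of folds, at least 2.
#' @param rule `"1se"` or `"min"`.
#' @param seed Seed for the fold assignment.
#' @return A list of class `cv_selection`: `lambda` (the choice), `rule`,
#'   `lambda_grid`, `cvm`, `cvsd`, `foldid`.
#' @export
cv_select_lambda <- function(path, folds = 10, rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(inherits(path, "penalized_path"))
  if (folds < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (path$family == "cox") {
    if (sum(path$event) < folds)
      stop("fewer events (", sum(path$event), ") than folds (", folds, ")",
           call. = FALSE)
    y <- survival::Surv(path$time, path$event)
    foldid <- make_foldid(path$event, folds, seed)
    cv <- glmnet::cv.glmnet(path$X, y, family = "cox", alpha = path$mixing,
                            lambda = path$lambda, foldid = foldid,
                            penalty.factor = path$penalty_factor,
                            type.measure = "deviance", standardize = TRUE)
  } else {
    foldid <- make_foldid(rep(0L, length(path$y)), folds, seed)
    cv <- glmnet::cv.glmnet(path$X, path$y, family = "gaussian",
                            alpha = path$mixing, lambda = path$lambda,
                            foldid = foldid, type.measure = "mse",
                            standardize = TRUE)
  }
  structure(list(lambda = select_lambda_from_cv(cv$lambda, cv$cvm, cv$cvsd, rule),
                 rule = rule, lambda_grid = cv$lambda,
                 cvm = cv$cvm, cvsd = cv$cvsd, foldid = foldid),
            class = "cv_selection")
}

# Full Gompertz PH log-likelihood and gradient in theta = (b0, log gamma, b).
gompertz_ph_loglik <- function(theta, X, time, event) {
  b0 <- theta[1]; g <- exp(theta[2])
  xb <- b0 + if (is.null(X)) 0 else drop(X %*% theta[-(1:2)])
  gt <- expm1(g * time) / g
  sum(event * (xb + g * time)) - sum(exp(xb) * gt)
}

gompertz_ph_grad <- function(theta, X, time, event) {
  b0 <- theta[1]; g <- exp(theta[2])
  xb <- b0 + if (is.null(X)) 0 else drop(X %*% theta[-(1:2)])
  exb <- exp(xb)
  gt <- expm1(g * time) / g
  dgt_dg <- (g * time * exp(g * time) - expm1(g * time)) / g^2
  d_b0 <- sum(event) - sum(exb * gt)
  d_lg <- g * (sum(event * time) - sum(exb * dgt_dg))
  if (is.null(X)) return(c(d_b0, d_lg))
  d_b <- drop(crossprod(X, event - exb * gt))
  c(d_b0, d_lg, d_b)
}

#' Maximum-likelihood Gompertz proportional-hazards fit
#'
#' Maximizes the full log-likelihood
#' `sum_i [delta_i (xb_i + gamma t_i) - exp(xb_i)(exp(gamma t_i) - 1)/gamma]`
#' with `xb = intercept + X b`, over the intercept, the covariate weights
#' and `gamma` (kept positive via a log parameterization). BFGS with the
#' analytic gradient, polished by Newton steps until the gradient norm falls
#' below `tol`.
#'
#' @param X Covariate matrix (subjects x variables) or `NULL` for an
#'   intercept-plus-gamma-only model.
#' @param time Follow-up, months.
#' @param event 0/1 event indicator; at least one event.
#' @param gamma_fixed Optional fixed value of `gamma` (then only the linear
#'   part is estimated).
#' @param tol Gradient max-norm declaring convergence (default 1e-8).
#' @param max_iter Maximum Newton polish iterations.
#' @return An object of class `gompertz_ph`: `intercept`, `gamma`, `coef`
#'   (named, original scale), `loglik`, `se` (delta-method for `gamma`),
#'   `vcov` (on the internal parameterization), `gradient_norm`, `converged`.
#' @export
fit_gompertz_ph <- function(X, time, event, gamma_fixed = NULL,
                            tol = 1e-8, max_iter = 50) {
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (sum(event) < 1) stop("no events: Gompertz likelihood unbounded", call. = FALSE)
  p <- if (is.null(X)) 0L else ncol(X)

  if (!is.null(gamma_fixed)) {
    if (gamma_fixed <= 0) stop("`gamma_fixed` must be positive", call. = FALSE)
    lg <- log(gamma_fixed)
    nll <- function(th) -gompertz_ph_loglik(c(th[1], lg, th[-1]), X, time, event)
    grd <- function(th) -gompertz_ph_grad(c(th[1], lg, th[-1]), X, time, event)[-2]
    th0 <- c(log(sum(event) / sum(time)), rep(0, p))
    opt <- stats::optim(th0, nll, grd, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    theta <- c(opt$par[1], lg, opt$par[-1])
    free <- c(1L, seq_len(p) + 2L)
  } else {
    nll <- function(th) -gompertz_ph_loglik(th, X, time, event)
    grd <- function(th) -gompertz_ph_grad(th, X, time, event)
    th0 <- c(log(sum(event) / sum(time)), log(0.008), rep(0, p))
    opt <- stats::optim(th0, nll, grd, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    theta <- opt$par
    free <- seq_along(theta)
  }

  # Newton polish on the free parameters to drive the gradient norm down
  gnorm <- function(th) max(abs(gompertz_ph_grad(th, X, time, event)[free]))
  it <- 0L
  while (gnorm(theta) > tol && it < max_iter) {
    g_free <- gompertz_ph_grad(theta, X, time, event)[free]
    H <- stats::optimHess(theta[free],
                          function(thf) { th <- theta; th[free] <- thf
                            -gompertz_ph_loglik(th, X, time, event) },
                          function(thf) { th <- theta; th[free] <- thf
                            -gompertz_ph_grad(th, X, time, event)[free] })
    step <- tryCatch(solve(H, g_free), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- theta; cand[free] <- theta[free] + step
    # backtrack if the likelihood worsens
    s <- 1
    while (gompertz_ph_loglik(cand, X, time, event) <
           gompertz_ph_loglik(theta, X, time, event) && s > 1e-4) {
      s <- s / 2
      cand[free] <- theta[free] + s * step
    }
    theta <- cand
    it <- it + 1L
  }
  gn <- gnorm(theta)
  if (gn > sqrt(tol))
    stop(sprintf(paste0("Gompertz PH fit failed to converge: gradient norm ",
                        "%.3g after %d polish iterations (loglik %.4f)"),
                 gn, it, gompertz_ph_loglik(theta, X, time, event)),
         call. = FALSE)
  H <- stats::optimHess(theta[free],
                        function(thf) { th <- theta; th[free] <- thf
                          -gompertz_ph_loglik(th, X, time, event) })
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA, length(free), length(free)))
  par_names <- c("intercept", if (is.null(gamma_fixed)) "log_gamma",
                 if (p > 0) colnames(X))
  dimnames(vcov) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(vcov), 0))
  gamma <- exp(theta[2])
  se_gamma <- if (is.null(gamma_fixed)) gamma * se[["log_gamma"]] else NA_real_
  structure(list(intercept = theta[1], gamma = gamma,
                 coef = if (p > 0) stats::setNames(theta[-(1:2)], colnames(X)) else numeric(0),
                 loglik = gompertz_ph_loglik(theta, X, time, event),
                 se = se, se_gamma = se_gamma, vcov = vcov,
                 gradient_norm = gn, converged = gn <= tol,
                 n = length(time), events = sum(event)),
            class = "gompertz_ph")
}

#' @export
print.gompertz_ph <- function(x, ...) {
  cat(sprintf("Gompertz PH fit: n = %d, events = %d, loglik = %.3f\n",
              x$n, x$events, x$loglik))
  cat(sprintf("  intercept = %.4f, gamma = %.6g per month (se %.2g)\n",
              x$intercept, x$gamma, x$se_gamma))
  if (length(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' Build a Phenotypic Age model from a clinical cohort
#'
#' The step-1 pipeline: deaths from non-aging-related causes are treated as
#' censored, a penalized Cox path over all candidate biomarkers (plus
#' chronological age, which is never penalized away) is cross-validated and
#' the one-standard-error penalty chosen, the selected variables are refit
#' in the parametric Gompertz proportional-hazards model, and an age-only
#' Gompertz sub-model is fit on the same data to define the risk-to-years
#' conversion.
#'
#' @param cohort A `clinical_cohort` data frame (needs the biomarker
#'   columns, `age`, `time`, `event`, `cause`).
#' @param mixing Elastic-net mixing for the selection step (default 0.5).
#' @param folds,rule Cross-validation settings (defaults 10 and `"1se"`).
#' @param seed Seed for fold assignment.
#' @param horizon Risk horizon in months for the resulting model.
#' @return A [phenoage_model()], with attributes `selection` (the
#'   `cv_selection`), `gompertz_fit` and `age_only_fit`.
#' @export
build_phenoage_model <- function(cohort, mixing = 0.5, folds = 10,
                                 rule = "1se", seed = 1L, horizon = 120) {
  needed <- c("age", "time", "event", "cause")
  if (!all(needed %in% names(cohort)))
    stop("cohort needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  # aging-related mortality is the endpoint; other deaths are censored
  aging_event <- as.integer(cohort$event == 1 &
                              !is.na(cohort$cause) & cohort$cause == "aging-related")
  if (sum(aging_event) == 0)
    stop("zero aging-related events after the cause filter", call. = FALSE)
  marker_cols <- setdiff(names(cohort),
                         c("id", "time", "event", "cause", "true_xb"))
  X <- as.matrix(cohort[, marker_cols, drop = FALSE])
  if ("crp" %in% colnames(X)) X[, "crp"] <- log(X[, "crp"])
  pf <- rep(1, ncol(X))
  pf[colnames(X) == "age"] <- 0  # age is always retained
  path <- fit_penalized_cox(X, cohort$time, aging_event, mixing = mixing,
                            penalty_factor = pf)
  sel <- cv_select_lambda(path, folds = folds, rule = rule, seed = seed)
  b <- path$beta[, which.min(abs(path$lambda - sel$lambda))]
  keep <- union("age", names(b)[b != 0])
  keep <- colnames(X)[colnames(X) %in% keep]  # stable column order
  gfit <- fit_gompertz_ph(X[, keep, drop = FALSE], cohort$time, aging_event)
  afit <- fit_gompertz_ph(X[, "age", drop = FALSE], cohort$time, aging_event)
  model <- phenoage_model(
    weights = gfit$coef, intercept = gfit$intercept, gamma = gfit$gamma,
    horizon = horizon,
    age_only = age_only_gompertz(b0 = afit$intercept, b_age = afit$coef[["age"]],
                                 gamma = afit$gamma, horizon = horizon))
  attr(model, "selection") <- sel
  attr(model, "gompertz_fit") <- gfit
  attr(model, "age_only_fit") <- afit
  model
}

#' Fit an elastic-net path for a quantitative response
#'
#' Companion to [fit_penalized_cox()] for the step-2 squared-error problem;
#' same grid conventions, original-scale coefficients.
#'
#' @inheritParams fit_penalized_cox
#' @param y Quantitative response (phenotypic age, years).
#' @return A `penalized_path` with `family = "gaussian"`.
#' @export
fit_elastic_net_path <- function(X, y, mixing = 0.5, lambda = NULL,
                                 nlambda = 100, lambda_min_ratio = 1e-4, ...) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("`y` must align with rows of `X`", call. = FALSE)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = mixing,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio, standardize = TRUE, ...)
  structure(list(lambda = fit$lambda, beta = as.matrix(fit$beta),
                 a0 = fit$a0, mixing = mixing, fit = fit,
                 X = X, y = y, family = "gaussian"),
            class = "penalized_path")
}

#' Train a CpG clock by elastic net
#'
#' Regresses phenotypic age on beta values over a penalty grid, selects the
#' penalty by cross-validated mean squared error (`"min"` rule by default)
#' and returns the sparse linear clock. Training-set mean betas are stored
#' with the clock for later imputation of missing CpGs.
#'
#' @param m A [methylation_matrix()] or bare beta matrix (samples x CpGs).
#' @param phenoages Response, years, one per sample.
#' @param mixing Elastic-net mixing (default 0.5).
#' @param folds,rule Cross-validation settings (defaults 10, `"min"`).
#' @param seed Seed for fold assignment.
#' @param universe Optional CpG universe to restrict to first.
#' @return An object of class `trained_clock`: `clock` (a
#'   [clock_coefficients()]), `lambda`, `cv`, `n`, `n_nonzero`.
#' @export
fit_elastic_net_clock <- function(m, phenoages, mixing = 0.5, folds = 10,
                                  rule = "min", seed = 1L, universe = NULL) {
  if (!is.null(universe)) m <- restrict_to_universe(m, universe)
  betas <- if (inherits(m, "methylation_matrix")) m$betas else as.matrix(m)
  if (anyNA(betas)) stop("beta matrix contains missing values", call. = FALSE)
  n <- nrow(betas)
  if (length(phenoages) != n) stop("`phenoages` must align with samples", call. = FALSE)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  tm <- stats::setNames(colMeans(betas), colnames(betas))
  if (stats::var(phenoages) == 0) {
    clock <- clock_coefficients(intercept = phenoages[1],
                                weights = stats::setNames(numeric(0), character(0)),
                                training_means = tm)
    return(structure(list(clock = clock, lambda = NA_real_, cv = NULL,
                          n = n, n_nonzero = 0L),
                     class = "trained_clock"))
  }
  path <- fit_elastic_net_path(betas, phenoages, mixing = mixing)
  sel <- cv_select_lambda(path, folds = folds, rule = rule, seed = seed)
  i <- which.min(abs(path$lambda - sel$lambda))
  w <- path$beta[, i]
  w <- w[w != 0]
  clock <- clock_coefficients(intercept = path$a0[i], weights = w,
                              training_means = tm)
  structure(list(clock = clock, lambda = sel$lambda, cv = sel,
                 n = n, n_nonzero = length(w)),
            class = "trained_clock")
}

#' @export
print.trained_clock <- function(x, ...) {
  cat(sprintf("Trained clock: %d samples, %d nonzero CpGs, lambda = %.4g\n",
              x$n, x$n_nonzero, x$lambda))
  invisible(x)
}

#' Restrict a methylation matrix to a CpG universe
#'
#' Column-subsets to the ids present in `universe`, in universe order (for
#' example the CpGs shared by the 27k, 450k and EPIC platforms). Duplicated
#' universe ids are dropped with a warning; an empty intersection is an
#' error. The number of universe ids absent from the matrix is reported via
#' a message and stored as attribute `n_dropped`.
#'
#' @param m A [methylation_matrix()] or bare beta matrix.
#' @param universe Character vector of CpG ids.
#' @return Same class as `m`, restricted.
#' @export
restrict_to_universe <- function(m, universe) {
  if (length(universe) == 0) stop("`universe` must be non-empty", call. = FALSE)
  if (anyDuplicated(universe)) {
    warning("duplicated CpG ids in universe; de-duplicating", call. = FALSE)
    universe <- universe[!duplicated(universe)]
  }
  cols <- if (inherits(m, "methylation_matrix")) m$cpg_ids else colnames(m)
  keep <- universe[universe %in% cols]
  if (length(keep) == 0) stop("universe shares no CpGs with the matrix", call. = FALSE)
  dropped <- length(universe) - length(keep)
  if (dropped > 0)
    message(dropped, " universe CpG(s) absent from the matrix; dropped")
  if (inherits(m, "methylation_matrix")) {
    out <- m
    out$betas <- m$betas[, keep, drop = FALSE]
    out$cpg_ids <- keep
  } else {
    out <- m[, keep, drop = FALSE]
  }
  attr(out, "n_dropped") <- dropped
  out
}
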