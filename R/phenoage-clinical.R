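# Clinical Phenotypic Age: nine routine blood biomarkers plus chronological
# age, combined through a Gompertz proportional-hazards mortality model and
# expressed in years as the age at which an average person carries the same
# fixed-horizon mortality risk.

# Registry of the panel variables, their units (SI-style convention used
# internally) and the published per-unit weights. CRP is stored raw and
# natural-logged at scoring time.
phenoage_biomarkers <- function() {
  data.frame(
    variable = c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
                 "mcv", "rdw", "alp", "wbc", "age"),
    unit = c("g/L", "umol/L", "mmol/L", "mg/dL (ln at scoring)", "%",
             "fL", "%", "U/L", "1000 cells/uL", "years"),
    weight = c(-0.0336, 0.0095, 0.1953, 0.0954, -0.0120,
               0.0268, 0.3306, 0.0019, 0.0554, 0.0804),
    stringsAsFactors = FALSE
  )
}

#' Published per-unit weights of the Phenotypic Age panel
#'
#' Named vector of log-hazard weights for the nine clinical biomarkers and
#' chronological age (albumin g/L, creatinine umol/L, glucose mmol/L,
#' ln CRP mg/dL, lymphocyte %, mean cell volume fL, red cell distribution
#' width %, alkaline phosphatase U/L, white cell count 1000/uL, age years).
#'
#' @return Named numeric vector of length 10.
#' @export
phenoage_weights <- function() {
  b <- phenoage_biomarkers()
  stats::setNames(b$weight, b$variable)
}

#' Validate a clinical biomarker panel
#'
#' @param panel Data frame with one row per subject and the columns named in
#'   [phenoage_weights()] (or at least those a given model needs).
#' @param required Character vector of column names that must be present.
#' @return The panel, invisibly, after validation.
#' @keywords internal
validate_panel <- function(panel, required = names(phenoage_weights())) {
  if (!is.data.frame(panel)) stop("`panel` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    stop("missing biomarker column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (v in required) {
    x <- panel[[v]]
    if (!is.numeric(x)) stop("column `", v, "` must be numeric", call. = FALSE)
    if (anyNA(x) || any(!is.finite(x)))
      stop("column `", v, "` contains missing or non-finite values", call. = FALSE)
  }
  if ("crp" %in% required && any(panel$crp <= 0))
    stop("`crp` must be strictly positive (its natural log enters the score)",
         call. = FALSE)
  # clinically implausible but finite values score with a warning, not an error
  if ("lymphocyte_pct" %in% required &&
      any(panel$lymphocyte_pct < 0 | panel$lymphocyte_pct > 100))
    warning("lymphocyte_pct outside [0, 100]; scoring anyway", call. = FALSE)
  conc <- intersect(c("albumin", "creatinine", "glucose", "mcv", "rdw", "alp", "wbc"),
                    required)
  for (v in conc)
    if (any(panel[[v]] <= 0))
      warning("non-positive `", v, "` values; scoring anyway", call. = FALSE)
  if ("age" %in% required && any(panel$age < 0))
    warning("negative ages; scoring anyway", call. = FALSE)
  invisible(panel)
}

#' Phenotypic Age model
#'
#' Bundles the Gompertz proportional-hazards mortality model (per-unit
#' weights, intercept, monthly slope `gamma`, risk horizon) with the
#' age-only Gompertz sub-model used to convert a horizon risk into years.
#'
#' @param weights Named numeric vector of per-unit weights; the name `crp`
#'   applies to the natural log of CRP.
#' @param intercept Dimensionless model intercept.
#' @param gamma Gompertz slope per month, positive.
#' @param horizon Risk horizon in months (default 120).
#' @param age_only An [age_only_gompertz()] model on the same time scale.
#' @return An object of class `phenoage_model`.
#' @seealso [phenoage_model_published()] for the packaged published
#'   coefficients, [build_phenoage_model()] to re-derive a model from data.
#' @export
phenoage_model <- function(weights, intercept, gamma, horizon = 120, age_only) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("`weights` must be a fully named numeric vector", call. = FALSE)
  if (anyDuplicated(names(weights))) stop("duplicate weight names", call. = FALSE)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  stopifnot(inherits(age_only, "age_only_gompertz"))
  structure(list(weights = weights, intercept = intercept, gamma = gamma,
                 horizon = horizon, age_only = age_only),
            class = "phenoage_model")
}

#' @export
print.phenoage_model <- function(x, ...) {
  cat("Phenotypic Age model (Gompertz proportional hazards)\n")
  cat(sprintf("  %d weighted variables; intercept = %.4g; gamma = %.6g per month; horizon = %g months\n",
              length(x$weights), x$intercept, x$gamma, x$horizon))
  print(round(x$weights, 4))
  invisible(x)
}

#' Published Phenotypic Age coefficients
#'
#' Loads the packaged published model: the ten per-unit weights, the model
#' intercept, the monthly Gompertz slope, the 120-month horizon, and the
#' age-only conversion constants, from a coefficients file shipped with the
#' package. The age-only sub-model is stored as the triplet
#' (offset, scale, const) of the conversion
#' `age = offset + log(const * (-log(1 - M))) / scale`, from which the
#' `(b0, b_age)` parameterization is derived exactly.
#'
#' @param path Optional path to an alternative coefficients file in the
#'   same two-column layout (`constant`, `value` rows plus `weight.<var>`
#'   rows).
#' @return A [phenoage_model()].
#' @export
phenoage_model_published <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phenoage_published.csv", package = "phenoclock",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  val <- stats::setNames(tab$value, tab$constant)
  wn <- grep("^weight\\.", names(val), value = TRUE)
  weights <- stats::setNames(as.numeric(val[wn]), sub("^weight\\.", "", wn))
  gamma <- as.numeric(val[["gamma"]])
  horizon <- as.numeric(val[["horizon"]])
  # derive (b0, b_age) so the closed-form conversion reproduces
  # offset + log(const * (-log(1-M))) / scale exactly
  b_age <- as.numeric(val[["ao.scale"]])
  b0 <- log(gamma / expm1(gamma * horizon)) - log(as.numeric(val[["ao.const"]])) -
    as.numeric(val[["ao.offset"]]) * b_age
  phenoage_model(weights = weights,
                 intercept = as.numeric(val[["intercept"]]),
                 gamma = gamma, horizon = horizon,
                 age_only = age_only_gompertz(b0, b_age, gamma, horizon))
}

#' Linear predictor of the mortality model
#'
#' `xb = intercept + sum_k weight_k * value_k`, with CRP entered as its
#' natural logarithm. Errors if any required biomarker column is absent or
#' missing; out-of-range but finite values score with a warning.
#'
#' @param panel Data frame of biomarker values, one row per subject.
#' @param model A [phenoage_model()].
#' @return Numeric vector of linear predictors, one per row of `panel`.
#' @export
linear_predictor <- function(panel, model) {
  stopifnot(inherits(model, "phenoage_model"))
  validate_panel(panel, required = names(model$weights))
  xb <- rep(model$intercept, nrow(panel))
  for (v in names(model$weights)) {
    x <- panel[[v]]
    if (v == "crp") x <- log(x)
    xb <- xb + model$weights[[v]] * x
  }
  xb
}

#' Phenotypic Age of a clinical biomarker panel
#'
#' Chains the linear predictor, the Gompertz horizon mortality risk and the
#' risk-to-years conversion, returning all three intermediates.
#'
#' @inheritParams linear_predictor
#' @return Data frame with columns `xb`, `mortality_score` and `phenoage`
#'   (years), one row per subject.
#' @examples
#' panel <- data.frame(albumin = 42, creatinine = 75, glucose = 5.2,
#'                     crp = 0.15, lymphocyte_pct = 31, mcv = 89, rdw = 12.8,
#'                     alp = 65, wbc = 6.1, age = 55)
#' phenotypic_age(panel, phenoage_model_published())
#' @export
phenotypic_age <- function(panel, model) {
  xb <- linear_predictor(panel, model)
  M <- gompertz_mortality_risk(xb, model$horizon, model$gamma)
  data.frame(xb = xb,
             mortality_score = M,
             phenoage = risk_to_phenoage(M, model$age_only))
}

#' Convert a US-conventional panel to the model's units
#'
#' Albumin g/dL to g/L (x10), creatinine mg/dL to umol/L (x88.4017),
#' glucose mg/dL to mmol/L (/18.016); all other columns pass through.
#'
#' @param panel Data frame in US-conventional units.
#' @param direction `"to_si"` (default) or `"to_conventional"` for the
#'   exact inverse.
#' @return The converted data frame.
#' @export
convert_units <- function(panel, direction = c("to_si", "to_conventional")) {
  direction <- match.arg(direction)
  if (!is.data.frame(panel)) stop("`panel` must be a data frame", call. = FALSE)
  fac <- c(albumin = 10, creatinine = 88.4017, glucose = 1 / 18.016)
  for (v in names(fac)) {
    if (!v %in% names(panel)) next
    x <- panel[[v]]
    if (any(!is.finite(x))) stop("non-finite `", v, "`", call. = FALSE)
    if (any(x < 0)) stop("negative `", v, "` concentration", call. = FALSE)
    panel[[v]] <- if (direction == "to_si") x * fac[[v]] else x / fac[[v]]
  }
  panel
}
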