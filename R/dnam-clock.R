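# Applying a linear methylation clock: DNAm phenotypic age scores,
# age-acceleration residuals, and coefficient-file I/O in the standard
# two-column (CpG, Weight) layout with a reserved Intercept row.

#' Methylation beta matrix container
#'
#' @param betas Numeric matrix, samples in rows, CpGs in columns, values in
#'   `[0, 1]` (violations up to 1e-6 are clamped; larger ones error) or `NA`
#'   for missing markers. Column names are CpG ids, row names sample ids.
#' @param ages Optional chronological ages (years), one per sample.
#' @param time,event,cause Optional survival follow-up (months), 0/1 event
#'   indicator and cause label per sample.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, ages = NULL, time = NULL, event = NULL,
                               cause = NULL) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("`betas` must be a numeric matrix (samples x CpGs)", call. = FALSE)
  if (is.null(colnames(betas))) stop("`betas` needs CpG column names", call. = FALSE)
  betas <- clamp_betas(betas)
  n <- nrow(betas)
  for (nm in c("ages", "time", "event")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop("`", nm, "` must have one value per sample", call. = FALSE)
  }
  structure(list(betas = betas, sample_ids = rownames(betas),
                 cpg_ids = colnames(betas), ages = ages,
                 time = time, event = event, cause = cause),
            class = "methylation_matrix")
}

clamp_betas <- function(betas, tol = 1e-6) {
  bad <- !is.na(betas) & (betas < -tol | betas > 1 + tol)
  if (any(bad))
    stop(sum(bad), " beta value(s) outside [0, 1] by more than ", tol, call. = FALSE)
  pmin(pmax(betas, 0), 1)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix: %d samples x %d CpGs%s%s\n",
              nrow(x$betas), ncol(x$betas),
              if (!is.null(x$ages)) ", with ages" else "",
              if (!is.null(x$time)) ", with survival follow-up" else ""))
  invisible(x)
}

#' Linear clock coefficients
#'
#' @param intercept Intercept in years.
#' @param weights Named numeric vector, years per beta unit, names are
#'   unique CpG ids.
#' @param training_means Optional named vector of training-set mean betas
#'   used to impute missing clock CpGs.
#' @return An object of class `clock_coefficients`.
#' @export
clock_coefficients <- function(intercept, weights, training_means = NULL) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("`weights` must be named by CpG id", call. = FALSE)
  if (anyDuplicated(names(weights)))
    stop("duplicate CpG id in clock weights: ",
         names(weights)[anyDuplicated(names(weights))], call. = FALSE)
  if (any(!is.finite(weights)) || !is.finite(intercept))
    stop("clock coefficients must be finite", call. = FALSE)
  structure(list(intercept = intercept, weights = weights,
                 training_means = training_means),
            class = "clock_coefficients")
}

#' @export
print.clock_coefficients <- function(x, ...) {
  cat(sprintf("Linear methylation clock: intercept %.3f years, %d CpG weights\n",
              x$intercept, length(x$weights)))
  invisible(x)
}

#' Apply a linear clock to a methylation matrix
#'
#' `score_i = intercept + sum_j weight_j * beta_ij`. Clock CpGs absent from
#' the matrix (or `NA` in a sample) are an error under the `"error"` policy,
#' or imputed from the clock's training means under
#' `"impute_training_mean"`, capped at `max_imputed_fraction` of the clock
#' CpGs per sample. Column order of the matrix never affects scores.
#'
#' @param m A [methylation_matrix()] or bare numeric matrix (samples x CpGs).
#' @param clock A [clock_coefficients()].
#' @param missing_policy `"error"` or `"impute_training_mean"`.
#' @param max_imputed_fraction Error if a larger fraction of clock CpGs must
#'   be imputed (default 0.05).
#' @return An object of class `clock_output`: a list with `dnam_phenoage`
#'   (years per sample), `acceleration` (residual on age, or `NULL` when the
#'   matrix carries no ages), `n_missing_cpgs` and `imputed_fraction`.
#' @export
apply_clock <- function(m, clock, missing_policy = c("error", "impute_training_mean"),
                        max_imputed_fraction = 0.05) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_coefficients"))
  ages <- NULL
  if (inherits(m, "methylation_matrix")) {
    ages <- m$ages
    betas <- m$betas
  } else if (is.matrix(m)) {
    betas <- clamp_betas(m)
  } else stop("`m` must be a methylation_matrix or numeric matrix", call. = FALSE)
  need <- names(clock$weights)
  absent <- setdiff(need, colnames(betas))
  sub <- matrix(NA_real_, nrow(betas), length(need),
                dimnames = list(rownames(betas), need))
  present <- intersect(need, colnames(betas))
  sub[, present] <- betas[, present, drop = FALSE]
  n_na <- sum(is.na(sub))
  imputed_fraction <- n_na / length(sub)
  if (n_na > 0) {
    if (missing_policy == "error")
      stop("clock CpGs missing from the matrix (", length(absent),
           " absent column(s), ", n_na, " missing value(s)); ",
           "use missing_policy = \"impute_training_mean\"", call. = FALSE)
    tm <- clock$training_means
    need_tm <- unique(need[colSums(is.na(sub)) > 0])
    if (is.null(tm) || !all(need_tm %in% names(tm)))
      stop("training means unavailable for missing clock CpG(s): ",
           paste(utils::head(setdiff(need_tm, names(tm)), 5), collapse = ", "),
           call. = FALSE)
    if (imputed_fraction > max_imputed_fraction)
      stop(sprintf("imputed fraction %.3f exceeds the cap %.3f",
                   imputed_fraction, max_imputed_fraction), call. = FALSE)
    for (j in need_tm) sub[is.na(sub[, j]), j] <- tm[[j]]
  }
  scores <- drop(clock$intercept + sub %*% clock$weights)
  accel <- NULL
  if (!is.null(ages) && length(unique(ages)) > 1L && length(ages) >= 3L)
    accel <- age_acceleration(scores, ages)
  structure(list(dnam_phenoage = scores, acceleration = accel,
                 n_missing_cpgs = length(absent),
                 imputed_fraction = imputed_fraction),
            class = "clock_output")
}

#' @export
print.clock_output <- function(x, ...) {
  cat(sprintf("Clock output: %d samples, mean DNAm phenotypic age %.1f years",
              length(x$dnam_phenoage), mean(x$dnam_phenoage)))
  if (x$n_missing_cpgs > 0)
    cat(sprintf("; %d clock CpGs imputed (fraction %.3f)",
                x$n_missing_cpgs, x$imputed_fraction))
  cat("\n")
  invisible(x)
}

#' Age-acceleration residuals
#'
#' Residuals from the least-squares regression of clock scores on
#' chronological age (with intercept). By construction the residuals have
#' mean zero and zero correlation with age: positive values mark samples
#' epigenetically older than expected for their age.
#'
#' @param scores Clock scores, years.
#' @param ages Chronological ages, years; must not be constant.
#' @return Residuals in years, same order as the input.
#' @export
age_acceleration <- function(scores, ages) {
  if (length(scores) != length(ages))
    stop("`scores` and `ages` must align", call. = FALSE)
  if (length(scores) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(ages) == 0) stop("`ages` must not be constant", call. = FALSE)
  stats::residuals(stats::lm(scores ~ ages))
}

#' Read / write clock coefficient files
#'
#' Delimited text with a header and columns `CpG`, `Weight` (optionally
#' `TrainingMean`); the intercept is stored as the reserved pseudo-CpG row
#' `Intercept`. The round trip `write_clock()` then `read_clock()` is
#' lossless.
#'
#' @param path File path.
#' @return `read_clock()` returns a [clock_coefficients()];
#'   `write_clock()` returns `path` invisibly.
#' @export
read_clock <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("CpG", "Weight") %in% names(tab)))
    stop("clock file needs columns `CpG` and `Weight`", call. = FALSE)
  if (!is.numeric(tab$Weight))
    stop("non-numeric weight in clock file", call. = FALSE)
  dup <- tab$CpG[duplicated(tab$CpG)]
  if (length(dup))
    stop("duplicate CpG row(s) in clock file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  ii <- tab$CpG == "Intercept"
  if (sum(ii) != 1L) stop("clock file needs exactly one Intercept row", call. = FALSE)
  tm <- NULL
  if ("TrainingMean" %in% names(tab)) {
    tm <- stats::setNames(tab$TrainingMean[!ii], tab$CpG[!ii])
    if (all(is.na(tm))) tm <- NULL
  }
  clock_coefficients(intercept = tab$Weight[ii],
                     weights = stats::setNames(tab$Weight[!ii], tab$CpG[!ii]),
                     training_means = tm)
}

#' @rdname read_clock
#' @param clock A [clock_coefficients()].
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_coefficients"))
  tab <- data.frame(CpG = c("Intercept", names(clock$weights)),
                    Weight = c(clock$intercept, unname(clock$weights)))
  if (!is.null(clock$training_means)) {
    tm <- clock$training_means[names(clock$weights)]
    tab$TrainingMean <- c(NA_real_, unname(tm))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
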