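# Delimited-text I/O for the objects the pipeline exchanges: biomarker
# panels, phenotypic-age score tables, beta matrices (with orientation
# auto-detection), and synthetic cohorts with a ground-truth sidecar.

#' Read a biomarker panel table
#'
#' Delimited text with a header naming the panel variables (see
#' [phenoage_weights()]); an optional `id` column is preserved.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame ready for [phenotypic_age()].
#' @export
read_biomarker_panels <- function(path, sep = ",") {
  panel <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  validate_panel(panel, required = intersect(names(phenoage_weights()), names(panel)))
  panel
}

#' Write phenotypic-age scores
#'
#' One row per subject: `id`, `xb`, `mortality_score`, `phenoage_years`.
#'
#' @param scores Data frame from [phenotypic_age()].
#' @param path Output path.
#' @param id Optional subject ids.
#' @export
write_phenoage_scores <- function(scores, path, id = NULL) {
  out <- data.frame(id = if (is.null(id)) seq_len(nrow(scores)) else id,
                    xb = scores$xb, mortality_score = scores$mortality_score,
                    phenoage_years = scores$phenoage)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a methylation beta matrix
#'
#' Delimited text whose first column holds ids. Orientation is
#' auto-detected: if the first-column ids look like CpG ids (`cg` followed
#' by digits) rows are taken as CpGs and the matrix is transposed to the
#' in-memory samples-x-CpGs convention, with a message.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A [methylation_matrix()] (without ages or survival columns).
#' @export
read_beta_matrix <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab)
  if (all(grepl("^cg[0-9]+$", rownames(mat)))) {
    message("rows look like CpG ids; transposing to samples x CpGs")
    mat <- t(mat)
  }
  methylation_matrix(mat)
}

#' Write a methylation beta matrix
#'
#' @param m A [methylation_matrix()] or bare matrix (samples x CpGs).
#' @param path Output path.
#' @export
write_beta_matrix <- function(m, path) {
  betas <- if (inherits(m, "methylation_matrix")) m$betas else m
  utils::write.csv(data.frame(id = rownames(betas), betas,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort with its ground-truth sidecar
#'
#' The observable table (biomarkers + survival) goes to `cohort.csv`; the
#' hidden truth (`true_xb` and the generator parameters) to
#' `cohort_truth.csv` and `cohort_spec.csv` alongside.
#'
#' @param cohort A `clinical_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort[, setdiff(names(cohort), "true_xb")]
  utils::write.csv(obs, file.path(dir, "cohort.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = cohort$id, true_xb = cohort$true_xb),
                   file.path(dir, "cohort_truth.csv"), row.names = FALSE, quote = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    flat <- c(n_subjects = spec$n_subjects, seed = spec$seed,
              age_low = spec$age_range[1], age_high = spec$age_range[2],
              n_biomarkers_total = spec$n_biomarkers_total,
              gompertz_gamma = spec$gompertz_gamma,
              gompertz_intercept = spec$gompertz_intercept,
              followup_months = spec$followup_months,
              aging_cause_prob = spec$aging_cause_prob,
              stats::setNames(spec$true_weights,
                              paste0("weight.", names(spec$true_weights))))
    utils::write.csv(data.frame(constant = names(flat), value = unname(flat)),
                     file.path(dir, "cohort_spec.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
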