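#' Exclude measures from an immune matrix
#'
#' Removes (a) explicitly listed measures and (b) measures whose fraction of
#' missing values exceeds `max_missing_fraction`.  Every removal is recorded
#' in the matrix log with its reason.  In the motivating study a handful of
#' measures were dropped during pre-processing; the identity of such
#' measures is carried by configuration rather than hard-coded.
#'
#' @param m an [immune_matrix()].
#' @param max_missing_fraction measures missing more than this fraction of
#'   subjects are removed (default 0.5).
#' @param explicit_exclusions character vector of measure ids to drop
#'   unconditionally.
#' @return a reduced `immune_matrix`.  Errors if fewer than 3 measures would
#'   remain (correlation analysis is meaningless below that).
#' @export
exclude_measures <- function(m, max_missing_fraction = 0.5,
                             explicit_exclusions = character()) {
  stopifnot(inherits(m, "immune_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in [0, 1]")
  }
  unknown <- setdiff(explicit_exclusions, measure_ids(m))
  if (length(unknown) > 0) {
    stop("explicit exclusions not present: ", paste(unknown, collapse = ", "))
  }
  miss_frac <- colMeans(m$missing_mask)
  by_frac <- measure_ids(m)[miss_frac > max_missing_fraction]
  drop <- union(explicit_exclusions, by_frac)
  keep <- setdiff(measure_ids(m), drop)
  if (length(keep) < 3) {
    stop("measure exclusion would leave fewer than 3 measures")
  }
  entries <- c(
    sprintf("excluded measure %s (explicit)", explicit_exclusions),
    sprintf("excluded measure %s (missing fraction %.2f > %.2f)",
            by_frac, miss_frac[by_frac], max_missing_fraction)
  )
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  out$missing_mask <- m$missing_mask[, keep, drop = FALSE]
  out$imputed_mask <- m$imputed_mask[, keep, drop = FALSE]
  out$annotations <- m$annotations[m$annotations$measure_id %in% keep, ]
  rownames(out$annotations) <- NULL
  out$log <- c(m$log, entries)
  out
}

#' Exclude subjects missing an entire measure battery
#'
#' Removes every subject for which all measures of the given category are
#' missing.  This mirrors excluding animals whose whole in vitro cytokine
#' response (CR) battery was not assayed; subjects missing only part of the
#' battery are retained.
#'
#' @param m an [immune_matrix()].
#' @param category the category whose complete absence disqualifies a
#'   subject (default `"CR"`).
#' @return a reduced `immune_matrix`.  A warning (not an error) is issued if
#'   fewer than 10 subjects remain, since correlations become unstable.
#' @export
exclude_subjects_missing_battery <- function(m, category = "CR") {
  stopifnot(inherits(m, "immune_matrix"))
  cols <- m$annotations$measure_id[m$annotations$category == category]
  if (length(cols) == 0) stop("category not present: ", category)
  all_missing <- rowSums(!m$missing_mask[, cols, drop = FALSE]) == 0
  keep <- !all_missing
  if (sum(keep) < 10) {
    warning("fewer than 10 subjects remain; correlations will be unstable")
  }
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$missing_mask <- m$missing_mask[keep, , drop = FALSE]
  out$imputed_mask <- m$imputed_mask[keep, , drop = FALSE]
  out$log <- c(m$log,
               sprintf("excluded %d/%d subjects missing the whole %s battery",
                       sum(all_missing), length(all_missing), category))
  out
}

#' Mean-impute missing values
#'
#' Replaces each missing cell by the mean of the measure's observed values
#' within this data set.  Each column's mean is exactly invariant under the
#' operation, and imputation never increases a column's variance.
#' Imputation is always per data set: wild and laboratory matrices must be
#' imputed separately, never pooled.
#'
#' @param m an [immune_matrix()].
#' @return an `immune_matrix` with no missing cells; `imputed_mask` marks
#'   the filled cells.  Errors, naming the measure, if any measure has no
#'   observed value (its mean is undefined).
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "immune_matrix"))
  n_obs <- colSums(!m$missing_mask)
  if (any(n_obs == 0)) {
    stop("cannot impute measure(s) with no observed values: ",
         paste(measure_ids(m)[n_obs == 0], collapse = ", "))
  }
  out <- m
  if (any(m$missing_mask)) {
    mu <- colMeans(m$values, na.rm = TRUE)
    fill <- matrix(rep(mu, each = nrow(m$values)), nrow(m$values))
    out$values[m$missing_mask] <- fill[m$missing_mask]
    out$imputed_mask <- m$imputed_mask | m$missing_mask
    out$missing_mask[] <- FALSE
    out$log <- c(m$log, sprintf("mean-imputed %d cells", sum(m$missing_mask)))
  }
  out
}

#' Standard preprocessing: exclude measures, exclude subjects, impute
#'
#' Applies the preprocessing steps in the order: explicit measure
#' exclusions, then [exclude_subjects_missing_battery()], then the
#' missing-fraction measure rule, then [impute_mean()].  The fraction rule
#' runs *after* subject exclusion deliberately: when a large fraction of
#' subjects misses the whole battery (realistically ~half), judging
#' battery measures on the full cohort would push every one of them past
#' the threshold and delete the battery the analysis is about; measure
#' quality is therefore assessed on the retained cohort.
#'
#' @param m an [immune_matrix()].
#' @inheritParams exclude_measures
#' @inheritParams exclude_subjects_missing_battery
#' @param report_path optional path; if given, the report is written as JSON.
#' @return list with `matrix` (processed `immune_matrix`) and `report`
#'   (list: removed measures with reasons, removed subjects, imputation
#'   counts per measure).
#' @export
preprocess <- function(m, max_missing_fraction = 0.5,
                       explicit_exclusions = character(),
                       category = "CR", report_path = NULL) {
  before_meas <- measure_ids(m)
  m1 <- exclude_measures(m, max_missing_fraction = 1,
                         explicit_exclusions = explicit_exclusions)
  before_subj <- subject_ids(m1)
  m2 <- exclude_subjects_missing_battery(m1, category)
  m3 <- exclude_measures(m2, max_missing_fraction = max_missing_fraction)
  m4 <- impute_mean(m3)
  report <- list(
    removed_measures = setdiff(before_meas, measure_ids(m3)),
    removal_log = setdiff(m3$log, m$log),
    removed_subjects = setdiff(before_subj, subject_ids(m2)),
    n_subjects = nrow(m4$values),
    n_measures = ncol(m4$values),
    imputed_per_measure = as.list(colSums(m4$imputed_mask))
  )
  if (!is.null(report_path)) write_json_file(report, report_path)
  list(matrix = m4, report = report)
}
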