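#' Immune phenotype matrix
#'
#' Container for a subjects x immune-measures matrix with a missingness
#' mask, an imputation mask, and per-measure category annotations.  This is
#' the input type of the preprocessing, correlation and PCA stages.
#'
#' @param values numeric matrix, subjects in rows, measures in columns, with
#'   `NA` marking missing cells.  Row and column names are the subject and
#'   measure identifiers (generated if absent).
#' @param annotations data.frame with columns `measure_id`, `category` and
#'   optionally `subcategory`, one row per measure (order is matched to the
#'   columns of `values` by `measure_id`).
#' @param environment label for the data set (e.g. `"wild"` or `"lab"`);
#'   imputation and correlation are always per-environment, never pooled.
#' @return an object of class `immune_matrix`: a list with elements
#'   `values`, `missing_mask` (TRUE where the value is currently missing),
#'   `imputed_mask` (TRUE where a missing value has been mean-filled),
#'   `annotations`, `environment` and `log` (a character record of the
#'   preprocessing steps applied).
#' @export
#' @examples
#' vals <- matrix(c(1, NA, 3, 4, 5, 6), nrow = 3,
#'                dimnames = list(NULL, c("IgG", "IgE")))
#' ann <- data.frame(measure_id = c("IgG", "IgE"), category = "Antibody")
#' immune_matrix(vals, ann)
immune_matrix <- function(values, annotations, environment = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("m%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate measure ids")
  if (anyDuplicated(rownames(values))) stop("duplicate subject ids")
  annotations <- as.data.frame(annotations)
  if (!all(c("measure_id", "category") %in% names(annotations))) {
    stop("`annotations` needs columns measure_id and category")
  }
  if (!"subcategory" %in% names(annotations)) {
    annotations$subcategory <- NA_character_
  }
  if (anyDuplicated(annotations$measure_id)) {
    stop("every measure_id must have exactly one category")
  }
  missing_ann <- setdiff(colnames(values), annotations$measure_id)
  if (length(missing_ann) > 0) {
    stop("measures without annotation: ", paste(missing_ann, collapse = ", "))
  }
  annotations <- annotations[match(colnames(values), annotations$measure_id),
                             c("measure_id", "category", "subcategory")]
  rownames(annotations) <- NULL
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) stop("non-finite values present where not missing")
  structure(list(
    values = values,
    missing_mask = is.na(values),
    imputed_mask = matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values)),
    annotations = annotations,
    environment = environment,
    log = character()
  ), class = "immune_matrix")
}

#' @export
print.immune_matrix <- function(x, ...) {
  cat(sprintf("immune_matrix: %d subjects x %d measures (%s)\n",
              nrow(x$values), ncol(x$values), x$environment))
  cat(sprintf("  categories: %s\n",
              paste(sprintf("%s=%d", names(table(x$annotations$category)),
                            table(x$annotations$category)), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%), imputed: %d\n",
              sum(x$missing_mask),
              100 * mean(x$missing_mask), sum(x$imputed_mask)))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname immune_matrix
#' @param x an `immune_matrix`.
#' @export
measure_ids <- function(x) colnames(x$values)

#' @rdname immune_matrix
#' @export
subject_ids <- function(x) rownames(x$values)

#' Read / write an immune matrix as TSV
#'
#' The matrix file has subjects in rows, a `subject_id` first column and one
#' column per measure; missing cells are the literal string `NA`.  The
#' annotation file has columns `measure_id`, `category`, `subcategory` and
#' optionally `planted_block` (ignored on read into the matrix itself).
#'
#' @param matrix_path path of the matrix TSV.
#' @param annotation_path path of the measure-annotation TSV.
#' @param environment environment label to attach.
#' @return `read_immune_matrix` returns an `immune_matrix`;
#'   `write_immune_matrix` returns the matrix path invisibly.
#' @export
read_immune_matrix <- function(matrix_path, annotation_path,
                               environment = "unspecified") {
  df <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") stop("first column must be subject_id")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df$subject_id)
  ann <- read.delim(annotation_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  immune_matrix(vals, ann, environment = environment)
}

#' @rdname read_immune_matrix
#' @param m an `immune_matrix` to write.
#' @export
write_immune_matrix <- function(m, matrix_path, annotation_path) {
  vals <- m$values
  vals[m$missing_mask] <- NA
  df <- data.frame(subject_id = rownames(vals), vals, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write.table(m$annotations, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(matrix_path)
}
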