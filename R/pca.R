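#' Principal component analysis of an immune matrix
#'
#' Centered PCA of the (fully imputed) subjects x measures matrix.  With
#' `scaling = "covariance"` (the default) measures are not standardized, so
#' a single measure with enormous variance - such as an absolute cell count
#' among percentages and concentrations - can dominate the first component;
#' `scaling = "correlation"` standardizes each measure first.  Component
#' signs are canonicalized (the largest-magnitude loading of each component
#' is made positive) so outputs are bit-stable.
#'
#' @param m an [immune_matrix()] with no missing values, at least 2
#'   measures and at least 2 subjects.
#' @param scaling `"covariance"` or `"correlation"`.
#' @return an object of class `pca_result`: list with `variance_shares`
#'   (eigenvalue proportions, non-increasing, summing to 1), `loadings`
#'   (measures x components, orthonormal columns), `scores` (subjects x
#'   components), `removed_measures` and `scaling`.
#' @export
run_pca <- function(m, scaling = c("covariance", "correlation")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(m, "immune_matrix"))
  if (any(m$missing_mask)) stop("matrix has missing cells; impute first")
  if (ncol(m$values) < 2) stop("need at least 2 measures")
  if (nrow(m$values) < 2) stop("need at least 2 subjects")
  if (scaling == "correlation") {
    v <- apply(m$values, 2, stats::var)
    if (any(v == 0)) {
      stop("zero-variance measure(s) under correlation scaling: ",
           paste(measure_ids(m)[v == 0], collapse = ", "))
    }
  }
  pc <- stats::prcomp(m$values, center = TRUE,
                      scale. = (scaling == "correlation"))
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(
    variance_shares = ev / sum(ev),
    loadings = loadings,
    scores = scores,
    removed_measures = character(),
    scaling = scaling
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$variance_shares))
  cat(sprintf("pca_result (%s scaling): %d components\n", x$scaling,
              length(x$variance_shares)))
  cat("  variance shares:",
      paste(sprintf("%.3f", x$variance_shares[1:k]), collapse = ", "),
      if (length(x$variance_shares) > k) "..." else "", "\n")
  if (length(x$removed_measures)) {
    cat("  removed before this run:",
        paste(x$removed_measures, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detect a dominant outlier measure in a PCA
#'
#' Flags the measure whose squared PC1 loading exceeds
#' `dominance_threshold` when PC1's variance share also exceeds it - the
#' automated analogue of spotting, by eye, that one high-variance measure
#' (e.g. a raw spleen-cell count) is carrying essentially all the variance.
#'
#' @param r a [run_pca()] result.
#' @param dominance_threshold proportion in `(0, 1]` (default 0.9).
#' @return the measure id, or `NA_character_` if none qualifies.
#' @export
detect_outlier_measure <- function(r, dominance_threshold = 0.9) {
  stopifnot(inherits(r, "pca_result"))
  if (r$variance_shares[1] <= dominance_threshold) return(NA_character_)
  l2 <- r$loadings[, 1]^2
  if (max(l2) <= dominance_threshold) return(NA_character_)
  rownames(r$loadings)[which.max(l2)]
}

#' PCA with iterative outlier-measure removal
#'
#' Runs PCA, removes the flagged dominant measure (if any), re-runs, and
#' repeats until nothing is flagged or `max_removals` is reached.  All runs
#' are returned in order, so the "99.6% then 67%" style collapse of PC1
#' after removing one dominant measure is directly inspectable.
#'
#' @inheritParams run_pca
#' @inheritParams detect_outlier_measure
#' @param max_removals maximum number of measures to remove (>= 0).
#' @return list of `pca_result`s, each recording the measures removed
#'   before that run in `removed_measures`.
#' @export
pca_with_outlier_removal <- function(m, scaling = c("covariance",
                                                    "correlation"),
                                     dominance_threshold = 0.9,
                                     max_removals = 1L) {
  scaling <- match.arg(scaling)
  if (max_removals < 0) stop("max_removals must be >= 0")
  removed <- character()
  runs <- list()
  cur <- m
  repeat {
    r <- run_pca(cur, scaling)
    r$removed_measures <- removed
    runs[[length(runs) + 1]] <- r
    if (length(removed) >= max_removals) break
    out <- detect_outlier_measure(r, dominance_threshold)
    if (is.na(out)) break
    removed <- c(removed, out)
    keep <- setdiff(measure_ids(cur), out)
    cur$values <- cur$values[, keep, drop = FALSE]
    cur$missing_mask <- cur$missing_mask[, keep, drop = FALSE]
    cur$imputed_mask <- cur$imputed_mask[, keep, drop = FALSE]
    cur$annotations <- cur$annotations[cur$annotations$measure_id %in% keep, ]
  }
  runs
}

#' Write a PCA result (variance shares, loadings, scores, summary JSON)
#' @param r a `pca_result`.
#' @param dir output directory.
#' @param prefix file-name prefix (default "pca").
#' @export
write_pca_result <- function(r, dir, prefix = "pca") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(component = seq_along(r$variance_shares),
                         variance_share = r$variance_shares),
              file.path(dir, paste0(prefix, "_variance_shares.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(measure_id = rownames(r$loadings), r$loadings,
                         check.names = FALSE),
              file.path(dir, paste0(prefix, "_loadings.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subject_id = rownames(r$scores), r$scores,
                         check.names = FALSE),
              file.path(dir, paste0(prefix, "_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(list(scaling = r$scaling,
                       removed_measures = r$removed_measures,
                       variance_shares = r$variance_shares),
                  file.path(dir, paste0(prefix, "_summary.json")))
  invisible(dir)
}
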