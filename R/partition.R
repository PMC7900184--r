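#' Node partition
#'
#' A community assignment for a set of named nodes.  `NA` is the
#' distinguished "unassigned" state (nodes that consensus clustering could
#' not place stably).  After canonicalization, community ids are the
#' contiguous integers `0..K-1`, ordered by decreasing community size with
#' ties broken by the smallest member position.
#'
#' @param assignment named vector of community labels; `NA` = unassigned.
#' @param source one of `"single_run"`, `"consensus"`, `"planted"`,
#'   `"external"`.
#' @param canonicalize relabel communities canonically (default TRUE).
#' @return an object of class `node_partition`: a named integer vector with
#'   attributes `source` and `n_communities`.
#' @export
#' @examples
#' node_partition(c(a = 1, b = 1, c = 2, d = NA), source = "external")
node_partition <- function(assignment,
                           source = c("external", "single_run", "consensus",
                                      "planted"),
                           canonicalize = TRUE) {
  source <- match.arg(source)
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("`assignment` must be fully named by node id")
  }
  if (anyDuplicated(names(assignment))) {
    stop("every node must appear exactly once")
  }
  labels <- as.vector(assignment)
  if (canonicalize) {
    labels <- canonical_labels(labels)
  } else {
    labels <- as.integer(factor(labels))  # just make integer codes
  }
  out <- stats::setNames(labels, names(assignment))
  attr(out, "source") <- source
  attr(out, "n_communities") <- length(unique(labels[!is.na(labels)]))
  class(out) <- "node_partition"
  out
}

# Relabel community codes 0..K-1 by decreasing size, ties by smallest
# member position; NA stays NA.
canonical_labels <- function(labels) {
  assigned <- !is.na(labels)
  if (!any(assigned)) return(rep(NA_integer_, length(labels)))
  codes <- as.integer(factor(labels[assigned]))
  sizes <- tabulate(codes)
  first_pos <- vapply(seq_along(sizes),
                      function(k) min(which(codes == k)), integer(1))
  rank <- order(-sizes, first_pos)
  new_code <- integer(length(sizes))
  new_code[rank] <- seq_along(sizes) - 1L
  out <- rep(NA_integer_, length(labels))
  out[assigned] <- new_code[codes]
  out
}

#' @export
print.node_partition <- function(x, ...) {
  k <- attr(x, "n_communities")
  cat(sprintf("node_partition (%s): %d nodes, %d communities, %d unassigned\n",
              attr(x, "source"), length(x), k, sum(is.na(x))))
  if (k > 0) {
    sz <- sort(table(unclass(x)), decreasing = TRUE)
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname node_partition
#' @param p a `node_partition`.
#' @export
n_communities <- function(p) attr(p, "n_communities")

#' @rdname node_partition
#' @export
assigned_nodes <- function(p) names(p)[!is.na(unclass(p))]

#' Members of each community
#' @param p a `node_partition`.
#' @return named list mapping community id to a character vector of node ids
#'   (unassigned nodes are omitted).
#' @export
community_members <- function(p) {
  v <- unclass(p)
  keep <- !is.na(v)
  split(names(p)[keep], v[keep])
}

#' Read / write a partition as TSV
#'
#' Two columns: `node_id` and `community_id`, with unassigned nodes written
#' as the literal string `UNASSIGNED`.
#'
#' @param p a `node_partition`; `path` a file path.
#' @param path file path.
#' @param source source label to attach on read.
#' @export
write_partition <- function(p, path) {
  comm <- ifelse(is.na(unclass(p)), "UNASSIGNED", as.character(unclass(p)))
  write.table(data.frame(node_id = names(p), community_id = comm),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, source = "external") {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character"))
  v <- suppressWarnings(as.integer(df$community_id))
  v[df$community_id == "UNASSIGNED"] <- NA_integer_
  node_partition(stats::setNames(v, df$node_id), source = source)
}
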