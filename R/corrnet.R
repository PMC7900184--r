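#' Pearson correlation matrix of an immune matrix
#'
#' Standard Pearson coefficients between all measure pairs, with each
#' subject as a sample.  Requires a fully imputed matrix (no missing
#' cells), at least 3 subjects, and nonzero variance in every measure.
#'
#' @param m an [immune_matrix()] with no missing values.
#' @return an object of class `corr_matrix`: list with `r` (symmetric
#'   matrix, unit diagonal), `measure_ids` and `n_samples`.
#' @export
pearson_matrix <- function(m) {
  stopifnot(inherits(m, "immune_matrix"))
  if (any(m$missing_mask)) {
    stop("matrix has missing cells; run impute_mean() first")
  }
  if (nrow(m$values) < 3) stop("need at least 3 subjects")
  v <- apply(m$values, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance measure(s): ",
         paste(measure_ids(m)[v == 0], collapse = ", "))
  }
  r <- stats::cor(m$values)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, measure_ids = colnames(r),
                 n_samples = nrow(m$values)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("corr_matrix: %d measures, %d samples, r in [%.3f, %.3f]\n",
              length(x$measure_ids), x$n_samples, min(off), max(off)))
  invisible(x)
}

#' Connectivity-constrained correlation threshold
#'
#' The largest threshold `t` at which the network with edges
#' `{(i,j) : w_ij >= t}` is still a single connected component, where
#' `w = r` for the positive network and `w = -r` for the negative network.
#' This is the bottleneck value: the minimum edge weight on the maximum
#' spanning tree of `w`, and always one of the matrix's actual entries.
#' Any threshold strictly above it disconnects the network.
#'
#' @param c a [pearson_matrix()] result.
#' @param sign `"positive"` or `"negative"`.
#' @return the bottleneck threshold (a weight value; for the negative
#'   network it applies to `-r`, i.e. edges are pairs with `r <= -t`).
#' @export
select_threshold <- function(c, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  w <- if (sign == "positive") c$r else -c$r
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  # Prim's algorithm on the complete graph; track the bottleneck (minimum
  # weight) edge of the maximum spanning tree.
  in_tree <- rep(FALSE, n)
  best <- w[, 1]
  in_tree[1] <- TRUE
  best[1] <- -Inf
  bottleneck <- Inf
  for (step in seq_len(n - 1)) {
    j <- which.max(replace(best, in_tree, -Inf))
    bottleneck <- min(bottleneck, best[j])
    in_tree[j] <- TRUE
    improve <- !in_tree & w[, j] > best
    best[improve] <- w[improve, j]
  }
  bottleneck
}

#' Construct an immune network at a given threshold
#'
#' For `sign = "positive"` an edge joins measures `i` and `j` iff
#' `r_ij >= t`; for `sign = "negative"` iff `r_ij <= -t` (with `t > 0`).
#' The closed rule (>=) makes the connectivity-constrained threshold of
#' [select_threshold()] well defined and handles tied correlation values
#' deterministically.  Connectedness is not required here: callers may use
#' sub-bottleneck thresholds.
#'
#' @param c a [pearson_matrix()] result.
#' @param t threshold.
#' @param sign `"positive"` or `"negative"`.
#' @param categories optional annotation data.frame (measure_id, category,
#'   subcategory) attached as node attributes.
#' @return an object of class `immune_network`.
#' @export
build_network <- function(c, t, sign = c("positive", "negative"),
                          categories = NULL) {
  sign <- match.arg(sign)
  if (sign == "negative" && t <= 0) stop("negative networks require t > 0")
  w <- if (sign == "positive") c$r else -c$r
  adj <- (w >= t)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  new_immune_network(g, sign = sign, threshold = t, categories = categories)
}

#' @keywords internal
#' @noRd
new_immune_network <- function(graph, sign, threshold, categories = NULL) {
  if (!is.null(categories)) {
    idx <- match(igraph::V(graph)$name, categories$measure_id)
    igraph::V(graph)$category <- categories$category[idx]
    igraph::V(graph)$subcategory <- categories$subcategory[idx]
  }
  structure(list(graph = graph, sign = sign, threshold = threshold),
            class = "immune_network")
}

#' @export
print.immune_network <- function(x, ...) {
  cat(sprintf("immune_network (%s, t = %s): N = %d nodes, e = %d edges",
              x$sign,
              if (is.na(x$threshold)) "NA" else sprintf("%.4f", x$threshold),
              network_size(x), edge_count(x)))
  comp <- igraph::components(x$graph)
  cat(sprintf(", %d component(s)\n", comp$no))
  invisible(x)
}

#' Basic network accessors
#' @param net an `immune_network`.
#' @return node count / edge count / character vector of node names.
#' @export
network_size <- function(net) igraph::vcount(net$graph)

#' @rdname network_size
#' @export
edge_count <- function(net) igraph::ecount(net$graph)

#' @rdname network_size
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Edge density of a network
#'
#' `2e / (N (N - 1))`: the fraction of realized node pairs.
#'
#' @param net an `immune_network`.
#' @return density in `[0, 1]`.  Errors for fewer than 2 nodes.
#' @export
edge_density <- function(net) {
  n <- network_size(net)
  if (n < 2) stop("edge density undefined for fewer than 2 nodes")
  2 * edge_count(net) / (n * (n - 1))
}

#' Edge density between (or within) communities
#'
#' For two distinct communities `a` and `b`: the number of edges with one
#' endpoint in each, divided by `|a| * |b|`.  For `a == b`: within-community
#' edges divided by `choose(|a|, 2)` (requires at least 2 members).
#'
#' @param net an `immune_network`.
#' @param p a [node_partition()] over the network's nodes.
#' @param a,b community ids in `p`.
#' @return density in `[0, 1]`.
#' @export
intercommunity_density <- function(net, p, a, b) {
  members <- community_members(p)
  na_ <- members[[as.character(a)]]
  nb_ <- members[[as.character(b)]]
  if (is.null(na_) || length(na_) == 0) stop("empty community: ", a)
  if (is.null(nb_) || length(nb_) == 0) stop("empty community: ", b)
  ends <- igraph::as_edgelist(net$graph)
  if (identical(as.character(a), as.character(b))) {
    if (length(na_) < 2) stop("within-community density needs >= 2 members")
    e_in <- sum(ends[, 1] %in% na_ & ends[, 2] %in% na_)
    return(e_in / choose(length(na_), 2))
  }
  e_ab <- sum((ends[, 1] %in% na_ & ends[, 2] %in% nb_) |
              (ends[, 1] %in% nb_ & ends[, 2] %in% na_))
  e_ab / (length(na_) * length(nb_))
}

#' Export a network as edge-list TSV and GraphML
#'
#' The edge list carries the correlation of each joined pair when the
#' correlation matrix is supplied; GraphML carries node category attributes
#' and graph-level `sign` and `threshold` attributes.
#'
#' @param net an `immune_network`.
#' @param edgelist_path,graphml_path output paths (either may be NULL).
#' @param c optional `corr_matrix` used to annotate edges with `r_ij`.
#' @return invisibly, the edge-list data.frame.
#' @export
write_network <- function(net, edgelist_path = NULL, graphml_path = NULL,
                          c = NULL) {
  ends <- igraph::as_edgelist(net$graph)
  df <- data.frame(node_a = ends[, 1], node_b = ends[, 2])
  if (!is.null(c)) {
    df$r_ij <- c$r[cbind(match(df$node_a, c$measure_ids),
                         match(df$node_b, c$measure_ids))]
  }
  if (!is.null(edgelist_path)) {
    write.table(df, edgelist_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- net$graph
    g <- igraph::set_graph_attr(g, "sign", net$sign)
    g <- igraph::set_graph_attr(g, "threshold",
                                if (is.na(net$threshold)) -999
                                else net$threshold)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(df)
}

#' Write a correlation matrix as square TSV
#' @param c a `corr_matrix`.
#' @param path output path.
#' @export
write_corr_matrix <- function(c, path) {
  df <- data.frame(measure_id = c$measure_ids, c$r, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
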