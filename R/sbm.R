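#' Fit a degree-corrected stochastic block model by description length
#'
#' Finds a partition (locally) minimizing the description length of the
#' degree-corrected microcanonical SBM: a greedy agglomerative merge from
#' singleton blocks selects the number of blocks, followed by node-level
#' refinement sweeps (random order, strictly improving moves, stop after a
#' sweep with no improvement; equal-objective moves keep the current
#' assignment).  The number of blocks is selected by the objective itself,
#' not fixed in advance.  Deterministic given `seed`; the RNG used is
#' internal to the optimizer, so the R random stream is untouched.
#'
#' @param net an `immune_network` with at least one edge.
#' @param seed integer seed.
#' @return list with `partition` (a canonical [node_partition()], source
#'   `"single_run"`) and `description_length` (nats).
#' @seealso [description_length()] for the exact objective,
#'   [consensus_partition()] for the stabilized version.
#' @export
fit_sbm <- function(net, seed) {
  stopifnot(inherits(net, "immune_network"))
  if (edge_count(net) < 1) {
    stop("SBM objective is degenerate on an edgeless network")
  }
  nodes <- network_nodes(net)
  edges <- igraph::as_edgelist(net$graph, names = FALSE)
  storage.mode(edges) <- "integer"
  fit <- .sbm_fit_cpp(length(nodes), edges - 1L, as.integer(seed))
  part <- node_partition(stats::setNames(fit$membership, nodes),
                         source = "single_run")
  list(partition = part, description_length = fit$description_length)
}

#' Description length of a partition under the degree-corrected SBM
#'
#' The exact (no Stirling approximation) description length, in nats, of a
#' simple undirected graph under the flat degree-corrected microcanonical
#' SBM with uniform priors.  With block sizes \eqn{n_r}, block degree sums
#' \eqn{e_r}, between-block edge counts \eqn{e_{rs}} and \eqn{e_{rr}} twice
#' the within-block edge count, node degrees \eqn{k_i}, \eqn{N} nodes,
#' \eqn{E} edges and \eqn{B} blocks:
#' \deqn{DL = -\sum_{r<s}\ln e_{rs}! - \sum_r \ln e_{rr}!! - \sum_i \ln k_i!
#'   + \sum_r \ln e_r! + \sum_r \ln \binom{n_r + e_r - 1}{e_r}
#'   + \ln \binom{B(B+1)/2 + E - 1}{E}
#'   + \ln \binom{N-1}{B-1} + \ln N! - \sum_r \ln n_r! + \ln N.}
#' Lower is better.  The value is invariant under community relabeling,
#' which makes exhaustive search over set partitions a valid optimality
#' oracle on small graphs.
#'
#' @param net an `immune_network`.
#' @param p a [node_partition()] covering every node, with no unassigned
#'   entries.
#' @return description length in nats.
#' @export
description_length <- function(net, p) {
  stopifnot(inherits(net, "immune_network"))
  nodes <- network_nodes(net)
  v <- unclass(p)[nodes]
  if (length(v) != length(nodes) || any(is.na(v))) {
    stop("partition must assign every network node (no UNASSIGNED entries)")
  }
  memb <- as.integer(factor(v)) - 1L
  edges <- igraph::as_edgelist(net$graph, names = FALSE)
  storage.mode(edges) <- "integer"
  .sbm_dl_cpp(length(nodes), edges - 1L, memb)
}

#' Consensus over a list of partitions
#'
#' Builds the co-classification frequency matrix of a list of partitions
#' over the same node set, joins node pairs co-classified with frequency at
#' least `theta` into consensus communities (connected components of the
#' stable-pair graph), and labels size-1 components as unassigned.
#'
#' @param partitions list of [node_partition()]s over identical node sets.
#' @param theta stability threshold in `(0.5, 1]`.
#' @return list with `partition` (canonical, source `"consensus"`) and
#'   `coassignment` (symmetric node x node frequency matrix).
#' @export
consensus_from_partitions <- function(partitions, theta) {
  if (length(partitions) < 2) stop("need at least 2 partitions")
  if (theta <= 0.5 || theta > 1) stop("theta must be in (0.5, 1]")
  nodes <- names(partitions[[1]])
  co <- matrix(0, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  for (p in partitions) {
    v <- unclass(p)[nodes]
    if (any(is.na(v))) stop("input partitions must have no unassigned nodes")
    co <- co + outer(v, v, "==")
  }
  co <- co / length(partitions)
  stable <- co >= theta
  diag(stable) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(stable, mode = "undirected")
  comp <- igraph::components(g)
  lab <- comp$membership
  lab[comp$csize[comp$membership] == 1] <- NA
  part <- node_partition(stats::setNames(lab, nodes), source = "consensus")
  list(partition = part, coassignment = co)
}

#' Consensus SBM community detection
#'
#' Runs [fit_sbm()] `n_runs` times with seeds `seed, seed + 1, ...,
#' seed + n_runs - 1` and combines the runs into one consensus partition
#' via the co-classification rule of [consensus_from_partitions()].  Nodes
#' with no stable partner are left unassigned, which real immune networks
#' produce occasionally (a node that joins a different community in every
#' run).  Deterministic given the inputs.
#'
#' @param net an `immune_network`.
#' @param n_runs number of SBM fits (>= 2; default 100).
#' @param theta stability threshold in `(0.5, 1]` (default 0.9).
#' @param seed base seed.
#' @return list with `partition` (a [node_partition()], source
#'   `"consensus"`) and `summary`, a `consensus_summary` holding the
#'   coassignment matrix, `n_runs`, `theta` and the per-run description
#'   lengths.
#' @export
consensus_partition <- function(net, n_runs = 100, theta = 0.9, seed = 1) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  runs <- lapply(seq_len(n_runs) - 1L, function(k) fit_sbm(net, seed + k))
  cons <- consensus_from_partitions(lapply(runs, `[[`, "partition"), theta)
  summary <- structure(list(
    coassignment = cons$coassignment,
    n_runs = as.integer(n_runs),
    theta = theta,
    per_run_description_lengths =
      vapply(runs, `[[`, numeric(1), "description_length")
  ), class = "consensus_summary")
  list(partition = cons$partition, summary = summary)
}

#' @export
print.consensus_summary <- function(x, ...) {
  cat(sprintf("consensus_summary: %d runs, theta = %.2f, DL in [%.2f, %.2f]\n",
              x$n_runs, x$theta,
              min(x$per_run_description_lengths),
              max(x$per_run_description_lengths)))
  invisible(x)
}

#' Write a consensus summary (coassignment TSV + JSON metadata)
#' @param s a `consensus_summary`.
#' @param coassignment_path path of the square TSV.
#' @param json_path path of the metadata JSON.
#' @export
write_consensus_summary <- function(s, coassignment_path, json_path) {
  df <- data.frame(node_id = rownames(s$coassignment), s$coassignment,
                   check.names = FALSE)
  write.table(df, coassignment_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_json_file(list(n_runs = s$n_runs, theta = s$theta,
                       per_run_description_lengths =
                         s$per_run_description_lengths),
                  json_path)
  invisible(coassignment_path)
}
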