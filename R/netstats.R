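#' Collapse a group of nodes into a single node
#'
#' In a network, the replacement node inherits the union of the group's
#' external neighbourhoods; edges internal to the group are dropped and
#' duplicates merged.  In a plain character vector of node ids (e.g. a
#' marked set for [concentration_test()]), the group is replaced by the
#' single new id, so it counts as one marked node.  Typical use: merging
#' near-duplicate cytokine-response measures (such as the five IL-13
#' responses) before a concentration test.
#'
#' @param x an `immune_network` or a character vector of node ids.
#' @param group node ids to collapse (at least 2, all present in `x`).
#' @param new_id identifier of the replacement node.
#' @return object of the same type as `x`.
#' @export
collapse_node_group <- function(x, group, new_id) {
  UseMethod("collapse_node_group")
}

#' @export
collapse_node_group.immune_network <- function(x, group, new_id) {
  if (length(group) < 2) stop("group must have at least 2 nodes")
  absent <- setdiff(group, network_nodes(x))
  if (length(absent) > 0) {
    stop("group node(s) absent: ", paste(absent, collapse = ", "))
  }
  g <- x$graph
  nb <- unique(unlist(lapply(group, function(v) {
    names(igraph::neighbors(g, v))
  })))
  nb <- setdiff(nb, group)
  g2 <- igraph::delete_vertices(g, group)
  g2 <- igraph::add_vertices(g2, 1, name = new_id)
  if (length(nb) > 0) {
    g2 <- igraph::add_edges(g2, as.vector(rbind(new_id, nb)))
  }
  out <- x
  out$graph <- g2
  out
}

#' @export
collapse_node_group.character <- function(x, group, new_id) {
  if (length(group) < 2) stop("group must have at least 2 nodes")
  absent <- setdiff(group, x)
  if (length(absent) > 0) {
    stop("group node(s) absent: ", paste(absent, collapse = ", "))
  }
  c(setdiff(x, group), new_id)
}

#' Concentration test for a marked node set
#'
#' Tests whether a set of marked nodes (e.g. the Th2-marker cytokine
#' responses) is more concentrated in few communities than random placement
#' predicts.  The statistic is `T`, the sum of the `m` largest
#' per-community counts of marked nodes, i.e. the maximum number of marked
#' nodes containable in `m` communities.  A null replicate redraws the
#' marked positions uniformly without replacement from all assigned nodes,
#' keeping the partition (and hence community sizes) fixed.  One-sided
#' (direction `ge`) with the add-one rule.
#'
#' @param p a [node_partition()].
#' @param marked character vector of marked node ids; must all be assigned
#'   (collapse or drop unassigned nodes first).
#' @param m number of communities allowed to contain the marked set, with
#'   `1 <= m <= n_communities(p)`.
#' @param n_null number of null replicates (default 10000).
#' @param seed RNG seed.
#' @return a `rand_test` result.
#' @export
concentration_test <- function(p, marked, m, n_null = 10000, seed = 1) {
  v <- unclass(p)
  unknown <- setdiff(marked, names(v))
  if (length(unknown) > 0) {
    stop("marked node(s) not in partition: ", paste(unknown, collapse = ", "))
  }
  if (any(is.na(v[marked]))) {
    stop("marked node(s) are UNASSIGNED: drop or collapse them first")
  }
  K <- n_communities(p)
  if (m < 1 || m > K) stop("m must be in 1..n_communities")
  labs <- v[!is.na(v)] + 1L  # 1-based codes for tabulate()
  top_m <- function(counts) sum(sort(counts, decreasing = TRUE)[seq_len(m)])
  observed <- top_m(tabulate(v[marked] + 1L, nbins = K))
  nm <- length(marked)
  null <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      top_m(tabulate(sample(labs, nm), nbins = K))
    }, numeric(1))
  })
  rand_test_result("concentration", observed, null, "ge", seed,
                   parameters = list(m = m, n_marked = nm,
                                     n_assigned = length(labs)))
}

# Exact enumeration oracle for the concentration test: exact
# P(T_null >= T_obs) over all subsets of |marked| assigned nodes.
# Feasible only for tiny fixtures; used to validate the Monte-Carlo path.
concentration_test_exact <- function(p, marked, m) {
  v <- unclass(p)
  stopifnot(all(marked %in% names(v)), !any(is.na(v[marked])))
  K <- n_communities(p)
  labs <- v[!is.na(v)] + 1L
  top_m <- function(counts) sum(sort(counts, decreasing = TRUE)[seq_len(m)])
  observed <- top_m(tabulate(v[marked] + 1L, nbins = K))
  subsets <- combn(length(labs), length(marked))
  stats <- apply(subsets, 2, function(ix) top_m(tabulate(labs[ix], nbins = K)))
  list(observed = observed, p_value = mean(stats >= observed))
}

# Chainness of a community trio: max over hub choice H of
# min(d(H, X), d(H, Y)) - d(X, Y), with d the inter-community density.
chainness <- function(d12, d13, d23) {
  max(min(d12, d13) - d23,   # hub = 1
      min(d12, d23) - d13,   # hub = 2
      min(d13, d23) - d12)   # hub = 3
}

#' Chain-likeness test for a community trio
#'
#' Tests whether three communities form a chain (one hub densely connected
#' to two peripheral communities that are sparsely connected to each
#' other), as the three cytokine-response communities do in mouse immune
#' networks.  The statistic is the maximum over hub choices of
#' `min(d(H, X), d(H, Y)) - d(X, Y)` with `d` the inter-community edge
#' density; it is 1 for a perfect chain and 0 for a fully symmetric trio.
#' Null replicates rewire the induced subgraph on the trio's nodes with
#' degree-preserving double-edge swaps (community labels fixed,
#' `10 * edges` swap attempts per replicate).  One-sided (direction `ge`).
#'
#' @param net an `immune_network`.
#' @param p a [node_partition()].
#' @param trio three community ids.
#' @param n_null number of null replicates (default 10000).
#' @param seed RNG seed.
#' @return a `rand_test` result.
#' @export
chain_test <- function(net, p, trio, n_null = 10000, seed = 1) {
  if (length(trio) != 3) stop("trio must name exactly 3 communities")
  members <- community_members(p)
  sets <- lapply(as.character(trio), function(id) members[[id]])
  if (any(vapply(sets, is.null, logical(1))) ||
      any(lengths(sets) == 0)) {
    stop("empty community in trio")
  }
  all_nodes <- unlist(sets)
  sub <- igraph::induced_subgraph(net$graph, all_nodes)
  lab <- integer(igraph::vcount(sub))
  for (k in 1:3) lab[match(sets[[k]], igraph::V(sub)$name)] <- k
  dens <- function(g) {
    ends <- igraph::as_edgelist(g, names = FALSE)
    l1 <- lab[ends[, 1]]; l2 <- lab[ends[, 2]]
    cnt <- function(a, b) sum((l1 == a & l2 == b) | (l1 == b & l2 == a))
    s <- lengths(sets)
    c(cnt(1, 2) / (s[1] * s[2]),
      cnt(1, 3) / (s[1] * s[3]),
      cnt(2, 3) / (s[2] * s[3]))
  }
  d_obs <- dens(sub)
  n_between <- sum(d_obs * c(lengths(sets)[1] * lengths(sets)[2],
                             lengths(sets)[1] * lengths(sets)[3],
                             lengths(sets)[2] * lengths(sets)[3]))
  if (round(n_between) < 2) {
    stop("fewer than 2 inter-community edges: chainness uninformative")
  }
  observed <- chainness(d_obs[1], d_obs[2], d_obs[3])
  niter <- 10 * igraph::ecount(sub)
  null <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      gr <- igraph::rewire(sub, igraph::keeping_degseq(niter = niter))
      d <- dens(gr)
      chainness(d[1], d[2], d[3])
    }, numeric(1))
  })
  rand_test_result("chainness", observed, null, "ge", seed,
                   parameters = list(trio = as.character(trio),
                                     swap_attempts = niter))
}

#' Community overlap between two partitions
#'
#' Counts of common nodes and Jaccard indices between every pair of
#' communities of two partitions, restricted to their shared node universe
#' (unassigned nodes are excluded).
#'
#' @param a,b [node_partition()]s sharing at least one node id.
#' @return an object of class `community_overlap`: list with
#'   `common_counts` and `jaccard` matrices (rows = communities of `a`,
#'   columns = communities of `b`) and `shared_nodes`.
#' @export
community_overlap <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("partitions share no nodes")
  ca <- lapply(community_members(a), intersect, shared)
  cb <- lapply(community_members(b), intersect, shared)
  counts <- outer(seq_along(ca), seq_along(cb),
                  Vectorize(function(i, j) length(intersect(ca[[i]], cb[[j]]))))
  jac <- outer(seq_along(ca), seq_along(cb),
               Vectorize(function(i, j) {
                 u <- length(union(ca[[i]], cb[[j]]))
                 if (u == 0) 0 else length(intersect(ca[[i]], cb[[j]])) / u
               }))
  dimnames(counts) <- dimnames(jac) <- list(names(ca), names(cb))
  structure(list(common_counts = counts, jaccard = jac,
                 shared_nodes = shared),
            class = "community_overlap")
}

#' @export
print.community_overlap <- function(x, ...) {
  cat(sprintf("community_overlap: %d x %d communities over %d shared nodes\n",
              nrow(x$common_counts), ncol(x$common_counts),
              length(x$shared_nodes)))
  cat("common counts:\n")
  print(x$common_counts)
  invisible(x)
}

#' Randomization test for common nodes between two communities
#'
#' Given a shared node universe and the sizes of three communities in each
#' of two networks (e.g. the three cytokine-response communities of the
#' wild and laboratory networks), tests whether the observed number of
#' common nodes between community `i` of the first and community `j` of
#' the second differs from random assignment.  A null replicate
#' independently assigns the universe's nodes at random into three groups
#' of `sizes_a` and, independently, of `sizes_b`, and counts the overlap of
#' the selected pair.  Two-sided: extremeness is `|count - null mean|`,
#' with the add-one rule.
#'
#' @param node_universe character vector of shared node ids.
#' @param sizes_a,sizes_b integer vectors (three community sizes each);
#'   each must sum to at most `length(node_universe)`.
#' @param pair integer pair `(i, j)` selecting the community of `a` and of
#'   `b` to compare.
#' @param observed_common the observed number of common nodes.
#' @param n_null number of null replicates (default 10000).
#' @param seed RNG seed.
#' @return a `rand_test` result.
#' @export
common_nodes_test <- function(node_universe, sizes_a, sizes_b, pair,
                              observed_common, n_null = 10000, seed = 1) {
  nu <- length(node_universe)
  if (sum(sizes_a) > nu || sum(sizes_b) > nu) {
    stop("community sizes exceed the node universe")
  }
  if (length(pair) != 2) stop("pair must be (i, j)")
  i <- pair[1]; j <- pair[2]
  if (observed_common > min(sizes_a[i], sizes_b[j])) {
    stop("impossible observation: observed_common exceeds community sizes")
  }
  starts_a <- cumsum(c(0, sizes_a))
  starts_b <- cumsum(c(0, sizes_b))
  ia <- seq2(starts_a[i] + 1, starts_a[i + 1])
  ib <- seq2(starts_b[j] + 1, starts_b[j + 1])
  null <- with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      ga <- sample.int(nu)[ia]
      gb <- sample.int(nu)[ib]
      sum(ga %in% gb)
    }, numeric(1))
  })
  rand_test_result("common_nodes", observed_common, null, "two_sided", seed,
                   parameters = list(sizes_a = sizes_a, sizes_b = sizes_b,
                                     pair = pair, n_universe = nu))
}

# seq() that yields integer(0) when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Permutation test of whole-partition similarity
#'
#' Measures the adjusted Rand index (ARI) between two partitions on their
#' shared assigned nodes, against a null in which one partition's labels
#' are randomly permuted over the nodes (community sizes preserved).
#' One-sided, direction `ge`: are the partitions more similar than chance?
#'
#' @param a,b [node_partition()]s; unassigned nodes are dropped.
#' @param n_null number of null replicates (default 10000).
#' @param seed RNG seed.
#' @return a `rand_test` result whose `observed` is the ARI.
#' @export
partition_similarity_test <- function(a, b, n_null = 10000, seed = 1) {
  shared <- intersect(assigned_nodes(a), assigned_nodes(b))
  if (length(shared) < 2) stop("fewer than 2 shared assigned nodes")
  va <- unclass(a)[shared]
  vb <- unclass(b)[shared]
  observed <- adjusted_rand_index(va, vb)
  null <- with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      adjusted_rand_index(va, sample(vb))
    }, numeric(1))
  })
  rand_test_result("partition_similarity_ari", observed, null, "ge", seed,
                   parameters = list(n_shared = length(shared)))
}

#' Write a randomization test result as JSON
#' @param x a `rand_test`.
#' @param path output path.
#' @export
write_rand_test <- function(x, path) {
  write_json_file(unclass(x), path)
}
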