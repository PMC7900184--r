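# Fixture builders and independent oracles shared across the test files.

# Build an immune_network from an explicit edge list over named nodes.
net_from_edges <- function(nodes, edges, sign = "positive", threshold = NA) {
  df <- if (length(edges) == 0) {
    data.frame(from = character(), to = character())
  } else {
    data.frame(from = vapply(edges, `[`, character(1), 1),
               to = vapply(edges, `[`, character(1), 2))
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, sign = sign, threshold = threshold),
            class = "immune_network")
}

# Complete graph on n named nodes.
complete_net <- function(n, prefix = "v") {
  nodes <- paste0(prefix, seq_len(n))
  pairs <- utils::combn(nodes, 2)
  net_from_edges(nodes, lapply(seq_len(ncol(pairs)), function(k) pairs[, k]))
}

# Erdos-Renyi graph with fixed seed (independent of package generators).
er_net <- function(n, p, seed) {
  nodes <- sprintf("e%02d", seq_len(n))
  set.seed(seed)
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  net_from_edges(nodes, lapply(which(keep), function(k) pairs[, k]))
}

# All set partitions of n items as a list of integer label vectors
# (restricted growth strings).  Bell(8) = 4140.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(), 0L)
  out
}

# Independent plain-R re-implementation of the degree-corrected
# microcanonical SBM description length (dual route to the C++ one).
dl_reference <- function(net, labels) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  stopifnot(length(labels) == length(nodes))
  b <- as.integer(factor(labels))
  B <- max(b)
  N <- length(nodes)
  E <- igraph::ecount(g)
  deg <- igraph::degree(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  m <- matrix(0, B, B)
  for (k in seq_len(nrow(ends))) {
    r <- b[ends[k, 1]]; s <- b[ends[k, 2]]
    if (r == s) m[r, r] <- m[r, r] + 2
    else { m[r, s] <- m[r, s] + 1; m[s, r] <- m[s, r] + 1 }
  }
  nr <- tabulate(b, B)
  er <- rowSums(m)
  lgf <- function(x) lgamma(x + 1)
  ldf2 <- function(x) lgf(x) - (x / 2) * log(2) - lgf(x / 2)
  lms <- function(n, mm) if (n == 0) 0 else lgf(n + mm - 1) - lgf(mm) - lgf(n - 1)
  S <- -sum(lgf(m[upper.tri(m)])) - sum(vapply(diag(m), ldf2, numeric(1))) -
    sum(lgf(deg)) + sum(lgf(er)) +
    sum(vapply(seq_len(B), function(r) lms(nr[r], er[r]), numeric(1))) +
    lms(B * (B + 1) / 2, E) +
    (lgf(N - 1) - lgf(B - 1) - lgf(N - B)) + lgf(N) - sum(lgf(nr)) + log(N)
  S
}

# Brute-force connectivity-threshold oracle: scan the sorted unique
# off-diagonal entries from the largest down (edges accumulated
# incrementally, union-find) and return the largest value at which the
# graph {w >= t} is one connected component.
brute_threshold <- function(w) {
  n <- nrow(w)
  vals <- sort(unique(w[upper.tri(w)]), decreasing = TRUE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  n_comp <- n
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[upper.tri(w)], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  wv <- w[upper.tri(w)][ord]
  k <- 1
  for (t in vals) {
    while (k <= nrow(idx) && wv[k] >= t) {
      ra <- find(idx[k, 1]); rb <- find(idx[k, 2])
      if (ra != rb) { parent[ra] <- rb; n_comp <- n_comp - 1 }
      k <- k + 1
    }
    if (n_comp == 1) return(t)
  }
  -Inf
}

# Is the graph {w >= t} connected?  (igraph route, independent of the
# package's Prim-based selector.)
connected_at <- function(w, t) {
  adj <- w >= t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no == 1
}

# Random symmetric "correlation-like" matrix with unit diagonal.
random_sym_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n)
  r <- (m + t(m)) / 2
  diag(r) <- 1
  dimnames(r) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  r
}

corr_from_matrix <- function(r, n_samples = 100) {
  structure(list(r = r, measure_ids = colnames(r), n_samples = n_samples),
            class = "corr_matrix")
}

# Pair-counting adjusted Rand index (O(n^2) brute force; independent of
# the contingency-table implementation in the package).
ari_pair_reference <- function(x, y) {
  n <- length(x)
  a <- d <- ab <- ba <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (!sx && !sy) d <- d + 1
      else if (sx) ab <- ab + 1
      else ba <- ba + 1
    }
  }
  np <- choose(n, 2)
  expected <- (a + ab) * (a + ba) / np
  denom <- ((a + ab) + (a + ba)) / 2 - expected
  if (abs(denom) < .Machine$double.eps) return(0)
  (a - expected) / denom
}

# Small immune matrix from explicit values.
tiny_immune_matrix <- function(values, categories = NULL, env = "wild") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  }
  if (is.null(categories)) categories <- rep("CR", ncol(values))
  ann <- data.frame(measure_id = colnames(values), category = categories)
  immune_matrix(values, ann, environment = env)
}

# The <= 8 node fixture set used by the SBM optimality criteria.
small_graph_fixtures <- function() {
  list(
    k4 = complete_net(4),
    k8 = complete_net(8),
    path8 = net_from_edges(letters[1:8],
                           lapply(1:7, function(i) letters[i:(i + 1)])),
    cycle8 = net_from_edges(letters[1:8],
                            c(lapply(1:7, function(i) letters[i:(i + 1)]),
                              list(c("h", "a")))),
    star8 = net_from_edges(letters[1:8],
                           lapply(2:8, function(i) c("a", letters[i]))),
    two_k4 = net_from_edges(letters[1:8],
                            c(lapply(utils::combn(letters[1:4], 2,
                                                  simplify = FALSE),
                                     identity),
                              lapply(utils::combn(letters[5:8], 2,
                                                  simplify = FALSE),
                                     identity))),
    barbell = net_from_edges(letters[1:8],
                             c(utils::combn(letters[1:4], 2, simplify = FALSE),
                               utils::combn(letters[5:8], 2, simplify = FALSE),
                               list(c("d", "e")))),
    bipartite35 = net_from_edges(letters[1:8],
                                 unlist(lapply(letters[1:3], function(u) {
                                   lapply(letters[4:8], function(v) c(u, v))
                                 }), recursive = FALSE)),
    er1 = er_net(7, 0.4, 101),
    er2 = er_net(8, 0.3, 202),
    er3 = er_net(8, 0.5, 303),
    planted = generate_planted_network(8, c(4, 4), 0.9, 0.1, seed = 5)$network
  )
}
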