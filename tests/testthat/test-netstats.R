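test_that("collapse_node_group merges neighbourhoods in networks", {
  # path a-b-c-d-e: collapsing {b,c,d} leaves the path a-X-e
  path5 <- net_from_edges(letters[1:5],
                          lapply(1:4, function(i) letters[i:(i + 1)]))
  col <- collapse_node_group(path5, c("b", "c", "d"), "X")
  expect_equal(network_size(col), 3)
  expect_equal(edge_count(col), 2)
  expect_setequal(names(igraph::neighbors(col$graph, "X")), c("a", "e"))
  # identical neighbourhoods: the merged node keeps them
  twin <- net_from_edges(c("u", "v", "x", "y"),
                         list(c("u", "x"), c("u", "y"),
                              c("v", "x"), c("v", "y")))
  colt <- collapse_node_group(twin, c("u", "v"), "uv")
  expect_setequal(names(igraph::neighbors(colt$graph, "uv")), c("x", "y"))
  # a-b with only the internal edge: merged node is isolated
  pair <- net_from_edges(c("a", "b", "c"), list(c("a", "b")))
  colp <- collapse_node_group(pair, c("a", "b"), "ab")
  expect_equal(igraph::degree(colp$graph, "ab"), 0, ignore_attr = TRUE)
  expect_error(collapse_node_group(path5, c("b", "zz"), "X"), "absent")
  expect_error(collapse_node_group(path5, "b", "X"), "at least 2")
  # marked-set flavour: the group becomes one marked node
  expect_setequal(collapse_node_group(c("il13a", "il13b", "ifng"),
                                      c("il13a", "il13b"), "il13"),
                  c("ifng", "il13"))
})

test_that("concentration test matches exact enumeration on the worked case", {
  # 6 nodes in two communities of 3; marked = one full community; m = 1
  p <- node_partition(setNames(c(1, 1, 1, 2, 2, 2), letters[1:6]))
  marked <- letters[1:3]
  ex <- immunet:::concentration_test_exact(p, marked, m = 1)
  expect_equal(ex$p_value, 2 / choose(6, 3))  # = 0.1
  res <- concentration_test(p, marked, m = 1, n_null = 10000, seed = 2)
  expect_equal(res$observed, 3)
  sigma <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(res$p_value - 0.1), 3 * sigma + 2 / 10001)
})

test_that("concentration test degenerate cases give p = 1", {
  p <- node_partition(setNames(c(1, 1, 2, 2, 3), letters[1:5]))
  # marked = all nodes
  r1 <- concentration_test(p, letters[1:5], m = 1, n_null = 200, seed = 1)
  expect_equal(r1$p_value, 1)
  # m = n_communities
  r2 <- concentration_test(p, letters[1:2], m = 3, n_null = 200, seed = 1)
  expect_equal(r2$observed, 2)
  expect_equal(r2$p_value, 1)
  # marked nodes must be assigned
  pna <- node_partition(setNames(c(1, 1, 2, 2, NA), letters[1:5]))
  expect_error(concentration_test(pna, c("a", "e"), 1), "UNASSIGNED")
  expect_error(concentration_test(p, "zz", 1), "not in partition")
  expect_error(concentration_test(p, "a", m = 9), "n_communities")
})

test_that("concentration Monte-Carlo agrees with enumeration on fixtures", {
  fixtures <- list(
    list(labs = c(1, 1, 1, 2, 2, 3, 3, 3), marked = c(1, 2, 6), m = 1),
    list(labs = c(1, 1, 2, 2, 2, 3, 3), marked = c(1, 3, 4, 6), m = 2),
    list(labs = c(1, 2, 2, 3, 3, 3), marked = c(4, 5), m = 1)
  )
  for (fx in fixtures) {
    nodes <- paste0("n", seq_along(fx$labs))
    p <- node_partition(setNames(fx$labs, nodes))
    marked <- nodes[fx$marked]
    ex <- immunet:::concentration_test_exact(p, marked, fx$m)
    mc <- concentration_test(p, marked, fx$m, n_null = 5000, seed = 8)
    sigma <- sqrt(ex$p_value * (1 - ex$p_value) / 5000)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * sigma + 2 / 5001)
    expect_equal(mc$observed, ex$observed)
  }
})

test_that("randomization tests are reproducible given the seed", {
  p <- node_partition(setNames(rep(1:4, each = 5), paste0("n", 1:20)))
  a <- concentration_test(p, paste0("n", c(1, 2, 6, 11)), 2,
                          n_null = 500, seed = 42)
  b <- concentration_test(p, paste0("n", c(1, 2, 6, 11)), 2,
                          n_null = 500, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_value, (1 + a$null_exceed_count) / (1 + a$n_null))
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
})

chain_fixture <- function(d_hub = 0.8, d_pp = 0.05, size = 4, seed = 7) {
  # hub community H plus peripherals X, Y; densities approx d_hub for
  # H-X and H-Y and d_pp for X-Y, sampled deterministically
  h <- paste0("h", seq_len(size))
  x <- paste0("x", seq_len(size))
  y <- paste0("y", seq_len(size))
  set.seed(seed)
  pick <- function(a, b, d) {
    pairs <- expand.grid(a, b, stringsAsFactors = FALSE)
    keep <- runif(nrow(pairs)) < d
    lapply(which(keep), function(k) c(pairs[k, 1], pairs[k, 2]))
  }
  edges <- c(pick(h, x, d_hub), pick(h, y, d_hub), pick(x, y, d_pp))
  net <- net_from_edges(c(h, x, y), edges)
  p <- node_partition(setNames(rep(1:3, each = size), c(h, x, y)))
  list(net = net, p = p,
       trio = unique(unclass(p)[c(x[1], y[1], h[1])]))  # hub last
}

test_that("chainness statistic hits its analytic extremes", {
  # perfect chain: complete H-X and H-Y bipartite graphs, nothing else
  fx <- chain_fixture(d_hub = 1, d_pp = 0, size = 3)
  res <- chain_test(fx$net, fx$p, fx$trio, n_null = 50, seed = 1)
  expect_equal(res$observed, 1)
  # fully connected trio: statistic 0
  k9 <- complete_net(9)
  p9 <- node_partition(setNames(rep(1:3, each = 3), network_nodes(k9)))
  res9 <- chain_test(k9, p9, c(0, 1, 2), n_null = 50, seed = 1)
  expect_equal(res9$observed, 0)
  # statistic is invariant under swapping the peripheral communities
  fx2 <- chain_fixture(d_hub = 0.7, d_pp = 0.2, size = 4, seed = 11)
  r1 <- chain_test(fx2$net, fx2$p, fx2$trio, n_null = 20, seed = 3)
  r2 <- chain_test(fx2$net, fx2$p, fx2$trio[c(2, 1, 3)], n_null = 20, seed = 3)
  expect_equal(r1$observed, r2$observed)
  # degenerate: too few inter-community edges
  sparse <- net_from_edges(letters[1:6], list(c("a", "b"), c("c", "d")))
  ps <- node_partition(setNames(c(1, 1, 2, 2, 3, 3), letters[1:6]))
  expect_error(chain_test(sparse, ps, c(0, 1, 2), 10, 1),
               "inter-community")
})

test_that("community_overlap computes counts and Jaccard indices", {
  pa <- node_partition(setNames(c(1, 1, 1, 2, 2), letters[1:5]))
  # identical partitions: matched diagonal of 1s
  ov <- community_overlap(pa, pa)
  expect_equal(diag(ov$jaccard), rep(1, 2), ignore_attr = TRUE)
  expect_equal(sum(ov$common_counts), 5)
  # worked 2/29 example: |A| = 14, |B| = 17, overlap 2
  a_nodes <- paste0("a", 1:12)
  b_nodes <- paste0("b", 1:15)
  shared <- c("s1", "s2")
  univ <- c(a_nodes, b_nodes, shared)
  pA <- node_partition(setNames(c(rep(1, 14), rep(2, 15)),
                                c(a_nodes, shared, b_nodes)))
  pB <- node_partition(setNames(c(rep(1, 17), rep(2, 12)),
                                c(b_nodes, shared, a_nodes)))
  ovx <- community_overlap(pA, pB)
  # the 14-node A community and 17-node B community share exactly s1, s2
  expect_true(any(abs(ovx$jaccard - 2 / 29) < 1e-12))
  expect_true(any(ovx$common_counts == 2))
  # disjoint communities give 0s; no shared nodes errors
  expect_error(community_overlap(
    node_partition(setNames(1, "q")),
    node_partition(setNames(1, "r"))), "share no nodes")
  # conservation: total counts = shared nodes assigned in both
  expect_equal(sum(ovx$common_counts), length(univ))
})

test_that("common_nodes_test behaves at its analytic anchors", {
  univ <- paste0("u", 1:45)
  # all nodes in one community of each network: overlap always |U|
  r <- common_nodes_test(univ, c(45, 0, 0), c(45, 0, 0), c(1, 1),
                         observed_common = 45, n_null = 100, seed = 1)
  expect_equal(r$p_value, 1)
  # hypergeometric mean: 15 * 15 / 45 = 5
  r2 <- common_nodes_test(univ, c(15, 15, 15), c(15, 15, 15), c(1, 1),
                          observed_common = 5, n_null = 4000, seed = 2)
  expect_equal(r2$null_mean, 5, tolerance = 0.1)
  expect_gt(r2$p_value, 0.5)  # observation equals the null expectation
  expect_error(common_nodes_test(univ, c(15, 15, 15), c(15, 15, 15), c(1, 1),
                                 observed_common = 16, 100, 1), "impossible")
  expect_error(common_nodes_test(univ[1:10], c(9, 9, 9), c(3, 3, 3), c(1, 1),
                                 2, 100, 1), "exceed")
})

test_that("partition similarity test uses ARI with a permutation null", {
  pa <- node_partition(setNames(rep(1:4, each = 6), paste0("n", 1:24)))
  same <- partition_similarity_test(pa, pa, n_null = 300, seed = 4)
  expect_equal(same$observed, 1)
  expect_lt(same$p_value, 0.05)
  # degenerate single-community partition: ARI 0 by convention, p = 1
  p1 <- node_partition(setNames(rep(1, 24), paste0("n", 1:24)))
  deg <- partition_similarity_test(p1, pa, n_null = 100, seed = 4)
  expect_equal(deg$observed, 0)
  expect_equal(deg$p_value, 1)
  # unassigned nodes are dropped before comparison
  pb <- node_partition(setNames(c(rep(1:4, each = 6), NA),
                                paste0("n", 1:25)))
  ok <- partition_similarity_test(pb, pa, n_null = 100, seed = 4)
  expect_equal(ok$parameters$n_shared, 24)
})

test_that("adjusted_rand_index matches a pair-counting reference", {
  set.seed(10)
  for (k in 1:5) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_pair_reference(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 9, 9)), 1)
})

test_that("test results serialize to JSON", {
  p <- node_partition(setNames(rep(1:2, each = 4), paste0("n", 1:8)))
  res <- concentration_test(p, c("n1", "n2"), 1, n_null = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rand_test(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$p_value, res$p_value)
  expect_equal(back$statistic_name, "concentration")
})
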