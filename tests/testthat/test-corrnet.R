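test_that("pearson_matrix computes standard coefficients", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 6, 9)
  m <- tiny_immune_matrix(cbind(x = x, negx = -x, y = y))
  cm <- pearson_matrix(m)
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["x", "negx"], -1)
  # closed-form oracle: r = sum(dx dy) / sqrt(sum dx^2 sum dy^2)
  dx <- x - mean(x); dy <- y - mean(y)
  r_hand <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(cm$r["x", "y"], r_hand, tolerance = 1e-12)
  expect_equal(cm$n_samples, 4)
  # contract violations
  m_na <- tiny_immune_matrix(cbind(a = c(1, NA, 3), b = c(1, 2, 3)))
  expect_error(pearson_matrix(m_na), "missing")
  m_const <- tiny_immune_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_error(pearson_matrix(m_const), "zero-variance")
  m_small <- tiny_immune_matrix(cbind(a = c(1, 2), b = c(2, 1)))
  expect_error(pearson_matrix(m_small), "3 subjects")
})

test_that("select_threshold returns the connectivity bottleneck", {
  r <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.1,
                0.3, 0.1, 1), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cm <- corr_from_matrix(r)
  expect_equal(select_threshold(cm, "positive"), 0.3)
  r2 <- matrix(0.5, 4, 4); diag(r2) <- 1
  dimnames(r2) <- list(letters[1:4], letters[1:4])
  expect_equal(select_threshold(corr_from_matrix(r2), "positive"), 0.5)
})

test_that("threshold selection agrees with the brute-force scan", {
  for (seed in 1:10) {
    n <- sample(10:30, 1)
    r <- random_sym_matrix(n, seed)
    cm <- corr_from_matrix(r)
    for (sgn in c("positive", "negative")) {
      w <- if (sgn == "positive") r else -r
      t_star <- select_threshold(cm, sgn)
      expect_equal(t_star, brute_threshold(w))
      expect_true(connected_at(w, t_star))
      larger <- sort(unique(w[upper.tri(w)]))
      nxt <- larger[larger > t_star]
      if (length(nxt) > 0) expect_false(connected_at(w, min(nxt)))
    }
  }
})

test_that("build_network applies the closed >= t edge rule", {
  r <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.1,
                0.3, 0.1, 1), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cm <- corr_from_matrix(r)
  net <- build_network(cm, 0.3, "positive")
  el <- igraph::as_edgelist(net$graph)
  expect_equal(edge_count(net), 2)
  expect_setequal(paste(el[, 1], el[, 2]), c("a b", "a c"))
  # t above the maximum: empty; t = -1: complete
  expect_equal(edge_count(build_network(cm, 0.9, "positive")), 0)
  expect_equal(edge_count(build_network(cm, -1, "positive")), 3)
  expect_error(build_network(cm, -0.2, "negative"), "t > 0")
})

test_that("negative network equals positive network of the negated matrix", {
  r <- random_sym_matrix(12, 77)
  cm <- corr_from_matrix(r)
  cm_neg <- corr_from_matrix(-r + diag(2, 12))  # negate off-diagonals
  dimnames(cm_neg$r) <- dimnames(r)
  cm_neg$measure_ids <- colnames(r)
  n1 <- build_network(cm, 0.4, "negative")
  n2 <- build_network(cm_neg, 0.4, "positive")
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
})

test_that("edge_density matches the 2e/N(N-1) formula", {
  expect_equal(edge_density(complete_net(4)), 1.0)
  path3 <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  expect_equal(edge_density(path3), 2 * 2 / (3 * 2))
  empty3 <- net_from_edges(c("a", "b", "c"), list())
  expect_equal(edge_density(empty3), 0)
  one <- net_from_edges("a", list())
  expect_error(edge_density(one), "fewer than 2")
  # monotone non-increasing in t
  r <- random_sym_matrix(15, 9)
  cm <- corr_from_matrix(r)
  dens <- vapply(seq(-1, 1, by = 0.1), function(t) {
    edge_density(build_network(cm, t, "positive"))
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("intercommunity_density counts cross and within edges", {
  nodes <- as.character(1:5)
  net <- net_from_edges(nodes, list(c("1", "3"), c("2", "5"), c("1", "2")))
  p <- node_partition(setNames(c(1, 1, 2, 2, 2), nodes), source = "planted")
  # communities canonicalized: {3,4,5} -> 0, {1,2} -> 1
  expect_equal(intercommunity_density(net, p, 1, 0), 2 / 6)
  expect_equal(intercommunity_density(net, p, 1, 1), 1)  # edge 1-2 within
  expect_equal(intercommunity_density(net, p, 0, 0), 0)
  expect_error(intercommunity_density(net, p, 0, 9), "empty community")
  # complete bipartite and empty cross cases
  bip <- net_from_edges(c("a", "b", "x", "y", "z"),
                        unlist(lapply(c("a", "b"), function(u) {
                          lapply(c("x", "y", "z"), function(v) c(u, v))
                        }), recursive = FALSE))
  pb <- node_partition(setNames(c(1, 1, 2, 2, 2), c("a", "b", "x", "y", "z")))
  expect_equal(intercommunity_density(bip, pb, 0, 1), 1)
})

test_that("community edge counts conserve the total edge count", {
  gp <- generate_planted_network(30, c(10, 10, 10), 0.5, 0.2, seed = 4)
  net <- gp$network
  p <- gp$partition
  ids <- names(community_members(p))
  sizes <- lengths(community_members(p))
  total <- 0
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      d <- intercommunity_density(net, p, ids[i], ids[j])
      npairs <- if (i == j) choose(sizes[i], 2) else sizes[i] * sizes[j]
      total <- total + d * npairs
    }
  }
  expect_equal(round(unname(total)), edge_count(net))
})

test_that("networks and correlation matrices serialize to standard formats", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 30, seed = 8,
                                        cell_missing_rate = 0,
                                        battery_missing_rate = 0))
  cm <- pearson_matrix(ds$matrix)
  t_star <- select_threshold(cm, "positive")
  net <- build_network(cm, t_star, "positive",
                       categories = ds$matrix$annotations)
  dir <- withr::local_tempdir()
  el <- write_network(net, file.path(dir, "net.tsv"),
                      file.path(dir, "net.graphml"), c = cm)
  expect_true(all(el$r_ij >= t_star))
  g2 <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), edge_count(net))
  expect_equal(igraph::graph_attr(g2, "sign"), "positive")
  write_corr_matrix(cm, file.path(dir, "corr.tsv"))
  back <- read.delim(file.path(dir, "corr.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), cm$r, ignore_attr = TRUE,
               tolerance = 1e-6)
})
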