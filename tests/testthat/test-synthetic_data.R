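test_that("invalid specs are rejected with the offending field named", {
  expect_error(synthetic_spec(cell_missing_rate = 1.2), "cell_missing_rate")
  expect_error(synthetic_spec(battery_missing_rate = -0.1),
               "battery_missing_rate")
  expect_error(synthetic_spec(rho_within = 1), "rho_within")
  expect_error(synthetic_spec(rho_negative = 0.2), "rho_negative")
  expect_error(synthetic_spec(rho_chain_strong = 0.1, rho_chain_weak = 0.2),
               "rho_chain_strong")
  # infeasible under the factor construction: chain too strong
  expect_error(synthetic_spec(rho_chain_strong = 0.69, rho_chain_weak = 0.1),
               "infeasible")
})

test_that("spec invariants hold for the default panel", {
  spec <- synthetic_spec()
  expect_equal(sum(spec$category_counts), 120)
  expect_equal(length(spec$block_assignment), 120)
  expect_equal(length(unique(spec$block_assignment)), 7)
  expect_true(spec$rho_chain_strong > spec$rho_chain_weak)
  expect_true(spec$rho_chain_weak >= spec$rho_background)
  # target correlation matrix is PSD by construction
  ev <- eigen(target_correlation(spec), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(min(ev) > -1e-8)
  # and realizes the requested block correlations exactly
  R <- target_correlation(spec)
  b <- spec$block_assignment
  hub <- names(b)[b == spec$chain_blocks[3]]
  per1 <- names(b)[b == spec$chain_blocks[1]]
  per2 <- names(b)[b == spec$chain_blocks[2]]
  nk1 <- names(b)[b == spec$negative_blocks[1]]
  nk2 <- names(b)[b == spec$negative_blocks[2]]
  expect_equal(unique(as.vector(round(R[hub, per1], 10))),
               spec$rho_chain_strong)
  expect_equal(unique(as.vector(round(R[per1, per2], 10))),
               spec$rho_chain_weak)
  expect_equal(unique(as.vector(round(R[nk1, nk2], 10))), spec$rho_negative)
  expect_equal(unique(as.vector(round(R[per1[1], per1[-1]], 10))),
               spec$rho_within)
})

test_that("independence case: correlations are near zero", {
  spec <- synthetic_spec(
    n_subjects = 2000,
    category_counts = c(CR = 6),
    block_assignment = stats::setNames(rep(1L, 6), sprintf("CR%02d", 1:6)),
    chain_blocks = c(1L, 1L, 1L), negative_blocks = c(1L, 1L),
    rho_within = 0, rho_chain_strong = 0, rho_chain_weak = 0,
    rho_background = 0, rho_negative = 0,
    cell_missing_rate = 0, battery_missing_rate = 0, seed = 42)
  ds <- generate_dataset(spec)
  r <- stats::cor(ds$matrix$values)
  expect_true(all(abs(r[upper.tri(r)]) < 3 / sqrt(2000)))
})

test_that("within-block correlation matches the requested value", {
  spec <- synthetic_spec(
    n_subjects = 2000,
    category_counts = c(CR = 5),
    block_assignment = stats::setNames(rep(1L, 5), sprintf("CR%02d", 1:5)),
    chain_blocks = c(1L, 1L, 1L), negative_blocks = c(1L, 1L),
    rho_within = 0.8, rho_chain_strong = 0, rho_chain_weak = 0,
    rho_background = 0, rho_negative = 0,
    cell_missing_rate = 0, battery_missing_rate = 0, seed = 7)
  # rho = 0 between blocks is vacuous here (one block); the chain/negative
  # machinery is off, so this isolates the within-block factor loading.
  ds <- generate_dataset(spec)
  r <- stats::cor(ds$matrix$values)
  expect_equal(mean(r[upper.tri(r)]), 0.8, tolerance = 0.05 / 0.8)
})

test_that("battery missingness hits a binomial fraction of subjects", {
  spec <- synthetic_spec(n_subjects = 400, cell_missing_rate = 0,
                         battery_missing_rate = 0.5, seed = 3)
  ds <- generate_dataset(spec)
  cr_cols <- ds$matrix$annotations$category == "CR"
  n_hit <- sum(rowSums(!ds$matrix$missing_mask[, cr_cols]) == 0)
  expect_gte(n_hit, qbinom(0.005, 400, 0.5))
  expect_lte(n_hit, qbinom(0.995, 400, 0.5))
  # cell missingness is near its configured rate on the other columns
  spec2 <- synthetic_spec(n_subjects = 400, cell_missing_rate = 0.1,
                          battery_missing_rate = 0, seed = 3)
  ds2 <- generate_dataset(spec2)
  expect_lt(abs(mean(ds2$matrix$missing_mask) - 0.1), 0.01)
})

test_that("generation is deterministic given the spec and seed", {
  s <- synthetic_spec(n_subjects = 40, seed = 99)
  d1 <- generate_dataset(s)
  d2 <- generate_dataset(s)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(unclass(d1$truth_partition), unclass(d2$truth_partition))
  d3 <- generate_dataset(synthetic_spec(n_subjects = 40, seed = 100))
  expect_false(identical(d1$matrix$values, d3$matrix$values))
})

test_that("marginals are standard normal at large n", {
  spec <- synthetic_spec(n_subjects = 5000, cell_missing_rate = 0,
                         battery_missing_rate = 0, seed = 21)
  ds <- generate_dataset(spec)
  mu <- colMeans(ds$matrix$values)
  v <- apply(ds$matrix$values, 2, var)
  expect_true(all(abs(mu) < 0.1))
  expect_true(all(abs(v - 1) < 0.1))
})

test_that("lab environment permutes the measure-to-block map", {
  w <- generate_dataset(synthetic_spec(n_subjects = 20, seed = 5,
                                       environment = "wild"))
  l <- generate_dataset(synthetic_spec(n_subjects = 20, seed = 5,
                                       environment = "lab"))
  tw <- unclass(w$truth_partition)
  tl <- unclass(l$truth_partition)[names(tw)]
  expect_false(identical(tw, tl))
  expect_equal(sort(table(tw)), sort(table(tl)), ignore_attr = TRUE)
})

test_that("planted networks honour their edge probabilities", {
  # extreme cases
  gp <- generate_planted_network(10, c(5, 5), p_in = 1, p_out = 0, seed = 1)
  comp <- igraph::components(gp$network$graph)
  expect_equal(comp$no, 2)
  expect_equal(edge_count(gp$network), 2 * choose(5, 2))
  gp2 <- generate_planted_network(6, c(3, 3), p_in = 1, p_out = 1, seed = 1)
  expect_equal(edge_count(gp2$network), choose(6, 2))
  # binomial edge count for a stochastic case
  gp3 <- generate_planted_network(60, c(20, 20, 20), 0.6, 0.05, seed = 1)
  mu <- 3 * choose(20, 2) * 0.6 + 3 * 400 * 0.05
  sigma <- sqrt(3 * choose(20, 2) * 0.6 * 0.4 + 3 * 400 * 0.05 * 0.95)
  expect_lt(abs(edge_count(gp3$network) - mu), 3 * sigma)
  # invalid configurations
  expect_error(generate_planted_network(10, c(5, 4), 0.5, 0.1, 1),
               "sum to n_nodes")
  expect_error(generate_planted_network(10, c(5, 5), 0.2, 0.5, 1), "p_out")
})

test_that("synthetic datasets round-trip through TSV", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 15, seed = 2))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  m <- read_immune_matrix(file.path(dir, "matrix.tsv"),
                          file.path(dir, "annotations.tsv"),
                          environment = "wild")
  expect_equal(dim(m$values), dim(ds$matrix$values))
  expect_identical(m$missing_mask, ds$matrix$missing_mask)
  obs <- !ds$matrix$missing_mask
  expect_equal(m$values[obs], ds$matrix$values[obs], tolerance = 1e-6)
})
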