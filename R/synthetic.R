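#' Specification of a synthetic immune data set
#'
#' Describes a subjects x measures data set with planted community
#' structure, emulating a field study of wild and laboratory mouse immune
#' phenotypes: ~120 measures in six categories, block-correlated measures,
#' a chain of three cytokine-response (CR) blocks in which a hub block is
#' strongly correlated with two peripheral blocks that are only weakly
#' correlated with each other, a pair of mutually negatively correlated
#' NK-cell-like blocks, per-cell missingness, and whole-CR-battery
#' missingness for a fraction of subjects.
#'
#' Correlations are produced by a nested factor model (see
#' [generate_dataset()]), which is positive semidefinite by construction.
#' The feasibility of the requested correlations under that construction is
#' validated here; infeasible requests raise an error naming the offending
#' field.
#'
#' @param n_subjects number of subjects (default 460, a realistic wild
#'   cohort size).
#' @param category_counts named integer vector of measures per category.
#'   The default mirrors a 120-measure immune panel: Antibody 2,
#'   SerumProteins 3, BodySpleen 3, MFI 15, FACS 52, CR 45.
#' @param block_assignment named integer vector measure id -> planted block
#'   (1-based).  Default: 7 blocks (two NK-like FACS blocks of 14, the
#'   remaining 24 FACS measures, a 23-measure block of the
#'   antibody/serum/body/MFI measures, and three CR blocks of 15).
#' @param chain_blocks integer vector of the three chain block ids, the
#'   last being the hub.
#' @param negative_blocks integer vector of the two mutually negatively
#'   correlated block ids.
#' @param rho_within within-block measure correlation in `[0, 1)`.
#' @param rho_chain_strong hub-peripheral measure correlation.
#' @param rho_chain_weak peripheral-peripheral measure correlation; must
#'   satisfy `rho_chain_strong > rho_chain_weak >= rho_background`.
#' @param rho_background baseline inter-block measure correlation.
#' @param rho_negative measure correlation between the two negative blocks,
#'   in `(-1, 0]`.
#' @param cell_missing_rate per-cell missingness probability in `[0, 1)`.
#' @param battery_missing_rate probability that a subject misses the entire
#'   battery of `battery_category` measures, in `[0, 1)`.
#' @param battery_category category affected by battery missingness.
#' @param environment `"wild"` or `"lab"`.  The lab environment uses a
#'   seed-determined permutation of the measure-to-block map, so block
#'   sizes are preserved but community composition differs.
#' @param seed RNG seed; the generated data set is a deterministic function
#'   of the spec including the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 460,
                           category_counts = c(Antibody = 2, SerumProteins = 3,
                                               BodySpleen = 3, MFI = 15,
                                               FACS = 52, CR = 45),
                           block_assignment = NULL,
                           chain_blocks = c(5L, 6L, 7L),
                           negative_blocks = c(1L, 2L),
                           rho_within = 0.7,
                           rho_chain_strong = 0.28,
                           rho_chain_weak = 0.15,
                           rho_background = 0.05,
                           rho_negative = -0.4,
                           cell_missing_rate = 0.1,
                           battery_missing_rate = 0.48,
                           battery_category = "CR",
                           environment = c("wild", "lab"),
                           seed = 1L) {
  environment <- match.arg(environment)
  chk_rate <- function(x, nm, lo = 0, hi = 1, lo_ok = TRUE, hi_ok = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 &&
      (x > lo || (lo_ok && x == lo)) && (x < hi || (hi_ok && x == hi))
    if (!ok) stop(sprintf("invalid %s: must be in %s%g, %g%s", nm,
                          if (lo_ok) "[" else "(", lo, hi,
                          if (hi_ok) "]" else ")"), call. = FALSE)
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("invalid n_subjects")
  chk_rate(rho_within, "rho_within")
  chk_rate(cell_missing_rate, "cell_missing_rate")
  chk_rate(battery_missing_rate, "battery_missing_rate")
  chk_rate(rho_negative, "rho_negative", lo = -1, hi = 0,
           lo_ok = FALSE, hi_ok = TRUE)

  anno <- default_annotations(category_counts)
  if (is.null(block_assignment)) {
    block_assignment <- default_block_assignment(anno, category_counts)
  }
  if (is.null(names(block_assignment)) ||
      !setequal(names(block_assignment), anno$measure_id)) {
    stop("block_assignment must be named by measure id and cover all measures")
  }
  block_assignment <- block_assignment[anno$measure_id]
  blocks <- sort(unique(block_assignment))

  if (rho_within > 0) {
    if (rho_background < 0) stop("invalid rho_background: must be >= 0")
    if (rho_chain_weak < rho_background) {
      stop("invalid rho_chain_weak: need rho_chain_weak >= rho_background")
    }
    chain_active <- rho_chain_strong != rho_background ||
      rho_chain_weak != rho_background
    negative_active <- rho_negative < rho_background
    if (chain_active && !(rho_chain_strong > rho_chain_weak)) {
      stop("invalid rho_chain_strong: need rho_chain_strong > rho_chain_weak")
    }
    if (chain_active && negative_active &&
        length(intersect(chain_blocks, negative_blocks)) > 0) {
      stop("chain_blocks and negative_blocks must be disjoint")
    }
    # factor-loading feasibility (see generate_dataset)
    w <- rho_within
    g2 <- rho_background / w
    if (g2 > 1) stop("invalid rho_background: exceeds rho_within")
    if (rho_chain_strong > rho_background) {
      b2 <- (rho_chain_weak - rho_background) / w
      if (b2 <= 0) {
        stop("invalid rho_chain_weak: must exceed rho_background for a chain")
      }
      a2 <- ((rho_chain_strong - rho_background) / w)^2 / b2
      if (a2 + g2 > 1 + 1e-12) {
        stop("invalid rho_chain_strong: infeasible under the factor model ",
             "(reduce it, or raise rho_chain_weak or rho_within)")
      }
      if (b2 + g2 > 1 + 1e-12) stop("invalid rho_chain_weak: infeasible")
    }
    d2 <- (rho_background - rho_negative) / w
    if (d2 + g2 > 1 + 1e-12) {
      stop("invalid rho_negative: infeasible under the factor model")
    }
  } else {
    if (any(c(rho_chain_strong, rho_chain_weak, rho_background,
              abs(rho_negative)) != 0)) {
      stop("with rho_within = 0 all inter-block correlations must be 0")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    category_counts = category_counts,
    annotations = anno,
    block_assignment = block_assignment,
    chain_blocks = as.integer(chain_blocks),
    negative_blocks = as.integer(negative_blocks),
    blocks = blocks,
    rho_within = rho_within,
    rho_chain_strong = rho_chain_strong,
    rho_chain_weak = rho_chain_weak,
    rho_background = rho_background,
    rho_negative = rho_negative,
    cell_missing_rate = cell_missing_rate,
    battery_missing_rate = battery_missing_rate,
    battery_category = battery_category,
    environment = environment,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Measure ids and category/subcategory labels for given category counts.
default_annotations <- function(category_counts) {
  prefix <- c(Antibody = "Ab", SerumProteins = "SP", BodySpleen = "BS",
              MFI = "MFI", FACS = "FACS", CR = "CR")
  rows <- lapply(names(category_counts), function(cat) {
    k <- category_counts[[cat]]
    pre <- if (cat %in% names(prefix)) prefix[[cat]] else cat
    data.frame(measure_id = sprintf("%s%02d", pre, seq_len(k)),
               category = cat, subcategory = NA_character_,
               stringsAsFactors = FALSE)
  })
  anno <- do.call(rbind, rows)
  # Loose subcategories mirroring a cytometry panel: the first FACS
  # measures are NK-cell populations, MFI splits across cell types.
  if ("FACS" %in% names(category_counts) && category_counts[["FACS"]] >= 28) {
    idx <- which(anno$category == "FACS")
    anno$subcategory[idx[1:28]] <- "NK"
    anno$subcategory[idx[-(1:28)]] <- rep(c("T", "B", "other"),
                                          length.out = length(idx) - 28)
  }
  if ("MFI" %in% names(category_counts) && category_counts[["MFI"]] >= 3) {
    idx <- which(anno$category == "MFI")
    anno$subcategory[idx] <- rep(c("NK", "B", "T"), length.out = length(idx))
  }
  anno
}

# Default 7-block planted structure for the 120-measure panel.
default_block_assignment <- function(anno, category_counts) {
  need <- c(Antibody = 2, SerumProteins = 3, BodySpleen = 3, MFI = 15,
            FACS = 52, CR = 45)
  if (!identical(category_counts[names(need)], need)) {
    stop("default block_assignment requires the default category_counts; ",
         "supply block_assignment explicitly")
  }
  b <- integer(nrow(anno))
  names(b) <- anno$measure_id
  facs <- which(anno$category == "FACS")
  cr <- which(anno$category == "CR")
  other <- which(anno$category %in% c("Antibody", "SerumProteins",
                                      "BodySpleen", "MFI"))
  b[facs[1:14]] <- 1L       # NK-like block A
  b[facs[15:28]] <- 2L      # NK-like block B (negatively tied to A)
  b[facs[29:52]] <- 3L
  b[other] <- 4L
  b[cr[1:15]] <- 5L         # CR peripheral
  b[cr[16:30]] <- 6L        # CR peripheral
  b[cr[31:45]] <- 7L        # CR hub
  b
}

# Block-factor loading matrix L (blocks x factors) implementing the nested
# factor model.  Factors: 1 global, 1 chain, 1 negative-pair, 1 residual
# per block; rows have unit norm so block factors have unit variance.
block_loadings <- function(spec) {
  B <- length(spec$blocks)
  w <- spec$rho_within
  L <- matrix(0, nrow = B, ncol = 3 + B,
              dimnames = list(spec$blocks, NULL))
  if (w == 0) {
    L[, 3 + seq_len(B)] <- diag(B)
    return(L)
  }
  g <- sqrt(spec$rho_background / w)
  L[, 1] <- g
  if (spec$rho_chain_strong > spec$rho_background) {
    beta <- sqrt((spec$rho_chain_weak - spec$rho_background) / w)
    alpha <- ((spec$rho_chain_strong - spec$rho_background) / w) / beta
    hub <- as.character(spec$chain_blocks[3])
    periph <- as.character(spec$chain_blocks[1:2])
    L[hub, 2] <- alpha
    L[periph, 2] <- beta
  }
  if (spec$rho_negative < spec$rho_background) {
    d <- sqrt((spec$rho_background - spec$rho_negative) / w)
    L[as.character(spec$negative_blocks[1]), 3] <- d
    L[as.character(spec$negative_blocks[2]), 3] <- -d
  }
  resid <- 1 - rowSums(L[, 1:3, drop = FALSE]^2)
  resid[resid < 0] <- 0  # guarded by spec validation; clip rounding noise
  L[, 3 + seq_len(B)] <- diag(sqrt(resid), nrow = B)
  L
}

#' Target (population) correlation matrix of a synthetic spec
#'
#' The measure-level correlation matrix implied by the factor construction;
#' positive semidefinite by construction.  Mostly useful for tests and
#' documentation.
#'
#' @param spec a `synthetic_spec`.
#' @return measures x measures correlation matrix.
#' @export
target_correlation <- function(spec) {
  L <- block_loadings(spec)
  phi <- L %*% t(L)  # block-factor correlation matrix
  w <- spec$rho_within
  bidx <- match(spec$block_assignment, spec$blocks)
  R <- w * phi[bidx, bidx]
  diag(R) <- 1
  dimnames(R) <- list(names(spec$block_assignment),
                      names(spec$block_assignment))
  R
}

#' Generate a synthetic immune data set
#'
#' Subjects are drawn i.i.d. from a zero-mean multivariate normal whose
#' correlation matrix comes from a nested factor model: measure `i` equals
#' `sqrt(rho_within) * F_b(i) + sqrt(1 - rho_within) * eps_i`, with the
#' block factors `F_b` correlated through a global background factor, a
#' shared chain factor for the three chain blocks (the hub loading is
#' chosen so that `corr(F_hub, F_peripheral) = rho_chain_strong /
#' rho_within`), and a sign-flipped loading on a shared factor for the two
#' negative blocks.  This guarantees positive semidefiniteness without any
#' projection step.  Missingness is applied MCAR: per-cell with
#' `cell_missing_rate`, and whole-battery (all `battery_category` columns
#' of a selected subject) with `battery_missing_rate`.
#'
#' The result is a deterministic function of the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `matrix` (an [immune_matrix()]), `truth_partition` (planted
#'   [node_partition()]) and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_subjects = 50, seed = 7))
#' ds$matrix
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    assignment <- spec$block_assignment
    if (spec$environment == "lab") {
      # same mesoscale structure, different node composition
      perm <- sample(length(assignment))
      assignment <- stats::setNames(assignment[perm], names(assignment))
      assignment <- assignment[names(spec$block_assignment)]
    }
    n <- spec$n_subjects
    p <- length(assignment)
    L <- block_loadings(spec)
    B <- length(spec$blocks)
    S <- matrix(rnorm(n * ncol(L)), nrow = n)
    F <- S %*% t(L)  # n x B block factors, unit variance
    w <- spec$rho_within
    bidx <- match(assignment, spec$blocks)
    Z <- sqrt(w) * F[, bidx, drop = FALSE] +
      sqrt(1 - w) * matrix(rnorm(n * p), nrow = n)
    dimnames(Z) <- list(sprintf("s%04d", seq_len(n)), names(assignment))

    cell_miss <- matrix(runif(n * p) < spec$cell_missing_rate, n, p)
    battery_subj <- runif(n) < spec$battery_missing_rate
    battery_cols <- spec$annotations$category == spec$battery_category
    miss <- cell_miss
    miss[battery_subj, battery_cols] <- TRUE
    Z[miss] <- NA

    m <- immune_matrix(Z, spec$annotations, environment = spec$environment)
    truth <- node_partition(assignment, source = "planted")
    structure(list(matrix = m, truth_partition = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset (%s, seed %d): %d blocks planted\n",
              x$spec$environment, x$spec$seed,
              n_communities(x$truth_partition)))
  print(x$matrix)
  invisible(x)
}

#' Write a synthetic data set to a directory
#'
#' Emits `matrix.tsv` (subjects x measures, `NA` for missing),
#' `annotations.tsv` (measure_id, category, subcategory, planted_block) and
#' `spec.yaml`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anno <- ds$matrix$annotations
  anno$planted_block <- unclass(ds$truth_partition)[anno$measure_id]
  write_immune_matrix(ds$matrix, file.path(dir, "matrix.tsv"),
                      file.path(dir, "annotations.tsv"))
  write.table(anno, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  sp <- ds$spec
  sp$annotations <- NULL
  sp$block_assignment <- as.list(sp$block_assignment)
  sp$category_counts <- as.list(sp$category_counts)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Generate a planted-partition random graph
#'
#' Bernoulli edge sampling: within-block pairs with probability `p_in`,
#' between-block pairs with `p_out`.  A test fixture generator for
#' community-detection code with a known ground truth.
#'
#' @param n_nodes number of nodes.
#' @param block_sizes integer vector summing to `n_nodes`.
#' @param p_in,p_out within/between edge probabilities; `p_out` must not
#'   exceed `p_in` (assortative recovery is meaningless otherwise).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return list with `network` (an `immune_network` with sign "positive"
#'   and no threshold) and `partition` (the planted [node_partition()]).
#' @export
#' @examples
#' gp <- generate_planted_network(12, c(6, 6), p_in = 1, p_out = 0, seed = 1)
#' gp$partition
generate_planted_network <- function(n_nodes, block_sizes, p_in, p_out, seed) {
  if (sum(block_sizes) != n_nodes) stop("block_sizes must sum to n_nodes")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  block <- rep(seq_along(block_sizes), block_sizes)
  with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    same <- block[idx[, 1]] == block[idx[, 2]]
    prob <- ifelse(same, p_in, p_out)
    keep <- runif(nrow(idx)) < prob
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[idx[keep, 1]], to = nodes[idx[keep, 2]]),
      directed = FALSE,
      vertices = data.frame(name = nodes)
    )
    net <- new_immune_network(g, sign = "positive", threshold = NA_real_)
    part <- node_partition(stats::setNames(block, nodes), source = "planted")
    list(network = net, partition = part)
  })
}
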