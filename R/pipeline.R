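#' Read and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an equivalent R list) with blocks:
#' \describe{
#'   \item{input}{`matrix` and `annotations` TSV paths plus `environment`,
#'     \emph{or} a `synthetic` block of [synthetic_spec()] arguments.}
#'   \item{preprocess}{`max_missing_fraction`, `explicit_exclusions`,
#'     `battery_category`.}
#'   \item{network}{`signs` (subset of "positive"/"negative") and optional
#'     fixed `threshold` (default: connectivity-constrained bottleneck).}
#'   \item{communities}{`n_runs`, `theta`, `seed` (required).}
#'   \item{tests}{list of test specs, each with `type`
#'     ("concentration" or "chain"), a `seed` (required), `n_null`, and
#'     either `marked` (explicit node ids) or `category`/`subcategory`
#'     selectors (concentration, plus `m`), or `trio` (chain).}
#'   \item{pca}{`scaling`, `dominance_threshold`, `max_removals`.}
#'   \item{output_dir}{where artifacts are written.}
#' }
#' Seeds for every stochastic stage are mandatory; validation fails fast
#' before any computation if one is missing.
#'
#' @param path YAML file path.
#' @return validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param cfg a config list built in R.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(
    preprocess = list(max_missing_fraction = 0.5,
                      explicit_exclusions = character(),
                      battery_category = "CR"),
    network = list(signs = "positive", threshold = NULL),
    communities = list(n_runs = 100, theta = 0.9),
    tests = list(),
    pca = list(scaling = "covariance", dominance_threshold = 0.9,
               max_removals = 1)
  )
  for (nm in setdiff(names(defaults), "tests")) {
    cfg[[nm]] <- modifyList(defaults[[nm]],
                            if (is.null(cfg[[nm]])) list() else cfg[[nm]])
  }
  if (is.null(cfg$tests)) cfg$tests <- list()
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    stop("config error: need either `input` or `synthetic`")
  }
  if (!is.null(cfg$synthetic) && is.null(cfg$synthetic$seed)) {
    stop("config error: synthetic.seed is required")
  }
  if (is.null(cfg$communities$seed)) {
    stop("config error: communities.seed is required")
  }
  for (i in seq_along(cfg$tests)) {
    ts <- cfg$tests[[i]]
    if (is.null(ts$type) || !ts$type %in% c("concentration", "chain")) {
      stop("config error: tests[[", i, "]].type must be concentration|chain")
    }
    if (is.null(ts$seed)) {
      stop("config error: tests[[", i, "]].seed is required")
    }
  }
  bad_sign <- setdiff(cfg$network$signs, c("positive", "negative"))
  if (length(bad_sign)) stop("config error: unknown sign ", bad_sign[1])
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

resolve_marked_set <- function(ts, anno, nodes) {
  if (!is.null(ts$marked)) return(intersect(as.character(ts$marked), nodes))
  if (is.null(ts$category)) {
    stop("concentration test needs `marked` or `category`")
  }
  sel <- anno$category %in% ts$category
  if (!is.null(ts$subcategory)) {
    sel <- sel & anno$subcategory %in% ts$subcategory
  }
  intersect(anno$measure_id[sel], nodes)
}

#' Run the full immune-network pipeline
#'
#' Preprocess, correlate, threshold, build network(s), find consensus
#' communities, run the configured randomization tests, and run PCA; all
#' artifacts are written under the output directory and summarized in a
#' run manifest (`manifest.json`).  The run is deterministic given the
#' configuration: every stochastic stage takes its seed from the config
#' and records it in the manifest.  On a stage failure the manifest is
#' still written with a `FAILED` status naming the stage.
#'
#' @param cfg a [validate_pipeline_config()] config (or a path to YAML).
#' @param output_dir overrides `cfg$output_dir` if given.
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- validate_pipeline_config(cfg)
  out <- output_dir %||% cfg$output_dir
  if (is.null(out)) stop("config error: output_dir is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("immunet")),
                   status = "RUNNING", stages = list())
  stage <- "input"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(cfg$synthetic)) {
      spec <- do.call(synthetic_spec, cfg$synthetic)
      ds <- generate_dataset(spec)
      m <- ds$matrix
      truth <- ds$truth_partition
      write_synthetic_dataset(ds, file.path(out, "synthetic"))
      manifest$stages$input <- list(kind = "synthetic",
                                    seed = spec$seed,
                                    environment = spec$environment)
    } else {
      m <- read_immune_matrix(cfg$input$matrix, cfg$input$annotations,
                              environment = cfg$input$environment %||%
                                "unspecified")
      manifest$stages$input <- list(kind = "file",
                                    matrix = cfg$input$matrix)
    }

    stage <- "preprocess"
    pp <- preprocess(m,
                     max_missing_fraction = cfg$preprocess$max_missing_fraction,
                     explicit_exclusions =
                       as.character(cfg$preprocess$explicit_exclusions),
                     category = cfg$preprocess$battery_category,
                     report_path = file.path(out, "preprocess_report.json"))
    m <- pp$matrix
    manifest$stages$preprocess <- list(
      n_subjects = nrow(m$values), n_measures = ncol(m$values),
      removed_measures = pp$report$removed_measures,
      n_removed_subjects = length(pp$report$removed_subjects))

    stage <- "correlation"
    cm <- pearson_matrix(m)
    write_corr_matrix(cm, file.path(out, "correlation.tsv"))
    manifest$stages$correlation <- list(n_samples = cm$n_samples)

    for (sgn in cfg$network$signs) {
      stage <- paste0("network_", sgn)
      t_star <- cfg$network$threshold %||% select_threshold(cm, sgn)
      net <- build_network(cm, t_star, sgn, categories = m$annotations)
      write_network(net,
                    edgelist_path = file.path(out,
                                              paste0("network_", sgn, ".tsv")),
                    graphml_path = file.path(out,
                                             paste0("network_", sgn,
                                                    ".graphml")),
                    c = cm)
      connected <- igraph::components(net$graph)$no == 1

      stage <- paste0("communities_", sgn)
      cp <- consensus_partition(net, n_runs = cfg$communities$n_runs,
                                theta = cfg$communities$theta,
                                seed = cfg$communities$seed)
      write_partition(cp$partition,
                      file.path(out, paste0("partition_", sgn, ".tsv")))
      write_consensus_summary(cp$summary,
                              file.path(out, paste0("coassignment_", sgn,
                                                    ".tsv")),
                              file.path(out, paste0("consensus_", sgn,
                                                    ".json")))
      dens <- community_density_table(net, cp$partition)
      manifest$stages[[paste0("network_", sgn)]] <- list(
        sign = sgn, threshold = t_star, connected = connected,
        n_nodes = network_size(net), n_edges = edge_count(net),
        edge_density = edge_density(net),
        consensus_seed = cfg$communities$seed,
        n_runs = cfg$communities$n_runs, theta = cfg$communities$theta,
        n_communities = n_communities(cp$partition),
        n_unassigned = sum(is.na(unclass(cp$partition))),
        community_densities = dens,
        partition_file = paste0("partition_", sgn, ".tsv"))
      if (!is.null(truth)) {
        shared <- assigned_nodes(cp$partition)
        manifest$stages[[paste0("network_", sgn)]]$ari_vs_planted <-
          adjusted_rand_index(unclass(cp$partition)[shared],
                              unclass(truth)[shared])
      }

      stage <- paste0("tests_", sgn)
      test_results <- list()
      for (i in seq_along(cfg$tests)) {
        ts <- cfg$tests[[i]]
        res <- run_configured_test(ts, net, cp$partition, m$annotations)
        nm <- ts$name %||% paste0(ts$type, "_", i)
        write_rand_test(res, file.path(out, paste0("test_", sgn, "_", nm,
                                                   ".json")))
        test_results[[nm]] <- list(statistic = res$observed,
                                   p_value = res$p_value,
                                   n_null = res$n_null, seed = res$seed)
      }
      manifest$stages[[paste0("tests_", sgn)]] <- test_results
    }

    stage <- "pca"
    runs <- pca_with_outlier_removal(
      m, scaling = cfg$pca$scaling,
      dominance_threshold = cfg$pca$dominance_threshold,
      max_removals = cfg$pca$max_removals)
    for (k in seq_along(runs)) {
      write_pca_result(runs[[k]], out, prefix = sprintf("pca_run%d", k))
    }
    manifest$stages$pca <- lapply(runs, function(r) {
      list(pc1_share = r$variance_shares[1],
           pc2_share = if (length(r$variance_shares) > 1) {
             r$variance_shares[2]
           } else NA,
           removed_measures = r$removed_measures)
    })
    manifest$status <- "OK"
    manifest
  }, error = function(e) {
    manifest$status <<- "FAILED"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_json_file(manifest, file.path(out, "manifest.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  write_json_file(result, file.path(out, "manifest.json"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inter/within edge densities for all community pairs
community_density_table <- function(net, p) {
  ids <- names(community_members(p))
  sizes <- lengths(community_members(p))
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      if (i == j && sizes[i] < 2) next
      rows[[length(rows) + 1]] <- list(
        a = ids[i], b = ids[j],
        density = intercommunity_density(net, p, ids[i], ids[j]))
    }
  }
  rows
}

run_configured_test <- function(ts, net, partition, anno) {
  n_null <- ts$n_null %||% 10000
  if (ts$type == "concentration") {
    marked <- resolve_marked_set(ts, anno, network_nodes(net))
    marked <- intersect(marked, assigned_nodes(partition))
    if (length(marked) == 0) stop("empty marked set for concentration test")
    m_comm <- ts$m %||% 2
    concentration_test(partition, marked, m = m_comm, n_null = n_null,
                       seed = ts$seed)
  } else {
    trio <- ts$trio %||% {
      # default: the three communities richest in cytokine-response nodes,
      # the trio whose chain-like topology the analysis is interested in
      cat <- ts$category %||% "CR"
      cat_nodes <- anno$measure_id[anno$category == cat]
      members <- community_members(partition)
      score <- vapply(members, function(mm) {
        length(intersect(mm, cat_nodes))
      }, integer(1))
      if (sum(score > 0) >= 3) {
        names(sort(score, decreasing = TRUE))[1:3]
      } else {
        names(sort(lengths(members), decreasing = TRUE))[1:3]
      }
    }
    chain_test(net, partition, trio, n_null = n_null, seed = ts$seed)
  }
}

#' Compare two pipeline runs
#'
#' Cross-network comparison of two completed runs: community overlap
#' (common-node counts and Jaccard indices), a whole-partition similarity
#' permutation test, and optionally common-node randomization tests for a
#' selected trio of communities in each network (e.g. the three
#' cytokine-response communities).
#'
#' @param dir_a,dir_b output directories of two [run_pipeline()] runs.
#' @param output_dir where comparison artifacts are written.
#' @param sign which network's partition to compare (default "positive").
#' @param trio_a,trio_b optional community-id trios; when both are given,
#'   [common_nodes_test()] is run for every pair of the two trios.
#' @param n_null replicates for the randomization tests.
#' @param seed RNG seed.
#' @return comparison report list, invisibly (also written as JSON).
#' @export
compare_runs <- function(dir_a, dir_b, output_dir, sign = "positive",
                         trio_a = NULL, trio_b = NULL,
                         n_null = 10000, seed = 1) {
  pa <- read_partition(file.path(dir_a, paste0("partition_", sign, ".tsv")))
  pb <- read_partition(file.path(dir_b, paste0("partition_", sign, ".tsv")))
  shared <- intersect(names(pa), names(pb))
  if (length(shared) == 0) {
    stop("incompatible node universes; unshared nodes: ",
         paste(c(setdiff(names(pa), names(pb)),
                 setdiff(names(pb), names(pa))), collapse = ", "))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ov <- community_overlap(pa, pb)
  write.table(data.frame(community_a = rownames(ov$common_counts),
                         ov$common_counts, check.names = FALSE),
              file.path(output_dir, "common_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(community_a = rownames(ov$jaccard), ov$jaccard,
                         check.names = FALSE),
              file.path(output_dir, "jaccard.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sim <- partition_similarity_test(pa, pb, n_null = n_null, seed = seed)
  write_rand_test(sim, file.path(output_dir, "partition_similarity.json"))
  report <- list(n_shared_nodes = length(shared),
                 ari = sim$observed,
                 partition_similarity_p = sim$p_value,
                 common_nodes_tests = list())
  if (!is.null(trio_a) && !is.null(trio_b)) {
    universe <- intersect(unlist(community_members(pa)[as.character(trio_a)]),
                          shared)
    universe <- union(universe,
                      intersect(unlist(community_members(pb)[
                        as.character(trio_b)]), shared))
    sizes_a <- vapply(as.character(trio_a), function(id) {
      length(intersect(community_members(pa)[[id]], universe))
    }, integer(1))
    sizes_b <- vapply(as.character(trio_b), function(id) {
      length(intersect(community_members(pb)[[id]], universe))
    }, integer(1))
    k <- 0
    for (i in seq_along(trio_a)) {
      for (j in seq_along(trio_b)) {
        obs <- length(intersect(
          intersect(community_members(pa)[[as.character(trio_a[i])]],
                    universe),
          intersect(community_members(pb)[[as.character(trio_b[j])]],
                    universe)))
        res <- common_nodes_test(universe, sizes_a, sizes_b, c(i, j), obs,
                                 n_null = n_null, seed = seed + k)
        nm <- sprintf("a%s_b%s", trio_a[i], trio_b[j])
        write_rand_test(res, file.path(output_dir,
                                       paste0("common_nodes_", nm, ".json")))
        report$common_nodes_tests[[nm]] <- list(observed = obs,
                                                p_value = res$p_value)
        k <- k + 1
      }
    }
  }
  write_json_file(report, file.path(output_dir, "comparison.json"))
  invisible(report)
}
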