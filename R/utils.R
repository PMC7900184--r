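#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random seed, runs `code`, and restores the previous RNG state,
#' so seeded operations do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Permutation p-value with add-one correction
#'
#' p = (1 + number of null replicates at least as extreme) / (1 + n_null),
#' guaranteeing p in (0, 1].
#'
#' @param observed observed statistic.
#' @param null numeric vector of null replicates.
#' @param direction "ge", "le" or "two_sided".  Two-sided extremeness is
#'   measured as absolute deviation from the null mean.
#' @return list with `p_value` and `null_exceed_count`.
#' @keywords internal
#' @noRd
perm_pvalue <- function(observed, null, direction = c("ge", "le", "two_sided")) {
  direction <- match.arg(direction)
  exceed <- switch(direction,
    ge = sum(null >= observed),
    le = sum(null <= observed),
    two_sided = {
      center <- mean(null)
      sum(abs(null - center) >= abs(observed - center))
    }
  )
  list(p_value = (1 + exceed) / (1 + length(null)),
       null_exceed_count = as.integer(exceed))
}

#' Construct a randomization test result
#' @keywords internal
#' @noRd
rand_test_result <- function(statistic_name, observed, null, direction, seed,
                             parameters = list()) {
  pv <- perm_pvalue(observed, null, direction)
  structure(list(
    statistic_name = statistic_name,
    observed = observed,
    n_null = length(null),
    null_exceed_count = pv$null_exceed_count,
    p_value = pv$p_value,
    null_mean = mean(null),
    null_sd = stats::sd(null),
    seed = as.integer(seed),
    direction = direction,
    parameters = parameters
  ), class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("Randomization test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.6g  (null mean %.4g, sd %.4g)\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p = %.4g  (%s, %d null replicates, add-one rule, seed %d)\n",
              x$p_value, x$direction, x$n_null, x$seed))
  invisible(x)
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions of the same items.
#' By convention a degenerate comparison (either clustering places all items
#' in one community, or the correction denominator vanishes) returns 0.
#'
#' @param x,y vectors of community labels over the same items (equal length).
#' @return the adjusted Rand index, a number <= 1.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("adjusted_rand_index needs at least 2 items")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  tab <- table(x, y)
  nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (abs(denom) < .Machine$double.eps) return(0)
  (nij - expected) / denom
}

#' Serialize an object to pretty JSON on disk
#' @keywords internal
#' @noRd
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
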