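#' Dense ranks of a score vector (smaller is better)
#'
#' Rank 1 goes to the smallest distinct value, ties share the rank of their
#' distinct value, and the next distinct value gets the next integer — i.e.
#' each score's rank is one plus the number of distinct smaller values.
#'
#' @param scores Finite numeric vector.
#' @return Integer vector of ranks.
#' @export
dense_ranks <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  match(scores, sort(unique(scores)))
}

#' Rank table of algorithm scores across datasets
#'
#' Applies [dense_ranks()] to every row of a datasets-by-algorithms score
#' matrix (scores where smaller is better, e.g. Minkowski scores) and
#' averages the ranks per algorithm.
#'
#' @param scores Numeric matrix or data frame, rows = datasets, columns =
#'   algorithms.
#' @return A list of class `acl_rank_table` with `scores`, `ranks` and
#'   `avg_ranks`.
#' @export
rank_table <- function(scores) {
  scores <- as.matrix(scores)
  ranks <- t(apply(scores, 1L, dense_ranks))
  dimnames(ranks) <- dimnames(scores)
  structure(list(scores = scores, ranks = ranks,
                 avg_ranks = colMeans(ranks)),
            class = "acl_rank_table")
}

#' Average dense ranks per algorithm
#'
#' @param x An `acl_rank_table` (or a score matrix, ranked first).
#' @return Named numeric vector of column means of the dense-rank matrix.
#' @export
average_ranks <- function(x) {
  if (!inherits(x, "acl_rank_table")) x <- rank_table(x)
  x$avg_ranks
}

#' @export
print.acl_rank_table <- function(x, ...) {
  cat("<acl_rank_table>\n")
  disp <- matrix(sprintf("%.2f(%d)", x$scores, x$ranks), nrow(x$scores),
                 dimnames = dimnames(x$scores))
  print(disp, quote = FALSE)
  cat("Average rank:", paste(sprintf("%.2f", x$avg_ranks), collapse = " "),
      "\n")
  invisible(x)
}

#' Friedman test across datasets
#'
#' Tests whether the algorithms' score distributions differ across datasets.
#' Ranks are recomputed internally as tie-corrected average-style ranks
#' (which sum to `A(A+1)/2` per row, the form the chi-square reference
#' distribution assumes) rather than the dense ranks used for reporting.
#' Delegates to [stats::friedman.test()].
#'
#' @param scores Datasets-by-algorithms numeric matrix; smaller is better
#'   (direction does not affect the statistic).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("need at least 2 datasets and 2 algorithms")
  }
  if (all(apply(scores, 1L, function(r) length(unique(r)) == 1L))) {
    stop("Friedman statistic undefined: every row is constant")
  }
  ht <- stats::friedman.test(scores)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Nemenyi critical difference
#'
#' Two algorithms differ significantly when their average ranks differ by at
#' least `CD = q_alpha(A) * sqrt(A (A + 1) / (6 D))`, with `q_alpha` the
#' studentized-range quantile at infinite degrees of freedom divided by
#' `sqrt(2)`.
#'
#' @param n_algorithms Number of algorithms A (2..10).
#' @param n_datasets Number of datasets D (>= 1).
#' @param alpha Significance level, 0.05 or 0.10.
#' @return The critical difference (scalar).
#' @export
nemenyi_critical_difference <- function(n_algorithms, n_datasets,
                                        alpha = 0.05) {
  if (!isTRUE(all.equal(alpha, 0.05)) && !isTRUE(all.equal(alpha, 0.10))) {
    stop("alpha must be 0.05 or 0.10")
  }
  if (n_algorithms < 2L || n_algorithms > 10L) {
    stop("n_algorithms must lie in [2, 10]")
  }
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  q_alpha <- stats::qtukey(1 - alpha, nmeans = n_algorithms, df = Inf) / sqrt(2)
  q_alpha * sqrt(n_algorithms * (n_algorithms + 1) / (6 * n_datasets))
}

#' Benchmark Minkowski-score table
#'
#' Loads the bundled comparison table of best-of-ten Minkowski scores of six
#' clustering algorithms (the full method, its Euclidean-assignment and
#' unsupervised ablations, a fixed-feature clusterer, a genetic point-symmetry
#' clusterer and K-means) on seven standard benchmark datasets.
#'
#' @return Numeric matrix with dataset row names and algorithm column names.
#' @export
benchmark_scores <- function() {
  path <- system.file("extdata", "benchmark_minkowski_scores.csv",
                      package = "amosaclust", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}
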