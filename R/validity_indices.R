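# Signal used for solutions that cannot be scored (empty/too-small cluster,
# coincident centres). The pipeline catches this class and substitutes
# worst-case objective values instead of aborting the run.
degenerate_solution <- function(msg) {
  stop(errorCondition(msg, class = c("acl_degenerate", "error")))
}

as_partition <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("partition labels must not be missing")
  labels
}

#' Pair-agreement counts between two partitions
#'
#' Counts sample pairs by co-membership agreement between a reference
#' partition `T` and a candidate partition `S`: `n11` pairs co-clustered in
#' both, `n01` co-clustered only in `S`, `n10` co-clustered only in `T`,
#' `n00` in neither. Computed from the contingency table, so it scales as
#' the table rather than as all pairs.
#'
#' @param T_labels Reference partition (integer vector).
#' @param S_labels Candidate partition of the same length.
#' @return Named list with `n11`, `n01`, `n10`, `n00`.
#' @export
pair_counts <- function(T_labels, S_labels) {
  T_labels <- as_partition(T_labels); S_labels <- as_partition(S_labels)
  if (length(T_labels) != length(S_labels)) stop("partition length mismatch")
  n <- length(T_labels)
  tab <- table(T_labels, S_labels)
  choose2 <- function(x) x * (x - 1) / 2
  n11 <- sum(choose2(tab))
  same_T <- sum(choose2(rowSums(tab)))
  same_S <- sum(choose2(colSums(tab)))
  n10 <- same_T - n11
  n01 <- same_S - n11
  n00 <- choose2(n) - n11 - n10 - n01
  list(n11 = n11, n01 = n01, n10 = n10, n00 = n00)
}

#' Minkowski score
#'
#' `sqrt((n01 + n10) / (n11 + n10))` over the pair-agreement counts against
#' the reference partition `T`. Zero iff the two partitions induce the same
#' pair structure; lower is better. Asymmetric in its arguments: `n01` and
#' `n10` play different roles.
#'
#' @inheritParams pair_counts
#' @return Nonnegative scalar.
#' @export
minkowski_score <- function(T_labels, S_labels) {
  pc <- pair_counts(T_labels, S_labels)
  if (pc$n11 + pc$n10 == 0) {
    stop("Minkowski score undefined: reference partition has no co-clustered pair")
  }
  sqrt((pc$n01 + pc$n10) / (pc$n11 + pc$n10))
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected pair-agreement similarity between two partitions, 1 for
#' identical pair structure. The degenerate case in which the correction
#' removes all variation (both partitions a single cluster) returns 1 by
#' convention.
#'
#' @inheritParams pair_counts
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand <- function(T_labels, S_labels) {
  T_labels <- as_partition(T_labels); S_labels <- as_partition(S_labels)
  if (length(T_labels) != length(S_labels)) stop("partition length mismatch")
  n <- length(T_labels)
  if (n < 2L) stop("need at least 2 samples")
  tab <- table(T_labels, S_labels)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_term <- (sum_a + sum_b) / 2
  if (max_term - expected == 0) return(1)
  (sum_ij - expected) / (max_term - expected)
}

# Project data and centres onto the active feature subspace.
project_active <- function(data, centers, mask) {
  if (is.null(mask)) mask <- rep(1L, ncol(data))
  act <- which(mask == 1L)
  if (length(act) < 1L) stop("mask must keep at least one feature")
  list(X = data[, act, drop = FALSE], C = centers[, act, drop = FALSE])
}

#' Xie-Beni cluster validity index
#'
#' Total within-cluster squared Euclidean scatter divided by `n` times the
#' squared minimum inter-centre distance, all in the active feature
#' subspace. Small values indicate compact, well-separated clusters.
#'
#' @param data Numeric matrix (n x F).
#' @param partition Integer vector of cluster labels in `1..K`.
#' @param centers K x F matrix of cluster centres.
#' @param mask Optional 0/1 active-feature vector of length F.
#' @return Nonnegative scalar. Coincident centres raise a
#'   degenerate-solution error.
#' @export
xb_index <- function(data, partition, centers, mask = NULL) {
  partition <- as_partition(partition)
  pr <- project_active(as.matrix(data), as.matrix(centers), mask)
  K <- nrow(pr$C)
  if (K < 2L) stop("XB index requires K >= 2")
  D2c <- cross_dist2(pr$C, pr$C)
  diag(D2c) <- Inf
  min_sep2 <- min(D2c)
  if (min_sep2 <= 0 || anyDuplicated(pr$C) > 0L) {
    degenerate_solution("coincident cluster centres")
  }
  scatter <- sum((pr$X - pr$C[partition, , drop = FALSE])^2)
  scatter / (nrow(pr$X) * min_sep2)
}

#' Symmetry-based cluster validity index (Sym-index)
#'
#' `D_K / (K * E_K)` where `D_K` is the maximum inter-centre distance and
#' `E_K` the total within-cluster point-symmetry distance: for each point,
#' the mean distance from its reflection through its cluster centre to the
#' reflection's `knear` nearest neighbours *within that cluster*, times the
#' Euclidean point-centre distance. Larger values reward widely separated,
#' internally symmetric clusters. The within-cluster neighbour search is
#' deliberate: it scores the symmetry of each cluster about its own centre,
#' whereas assignment-time symmetry distances search the whole dataset.
#'
#' @inheritParams xb_index
#' @param knear Neighbour count for the symmetry measure (default 2).
#' @return Positive scalar. Clusters with fewer than `knear` members (the
#'   minimum the within-cluster neighbour search needs) or coincident
#'   centres raise a degenerate-solution error.
#' @export
sym_index <- function(data, partition, centers, mask = NULL, knear = 2L) {
  partition <- as_partition(partition)
  pr <- project_active(as.matrix(data), as.matrix(centers), mask)
  K <- nrow(pr$C)
  if (K < 2L) stop("Sym index requires K >= 2")
  sizes <- tabulate(partition, nbins = K)
  if (any(sizes < knear)) {
    degenerate_solution("cluster with fewer than knear members")
  }
  Dc <- sqrt(cross_dist2(pr$C, pr$C))
  D_K <- max(Dc)
  if (D_K <= 0) degenerate_solution("coincident cluster centres")
  E_K <- 0
  for (k in seq_len(K)) {
    rows <- which(partition == k)
    Xk <- pr$X[rows, , drop = FALSE]
    ck <- pr$C[k, ]
    refl <- sweep(-Xk, 2L, 2 * ck, `+`)
    dsym <- tryCatch(knear_mean_dist(refl, Xk, knear),
                     error = function(e) degenerate_solution(conditionMessage(e)))
    de <- sqrt(rowSums(sweep(Xk, 2L, ck, `-`)^2))
    E_K <- E_K + sum(dsym * de)
  }
  D_K / (K * E_K)
}
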