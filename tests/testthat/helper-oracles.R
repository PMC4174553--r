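# Independent brute-force oracles. These deliberately avoid the package's
# vectorised/compiled code paths: plain loops, full enumeration.

# Mean distance from the reflection of x through ctr to its knear nearest
# points with pairwise-distinct coordinates, by exhaustive scan.
oracle_dsym <- function(x, ctr, points, knear = 2L) {
  r <- 2 * ctr - x
  d <- apply(points, 1L, function(p) sqrt(sum((r - p)^2)))
  ord <- order(d, seq_along(d))
  chosen <- list()
  dists <- numeric(0)
  for (i in ord) {
    p <- points[i, ]
    dup <- any(vapply(chosen, function(q) all(q == p), logical(1)))
    if (!dup) {
      chosen[[length(chosen) + 1L]] <- p
      dists <- c(dists, d[i])
    }
    if (length(dists) == knear) break
  }
  stopifnot(length(dists) == knear)
  mean(dists)
}

oracle_dps <- function(x, ctr, points, knear = 2L) {
  oracle_dsym(x, ctr, points, knear) * sqrt(sum((x - ctr)^2))
}

# Maximum over points of the distance to the nearest other-index point.
oracle_theta <- function(points) {
  n <- nrow(points)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      best <- min(best, sqrt(sum((points[i, ] - points[j, ])^2)))
    }
    nn[i] <- best
  }
  max(nn)
}

# Strict Pareto dominance and O(m^2) non-dominated scan, written directly.
oracle_dominates <- function(u, v, directions) {
  s <- ifelse(directions == "max", 1, -1)
  a <- s * u; b <- s * v
  all(a >= b) && any(a > b)
}

oracle_nondominated <- function(objs, directions) {
  m <- nrow(objs)
  keep <- logical(m)
  for (i in seq_len(m)) {
    dominated <- FALSE
    for (j in seq_len(m)) {
      if (j != i && oracle_dominates(objs[j, ], objs[i, ], directions)) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# Pair counts by explicit enumeration of all sample pairs.
oracle_pair_counts <- function(T_labels, S_labels) {
  n <- length(T_labels)
  n11 <- n01 <- n10 <- n00 <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- T_labels[i] == T_labels[j]
      ss <- S_labels[i] == S_labels[j]
      if (st && ss) n11 <- n11 + 1L
      else if (!st && ss) n01 <- n01 + 1L
      else if (st && !ss) n10 <- n10 + 1L
      else n00 <- n00 + 1L
    }
  }
  list(n11 = n11, n01 = n01, n10 = n10, n00 = n00)
}

# ARI through the pair-counting identity (independent of the contingency
# table route used by the package).
oracle_ari <- function(T_labels, S_labels) {
  pc <- oracle_pair_counts(T_labels, S_labels)
  num <- 2 * (pc$n11 * pc$n00 - pc$n10 * pc$n01)
  den <- (pc$n11 + pc$n10) * (pc$n10 + pc$n00) +
    (pc$n11 + pc$n01) * (pc$n01 + pc$n00)
  if (den == 0) return(1)
  num / den
}

oracle_ms <- function(T_labels, S_labels) {
  pc <- oracle_pair_counts(T_labels, S_labels)
  sqrt((pc$n01 + pc$n10) / (pc$n11 + pc$n10))
}

# Tie-corrected Friedman chi-square from the textbook formula, using
# average-style within-row ranks.
oracle_friedman <- function(scores) {
  D <- nrow(scores); A <- ncol(scores)
  r <- t(apply(scores, 1L, rank))
  ties <- 0
  for (i in seq_len(D)) {
    tab <- table(scores[i, ])
    ties <- ties + sum(tab^3 - tab)
  }
  num <- 12 * sum((colSums(r) - D * (A + 1) / 2)^2)
  den <- D * A * (A + 1) - ties / (A - 1)
  num / den
}

# Small random dataset helper used across tests.
random_dataset <- function(n = 30, F = 3, k = 2, seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * F), n, F)
    labs <- sample(seq_len(k), n, replace = TRUE)
    dataset(pts, paste0("f", seq_len(F)), true_labels = labs,
            labeled_idx = seq_len(max(2, round(0.2 * n))))
  })
}
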