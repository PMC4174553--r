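#' Candidate solution: feature mask plus cluster centres
#'
#' The search state is a binary feature mask of length F together with K
#' centre vectors in the full feature space (only active coordinates enter
#' distance computations; inactive coordinates are carried along so that a
#' later mask flip can reactivate a feature without losing centre
#' information).
#'
#' @param mask 0/1 integer vector of length F with at least one 1.
#' @param centers K x F numeric matrix, K >= 2.
#' @return An object of class `acl_solution`.
#' @export
candidate_solution <- function(mask, centers) {
  mask <- as.integer(mask)
  centers <- as.matrix(centers)
  if (any(!mask %in% c(0L, 1L))) stop("mask must be binary")
  if (sum(mask) < 1L) stop("mask must have at least one active feature")
  if (nrow(centers) < 2L) stop("a solution encodes at least 2 centres")
  if (ncol(centers) != length(mask)) stop("centers and mask disagree on F")
  structure(list(mask = mask, centers = centers, K = nrow(centers)),
            class = "acl_solution")
}

#' @export
print.acl_solution <- function(x, ...) {
  cat(sprintf("<acl_solution> K = %d, %d/%d features active\n",
              x$K, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Mutation parameters
#'
#' @param delta Scale of the Laplace centre perturbation (default 1.0); the
#'   expected absolute displacement per coordinate equals `delta`.
#' @param flip_prob Per-bit mask flip probability; default `NULL` means
#'   `1 / F`, one expected flip per mutation.
#' @param kmax Upper bound on the number of centres.
#' @return A list of class `acl_mutation_params`.
#' @export
mutation_params <- function(delta = 1.0, flip_prob = NULL, kmax = NULL) {
  if (delta <= 0) stop("delta must be positive")
  if (!is.null(flip_prob) && (flip_prob <= 0 || flip_prob > 1)) {
    stop("flip_prob must lie in (0, 1]")
  }
  structure(list(delta = delta, flip_prob = flip_prob, kmax = kmax),
            class = "acl_mutation_params")
}

#' Random initial solution
#'
#' K is drawn uniformly from `2..kmax`; the centres are K distinct data
#' points sampled without replacement; mask bits are i.i.d. uniform on
#' \{0, 1\}, redrawn until at least one bit is set. Consumes the global RNG
#' stream (seed at the run level for reproducibility).
#'
#' @param ds An `acl_dataset`.
#' @param kmax Upper bound on K (>= 2, <= n).
#' @return An `acl_solution`.
#' @export
random_solution <- function(ds, kmax) {
  stopifnot(inherits(ds, "acl_dataset"))
  n <- nrow(ds$points); F <- ncol(ds$points)
  if (kmax < 2L) stop("kmax must be >= 2")
  if (kmax > n) stop("kmax cannot exceed the number of samples")
  K <- sample.int(kmax - 1L, 1L) + 1L
  centers <- ds$points[sample.int(n, K), , drop = FALSE]
  repeat {
    mask <- stats::rbinom(F, 1L, 0.5)
    if (sum(mask) >= 1L) break
  }
  candidate_solution(mask, centers)
}

# Laplace(mu, b) draws via inverse CDF.
rlaplace <- function(n, mu = 0, b = 1) {
  u <- stats::runif(n, -0.5, 0.5)
  mu - b * sign(u) * log1p(-2 * abs(u))
}

# Flip each mask bit with probability flip_prob, redrawing until the mask
# keeps at least one active feature.
flip_mask <- function(mask, flip_prob) {
  repeat {
    flips <- stats::rbinom(length(mask), 1L, flip_prob)
    new_mask <- as.integer(xor(mask, flips))
    if (sum(new_mask) >= 1L) return(new_mask)
  }
}

#' Mutate a candidate solution
#'
#' One of three moves is chosen uniformly: *perturb* (every coordinate of
#' every centre replaced by a Laplace draw centred on its old value with
#' scale `delta`), *delete* (one uniformly chosen centre removed, only
#' feasible when K > 2), or *insert* (one uniformly chosen data point
#' appended as a new centre, only feasible when K < kmax). An infeasible
#' delete or insert degrades to perturb. Every move also flips each mask bit
#' with probability `flip_prob` (redrawn if the result would deactivate all
#' features). The input solution is not modified.
#'
#' @param sol An `acl_solution`.
#' @param ds The dataset (source of insertable centres).
#' @param params An `acl_mutation_params`; `kmax` must be set.
#' @return A new `acl_solution`.
#' @export
mutate_solution <- function(sol, ds, params) {
  stopifnot(inherits(sol, "acl_solution"), inherits(params, "acl_mutation_params"))
  kmax <- params$kmax
  if (is.null(kmax)) stop("params$kmax must be set")
  flip_prob <- if (is.null(params$flip_prob)) 1 / length(sol$mask) else params$flip_prob
  move <- sample.int(3L, 1L)
  if (move == 2L && sol$K <= 2L) move <- 1L
  if (move == 3L && sol$K >= kmax) move <- 1L
  centers <- sol$centers
  if (move == 1L) {
    centers <- matrix(rlaplace(length(centers), mu = as.numeric(centers),
                               b = params$delta),
                      nrow = nrow(centers), ncol = ncol(centers))
  } else if (move == 2L) {
    drop <- sample.int(sol$K, 1L)
    centers <- centers[-drop, , drop = FALSE]
  } else {
    add <- sample.int(nrow(ds$points), 1L)
    centers <- rbind(centers, ds$points[add, ])
  }
  mask <- flip_mask(sol$mask, flip_prob)
  candidate_solution(mask, centers)
}
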