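# Squared Euclidean cross-distances between the rows of A and the rows of B.
# Clamped at zero to absorb negative round-off.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Group id per row of P such that rows with identical coordinates share a
# group ("unique" neighbours must have distinct coordinates).
coordinate_groups <- function(P) {
  coordinate_groups_cpp(as.matrix(P))
}

# For each row of `queries`, the mean Euclidean distance to its `knear`
# nearest pool points with pairwise-distinct coordinates. Exact scan (no
# approximation); ties broken by lower pool index; duplicated pool
# coordinates are collapsed so at most one representative of each
# coincident group can be selected.
knear_mean_dist <- function(queries, pool, knear, groups = NULL) {
  queries <- as.matrix(queries); pool <- as.matrix(pool)
  if (is.null(groups)) groups <- coordinate_groups(pool)
  knear_mean_dist_cpp(queries, pool, as.integer(knear), as.integer(groups))
}

#' Build a point-symmetry distance context
#'
#' Projects the dataset onto the active feature subspace, fixes the
#' neighbour count `knear`, and computes the symmetry threshold `theta` (the
#' maximum nearest-neighbour distance over all projected points) unless one
#' is supplied. All symmetry distances are evaluated against this projected
#' point set.
#'
#' @param points Numeric matrix (n x F) or an `acl_dataset`.
#' @param mask Optional 0/1 vector of length F selecting the active features;
#'   `NULL` keeps all features.
#' @param knear Number of nearest neighbours of the reflected point used by
#'   the symmetry measure (default 2).
#' @param theta Optional symmetry threshold override; by default the maximum
#'   nearest-neighbour distance of the projected points.
#' @return An object of class `acl_distance_context`.
#' @export
distance_context <- function(points, mask = NULL, knear = 2L, theta = NULL) {
  if (inherits(points, "acl_dataset")) points <- points$points
  points <- as.matrix(points)
  if (!is.null(mask)) {
    if (length(mask) != ncol(points)) stop("mask length does not match features")
    if (sum(mask) < 1L) stop("mask must keep at least one feature")
    points <- points[, which(mask == 1L), drop = FALSE]
  }
  if (knear < 1L) stop("knear must be >= 1")
  if (is.null(theta)) theta <- max_nn_distance(points)
  if (theta < 0) stop("theta must be nonnegative")
  structure(
    list(active_points = points, knear = as.integer(knear), theta = theta,
         groups = coordinate_groups(points)),
    class = "acl_distance_context"
  )
}

#' Reflection of a point through a centre
#'
#' @param x Numeric vector.
#' @param center Numeric vector of the same length.
#' @return `2 * center - x`.
#' @export
reflected_point <- function(x, center) {
  if (length(x) != length(center)) stop("dimension mismatch between x and center")
  2 * center - x
}

#' Symmetry measure of a point with respect to a centre
#'
#' The reflection of `x` through `center` is computed and its `knear`
#' coordinate-distinct nearest neighbours among all points in the context are
#' found; the measure is the mean of those neighbour distances. Small values
#' mean the dataset contains near-mirror images of `x` about `center`.
#'
#' @param x Point in the context's active subspace.
#' @param center Centre in the same subspace.
#' @param ctx An `acl_distance_context`.
#' @return Nonnegative scalar.
#' @export
sym_measure <- function(x, center, ctx) {
  stopifnot(inherits(ctx, "acl_distance_context"))
  d <- ncol(ctx$active_points)
  if (length(x) != d || length(center) != d) {
    stop("x and center must match the context's active dimensionality")
  }
  r <- reflected_point(x, center)
  knear_mean_dist(matrix(r, 1L), ctx$active_points, ctx$knear, ctx$groups)[1L]
}

#' Point-symmetry distance
#'
#' Product of the symmetry measure of `x` about `center` and the Euclidean
#' distance between `x` and `center`, both in the active subspace. Zero when
#' `x` coincides with the centre or when enough points coincide with the
#' reflection.
#'
#' @inheritParams sym_measure
#' @return Nonnegative scalar.
#' @export
ps_distance <- function(x, center, ctx) {
  sym_measure(x, center, ctx) * sqrt(sum((x - center)^2))
}

#' Maximum nearest-neighbour distance (the symmetry threshold)
#'
#' For every point, the distance to its nearest neighbour at a distinct
#' index is found (coincident duplicates therefore contribute zero); the
#' maximum of these is returned.
#'
#' @param points Numeric matrix with at least 2 rows.
#' @return Nonnegative scalar.
#' @export
max_nn_distance <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  D2 <- cross_dist2(points, points)
  diag(D2) <- Inf
  sqrt(max(apply(D2, 1L, min)))
}

# Batch symmetry measures of all rows of X about one centre, neighbours
# searched in `ctx` (assignment-time search over the whole projected set).
sym_measure_batch <- function(X, center, ctx) {
  R <- sweep(-X, 2L, 2 * center, `+`)
  knear_mean_dist(R, ctx$active_points, ctx$knear, ctx$groups)
}
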