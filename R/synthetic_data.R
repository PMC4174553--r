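#' Specification of a synthetic labelled mixture
#'
#' Describes a planted-cluster dataset: `k_true` clusters of symmetric shapes
#' living in `relevant_d` informative dimensions, padded with `noise_d`
#' label-independent uniform noise dimensions, with class labels known for a
#' `labeled_fraction` of the samples. All shapes have unit within-cluster
#' scale, so `separation` is the centre spacing in units of that scale.
#'
#' @param n Total sample count.
#' @param k_true Number of planted clusters (>= 2).
#' @param relevant_d Number of informative dimensions (>= 1; >= 2 for rings).
#' @param noise_d Number of irrelevant noise dimensions.
#' @param shapes Cluster shapes, recycled to length `k_true`; each one of
#'   `"spherical"`, `"elliptical"`, `"ring"`.
#' @param separation Pairwise centre distance in within-cluster scale units.
#' @param labeled_fraction Fraction of samples with known labels, in (0, 1].
#' @param seed Integer seed.
#' @return An object of class `acl_synthetic_spec`.
#' @export
synthetic_spec <- function(n = 300L, k_true = 3L, relevant_d = 2L,
                           noise_d = 3L, shapes = "spherical",
                           separation = 6, labeled_fraction = 0.1,
                           seed = 1L) {
  if (k_true < 2L) stop("k_true must be >= 2")
  if (relevant_d < 1L) stop("relevant_d must be >= 1")
  if (noise_d < 0L) stop("noise_d must be >= 0")
  if (separation <= 0) stop("separation must be positive")
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    stop("labeled_fraction must lie in (0, 1]")
  }
  shapes <- match.arg(shapes, c("spherical", "elliptical", "ring"),
                      several.ok = TRUE)
  shapes <- rep_len(shapes, k_true)
  if (any(shapes == "ring") && relevant_d < 2L) {
    stop("ring-shaped clusters need relevant_d >= 2")
  }
  structure(
    list(n = as.integer(n), k_true = as.integer(k_true),
         relevant_d = as.integer(relevant_d), noise_d = as.integer(noise_d),
         shapes = shapes, separation = separation,
         labeled_fraction = labeled_fraction, seed = as.integer(seed)),
    class = "acl_synthetic_spec"
  )
}

#' Generate a labelled mixture with planted symmetric clusters
#'
#' Cluster centres are placed along the diagonal of the relevant subspace at
#' spacing `separation` per coordinate, so pairwise centre distances are at
#' least `separation` within-cluster scale units. Spherical clusters are
#' isotropic unit Gaussians; elliptical clusters are axis-aligned Gaussians
#' with standard deviations decreasing linearly from 1 to 0.3 across the
#' relevant dimensions; rings live in the first two relevant dimensions with
#' unit radius, Gaussian radial jitter (sd 0.05 of the radius) and uniform
#' angle, and sd-0.05 Gaussian spread in any remaining relevant dimensions.
#' Every shape is point-symmetric about its centre. Noise dimensions are
#' drawn uniformly over the bounding range of the relevant dimensions,
#' independently of the labels. Cluster sizes are as equal as possible and
#' sum to `n`. Deterministic per `spec$seed`.
#'
#' @param spec An `acl_synthetic_spec`.
#' @return An `acl_dataset` with `true_labels` and `labeled_idx` set, and an
#'   attribute `true_relevant_mask`: a 0/1 vector marking the informative
#'   features.
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "acl_synthetic_spec"))
  n <- spec$n; k <- spec$k_true; rd <- spec$relevant_d; nd <- spec$noise_d
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(k), sizes)
  centers <- outer(seq_len(k) - 1, rep(spec$separation, rd))

  pts <- withr::with_seed(spec$seed, {
    rel <- matrix(0, n, rd)
    for (j in seq_len(k)) {
      rows <- which(labels == j)
      m <- length(rows)
      rel[rows, ] <- switch(
        spec$shapes[j],
        spherical = matrix(stats::rnorm(m * rd), m, rd),
        elliptical = {
          sds <- seq(1, 0.3, length.out = rd)
          sweep(matrix(stats::rnorm(m * rd), m, rd), 2, sds, `*`)
        },
        ring = {
          ang <- stats::runif(m, 0, 2 * pi)
          rad <- 1 + stats::rnorm(m, sd = 0.05)
          out <- cbind(rad * cos(ang), rad * sin(ang))
          if (rd > 2L) out <- cbind(out, matrix(stats::rnorm(m * (rd - 2L), sd = 0.05), m))
          out
        }
      )
      rel[rows, ] <- sweep(rel[rows, , drop = FALSE], 2, centers[j, ], `+`)
    }
    if (nd > 0L) {
      rng <- range(rel)
      noise <- matrix(stats::runif(n * nd, rng[1L], rng[2L]), n, nd)
      cbind(rel, noise)
    } else rel
  })

  feature_names <- c(
    paste0("rel_", seq_len(rd)),
    if (nd > 0L) paste0("noise_", seq_len(nd))
  )
  labeled_idx <- label_subsample(labels, spec$labeled_fraction,
                                 seed = spec$seed + 1L)
  ds <- dataset(pts, feature_names, true_labels = labels,
                labeled_idx = labeled_idx)
  attr(ds, "true_relevant_mask") <- as.integer(c(rep(1L, rd), rep(0L, nd)))
  ds
}

#' Draw the labelled subset
#'
#' Uniform sample without replacement of `round(fraction * n)` indices
#' (round-half-even), deterministic per seed.
#'
#' @param x An `acl_dataset` with `true_labels`, or a label vector.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Sorted integer vector of 1-based sample indices.
#' @export
label_subsample <- function(x, fraction, seed = 1L) {
  labels <- if (inherits(x, "acl_dataset")) x$true_labels else x
  if (is.null(labels)) stop("label_subsample requires true labels")
  draw_labeled_idx(labels, fraction, seed, stratified = FALSE)
}
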