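#' Algorithm variants
#'
#' The full method (`"semi-ps"`) assigns points by the theta-gated
#' point-symmetry distance and optimises four objectives: Sym-index (max),
#' Xie-Beni index (min), adjusted Rand index on the labelled subset (max)
#' and the number of active features (max). The ablations drop one
#' ingredient each: `"semi-euc"` swaps in plain Euclidean assignment;
#' `"feaclus"` drops the labelled-ARI objective (unsupervised feature
#' selection + clustering); `"vamosa"` additionally freezes the feature mask
#' to all ones and optimises only Sym and XB (pure automatic clustering).
#' `"kmeans"` names the [kmeans_baseline()].
#'
#' @param name One of `"semi-ps"`, `"semi-euc"`, `"feaclus"`, `"vamosa"`.
#' @return A list of class `acl_variant` with `name`, `distance`,
#'   `objectives` (named direction vector) and `feature_selection`.
#' @export
variant_spec <- function(name = c("semi-ps", "semi-euc", "feaclus", "vamosa")) {
  name <- match.arg(name)
  v <- switch(name,
    "semi-ps" = list(distance = "point-symmetry",
                     objectives = c(sym = "max", xb = "min", ari = "max",
                                    n_features = "max"),
                     feature_selection = TRUE),
    "semi-euc" = list(distance = "euclidean",
                      objectives = c(sym = "max", xb = "min", ari = "max",
                                     n_features = "max"),
                      feature_selection = TRUE),
    "feaclus" = list(distance = "point-symmetry",
                     objectives = c(sym = "max", xb = "min",
                                    n_features = "max"),
                     feature_selection = TRUE),
    "vamosa" = list(distance = "point-symmetry",
                    objectives = c(sym = "max", xb = "min"),
                    feature_selection = FALSE)
  )
  structure(c(list(name = name), v), class = "acl_variant")
}

# Assignment given a prebuilt distance context (hot path).
assign_with_context <- function(X, C, ctx, distance) {
  D2c <- cross_dist2(C, C)
  diag(D2c) <- Inf
  if (min(D2c) <= 0 || anyDuplicated(C) > 0L) {
    degenerate_solution("coincident cluster centres")
  }
  De <- sqrt(cross_dist2(X, C))
  euc <- max.col(-De, ties.method = "first")
  if (distance == "euclidean") return(euc)
  K <- nrow(C)
  Dsym <- vapply(seq_len(K), function(k) sym_measure_batch(X, C[k, ], ctx),
                 numeric(nrow(X)))
  Dps <- Dsym * De
  kstar <- max.col(-Dps, ties.method = "first")
  gate <- Dsym[cbind(seq_len(nrow(X)), kstar)] < ctx$theta
  ifelse(gate, kstar, euc)
}

#' Assign points to the clusters of a candidate solution
#'
#' In point-symmetry mode each point goes to the centre minimising the
#' point-symmetry distance, provided the corresponding symmetry measure is
#' below the threshold theta; otherwise it falls back to the Euclidean
#' nearest centre. In Euclidean mode assignment is always to the Euclidean
#' nearest centre. All distances live in the solution's active feature
#' subspace.
#'
#' @param ds An `acl_dataset`.
#' @param sol An `acl_solution`.
#' @param distance `"point-symmetry"` or `"euclidean"`.
#' @param theta Optional threshold override (`Inf` gives pure symmetry
#'   assignment, `0` pure Euclidean).
#' @param knear Neighbour count of the symmetry measure.
#' @param theta_scope Whether the default theta is the maximum
#'   nearest-neighbour distance in the active subspace (`"subspace"`,
#'   default, the space all other distances live in) or in the full feature
#'   space (`"full"`).
#' @return Integer vector of cluster labels in `1..K`.
#' @export
assign_points <- function(ds, sol, distance = c("point-symmetry", "euclidean"),
                          theta = NULL, knear = 2L,
                          theta_scope = c("subspace", "full")) {
  distance <- match.arg(distance)
  theta_scope <- match.arg(theta_scope)
  stopifnot(inherits(ds, "acl_dataset"), inherits(sol, "acl_solution"))
  pr <- project_active(ds$points, sol$centers, sol$mask)
  if (is.null(theta) && theta_scope == "full") {
    theta <- max_nn_distance(ds$points)
  }
  ctx <- distance_context(ds$points, sol$mask, knear = knear, theta = theta)
  assign_with_context(pr$X, pr$C, ctx, distance)
}

# Worst-case objective values substituted for degenerate solutions.
worst_objectives <- function(objectives) {
  worst <- c(sym = 0, xb = 1e12, ari = -1, n_features = 0)
  worst[names(objectives)]
}

#' Evaluate a candidate solution's objectives under a variant
#'
#' Points are assigned with the variant's distance, then the variant's
#' objectives are computed in declared order. The labelled-subset ARI
#' compares the induced partition, restricted to the labelled indices, with
#' the known labels (ARI is label-permutation invariant, so cluster ids need
#' not match class ids). Degenerate solutions (coincident centres, an empty
#' cluster, a cluster too small for the symmetry measure) receive worst-case
#' values (Sym 0, XB 1e12, ARI -1, features 0) instead of raising.
#'
#' @inheritParams assign_points
#' @param variant An `acl_variant`.
#' @return Named numeric objective vector.
#' @export
evaluate_objectives <- function(ds, sol, variant, knear = 2L,
                                theta_scope = c("subspace", "full")) {
  stopifnot(inherits(variant, "acl_variant"))
  theta_scope <- match.arg(theta_scope)
  obj_names <- names(variant$objectives)
  tryCatch({
    part <- assign_points(ds, sol, variant$distance, knear = knear,
                          theta_scope = theta_scope)
    objective_values(ds, sol, part, obj_names, knear)
  }, acl_degenerate = function(e) worst_objectives(variant$objectives))
}

# Objective values for an already-computed partition; raises acl_degenerate.
objective_values <- function(ds, sol, part, obj_names, knear) {
  if (any(tabulate(part, nbins = sol$K) == 0L)) {
    degenerate_solution("empty cluster")
  }
  vals <- vapply(obj_names, function(nm) {
    switch(nm,
      sym = sym_index(ds$points, part, sol$centers, sol$mask, knear),
      xb = xb_index(ds$points, part, sol$centers, sol$mask),
      ari = adjusted_rand(ds$true_labels[ds$labeled_idx],
                          part[ds$labeled_idx]),
      n_features = as.numeric(sum(sol$mask))
    )
  }, numeric(1))
  stats::setNames(vals, obj_names)
}

#' Select the best archive member using the labelled subset
#'
#' For every archive member the labelled points are assigned to the nearest
#' centre by Euclidean distance in the member's active subspace, and the
#' member minimising the Minkowski score of that assignment against the true
#' labels is returned (ties to the lower index).
#'
#' @param archive An `acl_archive` whose member solutions are
#'   `acl_solution`s.
#' @param ds An `acl_dataset` with a nonempty labelled subset.
#' @return Integer index into the archive.
#' @export
select_best_solution <- function(archive, ds) {
  stopifnot(inherits(archive, "acl_archive"))
  if (length(archive$members) < 1L) stop("archive is empty")
  if (length(ds$labeled_idx) < 1L) stop("labelled subset is empty")
  truth <- ds$true_labels[ds$labeled_idx]
  scores <- vapply(archive$members, function(m) {
    sol <- m$solution
    pr <- project_active(ds$points[ds$labeled_idx, , drop = FALSE],
                         sol$centers, sol$mask)
    lab <- max.col(-cross_dist2(pr$X, pr$C), ties.method = "first")
    tryCatch(minkowski_score(truth, lab), error = function(e) Inf)
  }, numeric(1))
  which.min(scores)
}

run_result <- function(archive_solutions, best, partition, metadata) {
  structure(list(archive = archive_solutions, best = as.integer(best),
                 partition = as.integer(partition), metadata = metadata),
            class = "acl_run_result")
}

#' @export
print.acl_run_result <- function(x, ...) {
  b <- x$archive[[x$best]]
  cat(sprintf("<acl_run_result> variant %s: %d archive solutions; best has K = %d, %d/%d features\n",
              x$metadata$variant, length(x$archive), nrow(b$centers),
              sum(b$mask), length(b$mask)))
  invisible(x)
}

#' Run one algorithm variant end to end
#'
#' Wires the solution encoding, the theta-gated assignment and the objective
#' evaluation into the AMOSA annealer, then picks the final solution: the
#' semi-supervised variants select the archive member with the lowest
#' labelled-subset Minkowski score, the unsupervised variants
#' (`feaclus`, `vamosa`) the member with the highest Sym-index (overridable
#' via `best_rule`). The reported partition is recomputed from the selected
#' solution's centres and mask. Theta values and distance contexts are
#' cached per feature mask within the run.
#'
#' @param ds An `acl_dataset` (labelled subset required for the
#'   semi-supervised variants).
#' @param variant Variant name or an `acl_variant`.
#' @param config An `acl_amosa_config`.
#' @param kmax Upper bound on the number of clusters; default
#'   `round(sqrt(n))`.
#' @param seed Integer seed (overrides `config$seed`).
#' @param knear Neighbour count of the symmetry measure.
#' @param theta_scope See [assign_points()].
#' @param best_rule `"auto"` (per-variant default), `"minkowski"` or
#'   `"sym"`.
#' @return An `acl_run_result`.
#' @export
run_variant <- function(ds, variant, config = amosa_config(),
                        kmax = NULL, seed = config$seed, knear = 2L,
                        theta_scope = c("subspace", "full"),
                        best_rule = c("auto", "minkowski", "sym")) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(ds, "acl_dataset"), inherits(variant, "acl_variant"))
  theta_scope <- match.arg(theta_scope)
  best_rule <- match.arg(best_rule)
  n <- nrow(ds$points); F <- ncol(ds$points)
  if (is.null(kmax)) kmax <- max(2L, as.integer(round(sqrt(n))))
  semi <- "ari" %in% names(variant$objectives)
  if (semi && length(ds$labeled_idx) < 1L) {
    stop("semi-supervised variants need a labelled subset")
  }
  if (is.null(seed)) stop("a seed is required for a reproducible run")
  config$seed <- as.integer(seed)
  params <- mutation_params(delta = 1.0, kmax = kmax)
  freeze <- !variant$feature_selection
  full_mask <- rep(1L, F)
  theta_full <- if (theta_scope == "full") max_nn_distance(ds$points) else NULL

  ctx_cache <- new.env(parent = emptyenv())
  get_ctx <- function(mask) {
    key <- paste(mask, collapse = "")
    ctx <- ctx_cache[[key]]
    if (is.null(ctx)) {
      ctx <- distance_context(ds$points, mask, knear = knear,
                              theta = theta_full)
      ctx_cache[[key]] <- ctx
    }
    ctx
  }

  evaluate <- function(sol) {
    tryCatch({
      pr <- project_active(ds$points, sol$centers, sol$mask)
      part <- assign_with_context(pr$X, pr$C, get_ctx(sol$mask),
                                  variant$distance)
      objective_values(ds, sol, part, names(variant$objectives), knear)
    }, acl_degenerate = function(e) worst_objectives(variant$objectives))
  }

  problem <- list(
    random_solution = function() {
      sol <- random_solution(ds, kmax)
      if (freeze) sol$mask <- full_mask
      sol
    },
    mutate = function(sol) {
      out <- mutate_solution(sol, ds, params)
      if (freeze) out$mask <- full_mask
      out
    },
    evaluate = evaluate,
    directions = unname(variant$objectives)
  )

  archive <- anneal(problem, config)
  rule <- if (best_rule == "auto") {
    if (semi) "minkowski" else "sym"
  } else best_rule
  best <- if (rule == "minkowski") {
    select_best_solution(archive, ds)
  } else {
    sym_pos <- match("sym", names(variant$objectives))
    which.max(vapply(archive$members, function(m) m$objectives[sym_pos],
                     numeric(1)))
  }
  best_sol <- archive$members[[best]]$solution
  partition <- assign_points(ds, best_sol, variant$distance, knear = knear,
                             theta_scope = theta_scope)
  run_result(
    archive_solutions = lapply(archive$members, function(m) {
      list(mask = m$solution$mask, centers = m$solution$centers,
           objectives = m$objectives)
    }),
    best = best,
    partition = partition,
    metadata = list(seed = config$seed, variant = variant$name,
                    kmax = kmax, knear = knear, theta_scope = theta_scope,
                    config = config[c("soft_limit", "hard_limit",
                                      "iter_per_temp", "t_max", "t_min",
                                      "cooling_rate", "init_factor")])
  )
}

#' K-means baseline
#'
#' Lloyd iterations from random data-point seeds until an assignment
#' fixpoint or 300 iterations, best of `restarts` restarts by within-cluster
#' sum of squares, with all features active.
#'
#' @param ds An `acl_dataset`.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param seed Integer seed.
#' @param restarts Number of random restarts (default 10).
#' @return An `acl_run_result` whose single archive entry carries the
#'   within-cluster sum of squares as its objective.
#' @export
kmeans_baseline <- function(ds, k, seed = 1L, restarts = 10L) {
  stopifnot(inherits(ds, "acl_dataset"))
  n <- nrow(ds$points)
  if (k < 2L || k > n) stop("k must lie in [2, n]")
  km <- withr::with_seed(as.integer(seed), {
    stats::kmeans(ds$points, centers = k, iter.max = 300L,
                  nstart = restarts, algorithm = "Lloyd")
  })
  run_result(
    archive_solutions = list(list(mask = rep(1L, ncol(ds$points)),
                                  centers = km$centers,
                                  objectives = c(wcss = km$tot.withinss))),
    best = 1L,
    partition = km$cluster,
    metadata = list(seed = as.integer(seed), variant = "kmeans", k = k,
                    restarts = restarts)
  )
}
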