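#' AMOSA configuration
#'
#' Archive limits and annealing schedule for archived multiobjective
#' simulated annealing. Defaults are the full study settings; tests and
#' examples typically use a reduced schedule.
#'
#' @param soft_limit Soft archive limit SL; a reduction to `hard_limit` is
#'   triggered whenever the archive exceeds it.
#' @param hard_limit Hard archive limit HL (< SL).
#' @param iter_per_temp Proposal/acceptance steps per temperature.
#' @param t_max,t_min Initial and final temperature.
#' @param cooling_rate Geometric cooling factor in (0, 1).
#' @param init_factor Initialisation draws `init_factor * soft_limit`
#'   hill-climbed random solutions (> 1).
#' @param seed Optional integer seed set at the start of [anneal()].
#' @return A list of class `acl_amosa_config`.
#' @export
amosa_config <- function(soft_limit = 100L, hard_limit = 50L,
                         iter_per_temp = 50L, t_max = 100, t_min = 1e-5,
                         cooling_rate = 0.9, init_factor = 2, seed = NULL) {
  if (!(soft_limit > hard_limit && hard_limit >= 1L)) {
    stop("need soft_limit > hard_limit >= 1")
  }
  if (cooling_rate <= 0 || cooling_rate >= 1) stop("cooling_rate must lie in (0, 1)")
  if (!(t_max > t_min && t_min > 0)) stop("need t_max > t_min > 0")
  if (init_factor <= 1) stop("init_factor must exceed 1")
  structure(
    list(soft_limit = as.integer(soft_limit), hard_limit = as.integer(hard_limit),
         iter_per_temp = as.integer(iter_per_temp), t_max = t_max,
         t_min = t_min, cooling_rate = cooling_rate,
         init_factor = init_factor, seed = seed),
    class = "acl_amosa_config"
  )
}

#' Geometric temperature schedule
#'
#' Temperatures `t_max * cooling_rate^t` for `t = 0, 1, ...` while they stay
#' at or above `t_min`.
#'
#' @inheritParams amosa_config
#' @return Numeric vector of temperature levels.
#' @export
temperature_schedule <- function(t_max, t_min, cooling_rate) {
  levels <- floor(log(t_min / t_max) / log(cooling_rate)) + 1L
  t_max * cooling_rate^(seq_len(levels) - 1)
}

# Signs turning every objective into a maximisation.
direction_signs <- function(directions) {
  if (!all(directions %in% c("max", "min"))) {
    stop("directions must be 'max' or 'min'")
  }
  ifelse(directions == "max", 1, -1)
}

#' Pareto dominance
#'
#' `u` dominates `v` iff it is no worse in every objective (per its
#' direction) and strictly better in at least one.
#'
#' @param u,v Objective vectors of equal length.
#' @param directions Character vector of `"max"` / `"min"` per objective.
#' @return Logical scalar.
#' @export
dominates <- function(u, v, directions) {
  if (length(u) != length(v) || length(u) != length(directions)) {
    stop("objective vector / direction length mismatch")
  }
  s <- direction_signs(directions)
  a <- s * u; b <- s * v
  all(a >= b) && any(a > b)
}

#' Amount of domination
#'
#' Product over the objectives on which `u` and `v` differ of the
#' range-normalised absolute gap `|u_i - v_i| / R_i`. Zero when `u == v`
#' (empty product convention). Scales the annealing acceptance
#' probabilities.
#'
#' @param u,v Objective vectors.
#' @param ranges Positive per-objective ranges `R_i`.
#' @return Nonnegative scalar.
#' @export
amount_of_domination <- function(u, v, ranges) {
  if (length(u) != length(v) || length(u) != length(ranges)) {
    stop("objective vector / range length mismatch")
  }
  if (any(ranges <= 0)) stop("all ranges must be positive")
  diffs <- abs(u - v)
  active <- diffs > 0
  if (!any(active)) return(0)
  prod(diffs[active] / ranges[active])
}

#' Non-dominated filter
#'
#' Indices of the objective vectors not dominated by any other vector in the
#' set (identical vectors are all kept, dominance being strict).
#'
#' @param objectives Numeric matrix, one row per solution, or a list of
#'   equal-length vectors.
#' @param directions Character vector of `"max"` / `"min"` per objective.
#' @return Integer vector of row indices.
#' @export
nondominated_filter <- function(objectives, directions) {
  if (is.list(objectives)) objectives <- do.call(rbind, objectives)
  objectives <- as.matrix(objectives)
  s <- direction_signs(directions)
  A <- sweep(objectives, 2L, s, `*`)
  m <- nrow(A)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    ge <- A >= matrix(A[i, ], m, ncol(A), byrow = TRUE)
    gt <- A > matrix(A[i, ], m, ncol(A), byrow = TRUE)
    dominated_by <- rowSums(ge) == ncol(A) & rowSums(gt) > 0
    dominated_by[i] <- FALSE
    if (any(dominated_by)) keep[i] <- FALSE
  }
  which(keep)
}

new_archive <- function(members, directions) {
  structure(list(members = members, directions = directions),
            class = "acl_archive")
}

#' @export
print.acl_archive <- function(x, ...) {
  cat(sprintf("<acl_archive> %d non-dominated solutions, %d objectives\n",
              length(x$members), length(x$directions)))
  invisible(x)
}

archive_objective_matrix <- function(archive) {
  do.call(rbind, lapply(archive$members, `[[`, "objectives"))
}

#' Reduce an archive by single-linkage clustering in objective space
#'
#' Objective vectors are range-normalised (minimised objectives
#' sign-flipped), clustered by single linkage into `target` groups, and each
#' group is represented by the member nearest its group centroid (ties to
#' the lower index). A reduction of a mutually non-dominated set stays
#' mutually non-dominated.
#'
#' @param archive An `acl_archive`.
#' @param target Desired size (>= 1).
#' @return The reduced `acl_archive`.
#' @export
reduce_archive <- function(archive, target) {
  stopifnot(inherits(archive, "acl_archive"))
  if (target < 1L) stop("target must be >= 1")
  m <- length(archive$members)
  if (m <= target) return(archive)
  A <- archive_objective_matrix(archive)
  s <- direction_signs(archive$directions)
  A <- sweep(A, 2L, s, `*`)
  rng <- pmax(apply(A, 2L, max) - apply(A, 2L, min), 1e-12)
  A <- sweep(A, 2L, rng, `/`)
  cl <- stats::cutree(stats::hclust(stats::dist(A), method = "single"),
                      k = target)
  keep <- vapply(seq_len(target), function(g) {
    ix <- which(cl == g)
    cen <- colMeans(A[ix, , drop = FALSE])
    d2 <- rowSums(sweep(A[ix, , drop = FALSE], 2L, cen, `-`)^2)
    ix[which.min(d2)]
  }, integer(1))
  new_archive(archive$members[sort(keep)], archive$directions)
}

# Per-objective ranges over the archive plus current and new objective
# vectors, floored at 1e-12.
running_ranges <- function(A, current_obj, new_obj) {
  M <- rbind(A, current_obj, new_obj)
  pmax(apply(M, 2L, max) - apply(M, 2L, min), 1e-12)
}

# Acceptance probability when the proposal is dominated: logistic in the
# average amount of domination over temperature. Increases with T, decreases
# with the domination gap, and vanishes as T -> 0.
acceptance_probability <- function(dom_avg, temperature) {
  1 / (1 + exp(dom_avg / temperature))
}

#' Archived multiobjective simulated annealing
#'
#' Generic annealer over an abstract problem. The problem is a list with
#' `random_solution()` (fresh state), `mutate(sol)` (proposal),
#' `evaluate(sol)` (deterministic objective vector) and `directions`
#' (`"max"`/`"min"` per objective). Initialisation draws
#' `init_factor * soft_limit` random solutions, refines each by
#' `iter_per_temp` hill-climbing steps (a mutant is accepted iff it
#' dominates the incumbent), seeds the archive with the non-dominated set
#' (reduced to the hard limit if above it), then anneals through the
#' geometric temperature schedule with `iter_per_temp` proposals per level.
#' A proposal dominated by the incumbent and/or archive members is accepted
#' as incumbent with probability `1 / (1 + exp(dom_avg / T))`; mutually
#' non-dominating proposals enter the archive (purging members they
#' dominate) unless archive members dominate them; a proposal dominating the
#' incumbent replaces it, except that when an archive member dominates the
#' proposal the incumbent jumps to that member with probability 1/2.
#' Whenever the archive exceeds the soft limit it is reduced to the hard
#' limit by [reduce_archive()].
#'
#' @param problem The abstract problem (see Details above).
#' @param config An `acl_amosa_config`.
#' @return An `acl_archive` of mutually non-dominated solutions.
#' @export
anneal <- function(problem, config) {
  stopifnot(inherits(config, "acl_amosa_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  directions <- problem$directions
  n_init <- ceiling(config$init_factor * config$soft_limit)

  # hill-climbed random initialisation
  inits <- vector("list", n_init)
  for (i in seq_len(n_init)) {
    sol <- problem$random_solution()
    obj <- problem$evaluate(sol)
    for (s in seq_len(config$iter_per_temp)) {
      cand <- problem$mutate(sol)
      cobj <- problem$evaluate(cand)
      if (dominates(cobj, obj, directions)) {
        sol <- cand; obj <- cobj
      }
    }
    inits[[i]] <- list(solution = sol, objectives = obj)
  }
  objs <- do.call(rbind, lapply(inits, `[[`, "objectives"))
  archive <- new_archive(inits[nondominated_filter(objs, directions)],
                         directions)
  if (length(archive$members) > config$hard_limit) {
    archive <- reduce_archive(archive, config$hard_limit)
  }

  pick <- sample.int(length(archive$members), 1L)
  current_sol <- archive$members[[pick]]$solution
  current_obj <- archive$members[[pick]]$objectives

  add_member <- function(archive, sol, obj, purge_idx) {
    members <- archive$members
    if (length(purge_idx) > 0L) members <- members[-purge_idx]
    members[[length(members) + 1L]] <- list(solution = sol, objectives = obj)
    archive <- new_archive(members, directions)
    if (length(archive$members) > config$soft_limit) {
      archive <- reduce_archive(archive, config$hard_limit)
    }
    archive
  }

  for (temperature in temperature_schedule(config$t_max, config$t_min,
                                           config$cooling_rate)) {
    for (step in seq_len(config$iter_per_temp)) {
      new_sol <- problem$mutate(current_sol)
      new_obj <- problem$evaluate(new_sol)
      A <- archive_objective_matrix(archive)
      ranges <- running_ranges(A, current_obj, new_obj)
      dom_by_arch <- which(vapply(seq_len(nrow(A)), function(j) {
        dominates(A[j, ], new_obj, directions)
      }, logical(1)))
      dom_of_arch <- which(vapply(seq_len(nrow(A)), function(j) {
        dominates(new_obj, A[j, ], directions)
      }, logical(1)))

      if (dominates(current_obj, new_obj, directions)) {
        # dominated by the incumbent (and possibly archive members)
        doms <- c(list(current_obj),
                  lapply(dom_by_arch, function(j) A[j, ]))
        dom_avg <- mean(vapply(doms, amount_of_domination, numeric(1),
                               v = new_obj, ranges = ranges))
        if (stats::runif(1) < acceptance_probability(dom_avg, temperature)) {
          current_sol <- new_sol; current_obj <- new_obj
        }
      } else if (dominates(new_obj, current_obj, directions)) {
        # proposal dominates the incumbent
        if (length(dom_by_arch) > 0L) {
          if (stats::runif(1) < 0.5) {
            j <- dom_by_arch[1L]
            current_sol <- archive$members[[j]]$solution
            current_obj <- archive$members[[j]]$objectives
          } else {
            current_sol <- new_sol; current_obj <- new_obj
          }
        } else {
          archive <- add_member(archive, new_sol, new_obj, dom_of_arch)
          current_sol <- new_sol; current_obj <- new_obj
        }
      } else {
        # incumbent and proposal mutually non-dominating
        if (length(dom_by_arch) > 0L) {
          doms <- lapply(dom_by_arch, function(j) A[j, ])
          dom_avg <- mean(vapply(doms, amount_of_domination, numeric(1),
                                 v = new_obj, ranges = ranges))
          if (stats::runif(1) < acceptance_probability(dom_avg, temperature)) {
            current_sol <- new_sol; current_obj <- new_obj
          }
        } else {
          archive <- add_member(archive, new_sol, new_obj, dom_of_arch)
          current_sol <- new_sol; current_obj <- new_obj
        }
      }
    }
  }
  archive
}
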