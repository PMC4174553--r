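test_that("dominates implements strict Pareto dominance per direction", {
  mm <- c("max", "max")
  expect_true(dominates(c(2, 2), c(1, 1), mm))
  expect_false(dominates(c(2, 1), c(1, 2), mm))
  expect_false(dominates(c(1, 2), c(2, 1), mm))
  expect_false(dominates(c(1, 1), c(1, 1), mm))
  expect_true(dominates(c(1, 1), c(1, 2), c("max", "min")))
  expect_error(dominates(c(1, 2), c(1, 2, 3), mm), "length mismatch")
})

test_that("amount_of_domination is the product of normalised gaps", {
  expect_equal(amount_of_domination(c(2, 4), c(1, 2), ranges = c(2, 4)), 0.25)
  expect_identical(amount_of_domination(c(3, 3), c(3, 3), ranges = c(1, 1)), 0)
  expect_equal(amount_of_domination(c(5, 1), c(2, 1), ranges = c(3, 1)), 1)
  expect_error(amount_of_domination(c(1, 2), c(0, 0), ranges = c(1, 0)),
               "positive")
})

test_that("nondominated_filter matches examples and the brute-force oracle", {
  mm <- c("max", "max")
  objs <- rbind(c(1, 3), c(3, 1), c(2, 2), c(1, 1))
  expect_identical(nondominated_filter(objs, mm), 1:3)
  same <- rbind(c(2, 2), c(2, 2), c(2, 2))
  expect_identical(nondominated_filter(same, mm), 1:3)
  chain <- rbind(c(3, 3), c(2, 2), c(1, 1))
  expect_identical(nondominated_filter(chain, mm), 1L)
  withr::with_seed(41, {
    for (rep in 1:60) {
      m <- sample(2:20, 1); d <- sample(2:4, 1)
      dirs <- sample(c("max", "min"), d, TRUE)
      objs <- matrix(sample(1:4, m * d, TRUE), m, d)  # ties likely
      expect_identical(nondominated_filter(objs, dirs),
                       oracle_nondominated(objs, dirs))
    }
  })
})

test_that("the geometric temperature schedule has the closed-form length", {
  sched <- temperature_schedule(100, 1e-5, 0.9)
  expect_length(sched, 153L)
  expect_identical(sched[1], 100)
  expect_gte(sched[153], 1e-5)
  expect_lt(100 * 0.9^153, 1e-5)
  expect_true(all(diff(sched) < 0))
})

test_that("reduce_archive keeps one representative per objective-space clump", {
  dirs <- c("max", "max")
  mk <- function(obj) list(solution = NULL, objectives = obj)
  small <- new_archive(list(mk(c(1, 3)), mk(c(3, 1))), dirs)
  expect_identical(reduce_archive(small, 2L), small)
  # two tight non-dominated clumps of 5 along a front
  withr::with_seed(42, {
    clump1 <- lapply(1:5, function(i) mk(c(0 + i * 1e-3, 1 - i * 1e-3)))
    clump2 <- lapply(1:5, function(i) mk(c(1 + i * 1e-3, 0 - i * 1e-3)))
  })
  arch <- new_archive(c(clump1, clump2), dirs)
  red <- reduce_archive(arch, 2L)
  expect_length(red$members, 2L)
  f1 <- vapply(red$members, function(m) m$objectives[1], numeric(1))
  expect_identical(sum(f1 < 0.5), 1L)  # one member from each clump
  # reduction of a non-dominated set stays non-dominated
  objs <- do.call(rbind, lapply(red$members, `[[`, "objectives"))
  expect_identical(nondominated_filter(objs, dirs), seq_len(nrow(objs)))
  expect_error(reduce_archive(arch, 0L), "target")
})

test_that("acceptance probability is monotone in T and in the domination gap", {
  expect_lt(acceptance_probability(1, 0.1), acceptance_probability(1, 10))
  expect_lt(acceptance_probability(2, 1), acceptance_probability(1, 1))
  expect_equal(acceptance_probability(0, 5), 0.5)
  expect_lt(acceptance_probability(1, 1e-6), 1e-10)
})

test_that("amosa_config validates its invariants", {
  expect_error(amosa_config(soft_limit = 10L, hard_limit = 10L), "soft_limit")
  expect_error(amosa_config(cooling_rate = 1), "cooling_rate")
  expect_error(amosa_config(t_max = 1, t_min = 2), "t_max")
  expect_error(amosa_config(init_factor = 1), "init_factor")
})

# Toy bi-objective problem: maximize (x, 1 - x^2) on the domain x in [0, 1]
# (mutation clamps a Gaussian step to the domain). Every feasible x is
# Pareto-optimal, so the analytic front is { (x, 1 - x^2) : x in [0, 1] }.
toy_problem <- function(step_sd = 0.1) {
  list(
    random_solution = function() stats::runif(1),
    mutate = function(x) min(max(x + stats::rnorm(1, sd = step_sd), 0), 1),
    evaluate = function(x) c(f1 = x, f2 = 1 - x^2),
    directions = c("max", "max")
  )
}

test_that("anneal recovers the toy bi-objective Pareto front", {
  cfg <- amosa_config(soft_limit = 30L, hard_limit = 15L, iter_per_temp = 20L,
                      t_max = 1, t_min = 1e-3, cooling_rate = 0.8, seed = 7L)
  arch <- anneal(toy_problem(), cfg)
  expect_s3_class(arch, "acl_archive")
  expect_lte(length(arch$members), cfg$soft_limit)
  expect_gte(length(arch$members), 2L)
  # every archive member lies within 1e-2 of the analytic front
  objs <- do.call(rbind, lapply(arch$members, `[[`, "objectives"))
  gap <- abs(objs[, "f2"] - (1 - objs[, "f1"]^2))
  expect_gte(mean(gap <= 1e-2 & objs[, "f1"] >= 0 & objs[, "f1"] <= 1), 0.95)
  # the archive is mutually non-dominated and spread along the front
  expect_identical(nondominated_filter(objs, arch$directions),
                   seq_len(nrow(objs)))
  expect_gt(max(objs[, "f1"]) - min(objs[, "f1"]), 0.3)
})

test_that("anneal is deterministic for a fixed seed", {
  cfg <- amosa_config(soft_limit = 12L, hard_limit = 6L, iter_per_temp = 10L,
                      t_max = 1, t_min = 0.05, cooling_rate = 0.7, seed = 9L)
  expect_identical(anneal(toy_problem(), cfg), anneal(toy_problem(), cfg))
})
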