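test_that("pair_counts matches hand enumeration and the oracle", {
  pc <- pair_counts(c(1, 1, 2), c(1, 2, 2))
  expect_identical(unlist(pc)[c("n11", "n10", "n01", "n00")],
                   c(n11 = 0, n10 = 1, n01 = 1, n00 = 1))
  labs <- c(1, 2, 1, 3, 2, 1)
  self <- pair_counts(labs, labs)
  expect_identical(self$n10, 0)
  expect_identical(self$n01, 0)
  single <- pair_counts(1:5, 1:5)
  expect_identical(unlist(single[c("n11", "n10", "n01")]),
                   c(n11 = 0, n10 = 0, n01 = 0))
  expect_error(pair_counts(c(1, 2), c(1, 2, 3)), "length mismatch")
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(4:15, 1)
      a <- sample(1:3, n, TRUE); b <- sample(1:4, n, TRUE)
      expect_identical(unlist(pair_counts(a, b)),
                       unlist(lapply(oracle_pair_counts(a, b), as.numeric)))
    }
  })
})

test_that("minkowski_score matches its definition and is asymmetric", {
  labs <- c(2, 2, 1, 3)
  expect_identical(minkowski_score(labs, labs), 0)
  expect_equal(minkowski_score(c(1, 1, 2), c(1, 2, 2)), sqrt(2),
               tolerance = 1e-15)
  expect_equal(minkowski_score(c(1, 1), c(1, 2)), 1)
  # undefined when the reference has no co-clustered pair
  expect_error(minkowski_score(1:4, c(1, 1, 2, 2)), "undefined")
  # concrete asymmetry counterexample
  expect_equal(minkowski_score(c(1, 1, 1), c(1, 1, 2)), sqrt(2 / 3))
  expect_equal(minkowski_score(c(1, 1, 2), c(1, 1, 1)), sqrt(2))
  withr::with_seed(22, {
    for (rep in 1:25) {
      n <- sample(4:15, 1)
      a <- rep(1:2, length.out = n); b <- sample(1:3, n, TRUE)
      expect_equal(minkowski_score(a, b), oracle_ms(a, b), tolerance = 1e-12)
    }
  })
})

test_that("adjusted_rand matches hand values, the oracle, and its conventions", {
  withr::with_seed(23, labs <- sample(1:4, 30, TRUE))
  expect_identical(adjusted_rand(labs, labs), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  # label-permutation invariance and symmetry
  expect_identical(adjusted_rand(labs, 5L - labs), 1)
  a <- sample(1:3, 12, TRUE); b <- sample(1:3, 12, TRUE)
  expect_equal(adjusted_rand(a, b), adjusted_rand(b, a), tolerance = 1e-15)
  # 0/0 convention: both partitions a single cluster
  expect_identical(adjusted_rand(rep(1, 5), rep(2, 5)), 1)
  expect_error(adjusted_rand(c(1, 2), c(1, 2, 3)), "length mismatch")
  withr::with_seed(24, {
    for (rep in 1:25) {
      n <- sample(4:15, 1)
      a <- sample(1:3, n, TRUE); b <- sample(1:4, n, TRUE)
      expect_equal(adjusted_rand(a, b), oracle_ari(a, b), tolerance = 1e-12)
    }
  })
})

test_that("adjusted_rand agrees with an independent library implementation", {
  withr::with_seed(26, {
    for (rep in 1:20) {
      n <- sample(10:40, 1)
      a <- sample(1:4, n, TRUE); b <- sample(1:3, n, TRUE)
      expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("MS = 0 iff ARI = 1 on valid inputs", {
  withr::with_seed(25, {
    for (rep in 1:10) {
      a <- sample(1:3, 12, TRUE)
      a[1:2] <- 1L  # guarantee a co-clustered reference pair
      b <- sample(1:3, 12, TRUE)
      ms0 <- minkowski_score(a, b) == 0
      ari1 <- isTRUE(all.equal(adjusted_rand(a, b), 1))
      expect_identical(ms0, ari1)
    }
  })
})

test_that("xb_index matches the worked configuration and its invariances", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  ctrs <- rbind(c(0, 0.5), c(10, 0.5))
  part <- c(1, 1, 2, 2)
  expect_equal(xb_index(pts, part, ctrs), 1 / (4 * 100), tolerance = 1e-15)
  # numerator zero when each point is its own centre
  expect_equal(xb_index(pts, 1:4, pts), 0)
  # invariant under uniform scaling and rigid translation
  s <- 3.7
  expect_equal(xb_index(s * pts, part, s * ctrs), xb_index(pts, part, ctrs),
               tolerance = 1e-12)
  sh <- c(5, -2)
  expect_equal(xb_index(sweep(pts, 2, sh, `+`), part,
                        sweep(ctrs, 2, sh, `+`)),
               xb_index(pts, part, ctrs), tolerance = 1e-12)
  # masked evaluation uses the active subspace only
  pts3 <- cbind(pts, c(100, -50, 7, 3))
  ctrs3 <- cbind(ctrs, c(0, 0))
  expect_equal(xb_index(pts3, part, ctrs3, mask = c(1L, 1L, 0L)),
               xb_index(pts, part, ctrs), tolerance = 1e-15)
  expect_error(xb_index(pts, part, rbind(c(1, 1), c(1, 1))),
               class = "acl_degenerate")
  expect_error(xb_index(pts, rep(1, 4), ctrs[1, , drop = FALSE]), "K >= 2")
})

test_that("sym_index matches the worked configuration and its invariances", {
  pts <- rbind(c(0, 0), c(2, 0), c(10, 0), c(12, 0))
  ctrs <- rbind(c(1, 0), c(11, 0))
  part <- c(1, 1, 2, 2)
  expect_equal(sym_index(pts, part, ctrs), 10 / (2 * 4), tolerance = 1e-15)
  sh <- c(-3, 8)
  expect_equal(sym_index(sweep(pts, 2, sh, `+`), part,
                         sweep(ctrs, 2, sh, `+`)),
               sym_index(pts, part, ctrs), tolerance = 1e-9)
  # widening the inter-centre gap with clusters fixed strictly increases Sym
  pts_far <- rbind(pts[1:2, ], sweep(pts[3:4, ], 2, c(20, 0), `+`))
  ctrs_far <- rbind(ctrs[1, ], ctrs[2, ] + c(20, 0))
  expect_gt(sym_index(pts_far, part, ctrs_far), sym_index(pts, part, ctrs))
  # degenerate cases signal rather than crash
  expect_error(sym_index(pts, c(1, 1, 1, 2), ctrs), class = "acl_degenerate")
  expect_error(sym_index(pts, part, rbind(c(1, 0), c(1, 0))),
               class = "acl_degenerate")
})

test_that("degenerate solutions carry the acl_degenerate condition class", {
  cond <- tryCatch(degenerate_solution("why"), condition = identity)
  expect_s3_class(cond, "acl_degenerate")
  expect_s3_class(cond, "error")
  expect_match(conditionMessage(cond), "why")
})
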