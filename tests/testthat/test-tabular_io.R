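write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_dataset draws the labelled subset reproducibly and at the right size", {
  withr::with_seed(7, {
    df <- data.frame(a = rnorm(150), b = rnorm(150),
                     class = sample(1:3, 150, TRUE))
  })
  path <- write_fixture_csv(df)
  ds <- read_dataset(path, label_column = "class", labeled_fraction = 0.1,
                     seed = 3)
  expect_equal(length(ds$labeled_idx), 15L)
  expect_equal(ncol(ds$points), 2L)
  expect_true(all(ds$labeled_idx %in% seq_len(150)))
  # same seed, same subset; different seed, (almost surely) different subset
  ds2 <- read_dataset(path, label_column = "class", labeled_fraction = 0.1,
                      seed = 3)
  expect_identical(ds$labeled_idx, ds2$labeled_idx)
  ds3 <- read_dataset(path, label_column = "class", labeled_fraction = 0.1,
                      seed = 4)
  expect_false(identical(ds$labeled_idx, ds3$labeled_idx))
  # fraction 1 labels everything
  ds_all <- read_dataset(path, label_column = "class", labeled_fraction = 1,
                         seed = 1)
  expect_identical(ds_all$labeled_idx, seq_len(150))
})

test_that("stratified labelled sampling is proportional per class", {
  withr::with_seed(8, {
    df <- data.frame(a = rnorm(200), class = rep(c(1, 2), c(150, 50)))
  })
  path <- write_fixture_csv(df)
  ds <- read_dataset(path, label_column = "class", labeled_fraction = 0.1,
                     seed = 5, stratified = TRUE)
  cls <- ds$true_labels[ds$labeled_idx]
  expect_equal(sum(cls == 1), 15L)
  expect_equal(sum(cls == 2), 5L)
})

test_that("read_dataset rejects malformed input with informative errors", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "oops,4"), p1)
  expect_error(read_dataset(p1, labeled_fraction = NULL), "non-numeric")
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", ",4"), p2)
  expect_error(read_dataset(p2, labeled_fraction = NULL), "missing value")
  # labelled fraction requested but no label column present
  p3 <- write_fixture_csv(data.frame(a = 1:4, b = 4:1))
  expect_error(read_dataset(p3, labeled_fraction = 0.1), "label_column")
  expect_error(read_dataset(p3, label_column = "class"), "not present")
  expect_error(read_dataset(tempfile(), labeled_fraction = NULL), "not found")
})

test_that("dataset constructor enforces its invariants", {
  expect_error(dataset(matrix(1, 1, 2)), "at least 2 samples")
  expect_error(dataset(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(dataset(matrix(1:4, 2, 2), labeled_idx = 1L), "true_labels")
  expect_error(dataset(matrix(1:4, 2, 2), true_labels = c(1, 2),
                       labeled_idx = 5L), "out of range")
})

test_that("dataset CSV round trip preserves points to full precision", {
  withr::with_seed(2, {
    ds <- dataset(matrix(rnorm(40), 10, 4), paste0("f", 1:4),
                  true_labels = rep(1:2, 5), labeled_idx = c(1L, 4L))
  })
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path, label_column = "class", labeled_fraction = 0.2,
                       seed = 9)
  expect_identical(unname(back$points), unname(ds$points))
  expect_identical(back$true_labels, ds$true_labels)
})

test_that("run results round trip through JSON and writes are byte-identical", {
  ds <- random_dataset(n = 20, F = 3, k = 2, seed = 4)
  res <- kmeans_baseline(ds, k = 2, seed = 1)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_result(res, p1)
  write_result(res, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_result(p1)
  expect_identical(back$partition, res$partition)
  expect_identical(back$archive[[1]]$mask, res$archive[[1]]$mask)
  expect_equal(back$archive[[1]]$centers, unname(res$archive[[1]]$centers))
  expect_identical(back$best, res$best)
  # an empty archive is rejected
  res_bad <- res
  res_bad$archive <- list()
  expect_error(write_result(res_bad, tempfile()), "at least one")
})

test_that("partitions export as a two-column CSV", {
  ds <- random_dataset(n = 12, F = 2, k = 2, seed = 5)
  res <- kmeans_baseline(ds, k = 2, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_partition_csv(res, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("sample_id", "cluster"))
  expect_identical(df$cluster, res$partition)
})
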