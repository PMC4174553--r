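#' Construct a dataset object
#'
#' A dataset bundles the numeric feature matrix with optional ground-truth
#' class labels and the indices of the samples whose labels are treated as
#' known (the supervised fraction used by the semi-supervised variants).
#'
#' @param points Numeric matrix, rows = samples, columns = features.
#' @param feature_names Character vector of length `ncol(points)`.
#' @param true_labels Optional integer vector of length `nrow(points)`.
#' @param labeled_idx Integer vector of row indices (1-based) whose labels
#'   are considered known. Must be empty when `true_labels` is `NULL`.
#' @return An object of class `acl_dataset`.
#' @export
dataset <- function(points, feature_names = colnames(points),
                    true_labels = NULL, labeled_idx = integer(0)) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 2L) stop("a dataset needs at least 2 samples")
  if (ncol(points) < 1L) stop("a dataset needs at least 1 feature")
  if (anyNA(points)) stop("dataset contains missing values")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(points)))
  if (length(feature_names) != ncol(points)) {
    stop("feature_names length does not match the number of columns")
  }
  if (!is.null(true_labels)) {
    true_labels <- as.integer(as.factor(true_labels))
    if (length(true_labels) != n) stop("true_labels length does not match n")
  }
  labeled_idx <- sort(unique(as.integer(labeled_idx)))
  if (length(labeled_idx) > 0L) {
    if (is.null(true_labels)) {
      stop("labeled_idx requires true_labels to be present")
    }
    if (any(labeled_idx < 1L) || any(labeled_idx > n)) {
      stop("labeled_idx out of range")
    }
  }
  structure(
    list(points = points, feature_names = feature_names,
         true_labels = true_labels, labeled_idx = labeled_idx),
    class = "acl_dataset"
  )
}

#' @export
print.acl_dataset <- function(x, ...) {
  cat(sprintf("<acl_dataset> %d samples x %d features", nrow(x$points),
              ncol(x$points)))
  if (!is.null(x$true_labels)) {
    cat(sprintf("; %d classes, %d labelled samples",
                length(unique(x$true_labels)), length(x$labeled_idx)))
  }
  cat("\n")
  invisible(x)
}

#' Read a dataset from CSV
#'
#' Reads a comma-separated table (header row required, '.' decimal point,
#' UTF-8) into a dataset. If `label_column` is given, that column is removed
#' from the feature matrix, converted to integer class labels, and a labelled
#' subset of size `round(labeled_fraction * n)` is drawn uniformly without
#' replacement (or per class when `stratified = TRUE`), reproducibly for a
#' given `seed`. Rows with missing values are rejected, not imputed.
#'
#' @param path Path to a CSV file.
#' @param label_column Optional name of the class-label column.
#' @param labeled_fraction Fraction of samples whose labels are treated as
#'   known; must lie in (0, 1]. Only used when `label_column` is given.
#' @param seed Integer seed controlling the labelled subsample.
#' @param stratified Draw the labelled subset proportionally per class
#'   instead of uniformly over all samples.
#' @return An `acl_dataset`.
#' @export
read_dataset <- function(path, label_column = NULL, labeled_fraction = 0.1,
                         seed = 1L, stratified = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop("dataset must contain at least 2 rows")
  true_labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not present in ", path)
    }
    true_labels <- df[[label_column]]
    df <- df[, setdiff(names(df), label_column), drop = FALSE]
  } else if (!missing(labeled_fraction) && !is.null(labeled_fraction)) {
    # a labelled fraction was explicitly requested but no label column exists
    stop("labeled_fraction requested but no label_column given")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(df)[j], if (is.na(bad)) 1L else bad))
    }
    miss <- which(is.na(col))
    if (length(miss) > 0L) {
      stop(sprintf("missing value in column '%s', row %d (rows with missing values are rejected)",
                   names(df)[j], miss[1L]))
    }
  }
  points <- as.matrix(df)
  labeled_idx <- integer(0)
  if (!is.null(true_labels)) {
    ds0 <- dataset(points, names(df), true_labels)
    labeled_idx <- draw_labeled_idx(ds0$true_labels, labeled_fraction, seed,
                                    stratified = stratified)
    return(dataset(points, names(df), true_labels, labeled_idx))
  }
  dataset(points, names(df))
}

# Uniform (or per-class stratified) draw of round(fraction * n) indices,
# deterministic per seed. Base round() is round-half-even.
draw_labeled_idx <- function(true_labels, fraction, seed, stratified = FALSE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("labeled fraction must lie in (0, 1]")
  }
  n <- length(true_labels)
  m <- as.integer(round(fraction * n))
  withr::with_seed(as.integer(seed), {
    if (!stratified) {
      sort(sample.int(n, m))
    } else {
      idx <- unlist(lapply(split(seq_len(n), true_labels), function(ix) {
        mk <- as.integer(round(fraction * length(ix)))
        if (mk == 0L) return(integer(0))
        ix[sample.int(length(ix), mk)]
      }), use.names = FALSE)
      sort(idx)
    }
  })
}

#' Write a run result to JSON
#'
#' Serialises the archive (feature masks as 0/1 strings, centres, objective
#' values), the selected best solution, the final partition and the run
#' metadata. The file is round-trippable via [read_result()] and two writes
#' of the same result are byte-identical.
#'
#' @param result A `run_result` as returned by [run_variant()] or
#'   [kmeans_baseline()].
#' @param path Output file path.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "acl_run_result"))
  if (length(result$archive) < 1L) stop("a run always yields at least one solution")
  out <- list(
    archive = lapply(result$archive, function(m) {
      list(mask = paste(m$mask, collapse = ""),
           centers = m$centers,
           objectives = as.list(m$objectives))
    }),
    best = result$best,
    partition = result$partition,
    metadata = result$metadata
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run result written by [write_result()]
#' @param path Path to the JSON file.
#' @return A `run_result`.
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  archive <- lapply(seq_len(length(x$archive$mask)), function(i) {
    list(
      mask = as.integer(strsplit(x$archive$mask[[i]], "")[[1]]),
      centers = {
        cm <- x$archive$centers[[i]]
        matrix(as.numeric(cm), nrow = nrow(cm), ncol = ncol(cm))
      },
      objectives = unlist(x$archive$objectives[i, , drop = TRUE])
    )
  })
  structure(
    list(archive = archive, best = as.integer(x$best),
         partition = as.integer(x$partition), metadata = x$metadata),
    class = "acl_run_result"
  )
}

#' Export a partition as a two-column CSV
#'
#' @param result A `run_result`.
#' @param path Output file path; columns `sample_id`, `cluster`.
#' @export
write_partition_csv <- function(result, path) {
  stopifnot(inherits(result, "acl_run_result"))
  utils::write.csv(
    data.frame(sample_id = seq_along(result$partition),
               cluster = result$partition),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a dataset to CSV (the dialect read by [read_dataset()])
#'
#' @param ds An `acl_dataset`.
#' @param path Output file path.
#' @param label_column Name for the class-label column when the dataset has
#'   true labels; `NULL` omits labels.
#' @export
write_dataset <- function(ds, path, label_column = "class") {
  stopifnot(inherits(ds, "acl_dataset"))
  # %.17g keeps enough digits that read_dataset() recovers the doubles exactly
  df <- as.data.frame(apply(ds$points, 2L, function(col) sprintf("%.17g", col)))
  names(df) <- ds$feature_names
  if (!is.null(ds$true_labels) && !is.null(label_column)) {
    df[[label_column]] <- ds$true_labels
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
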