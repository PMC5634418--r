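#' Labeled two-group expression dataset
#'
#' The universal container of the package: a numeric feature-by-sample matrix
#' (microarray convention: one row per probe/gene, one column per sample)
#' together with a binary class label per sample and a declared positive class.
#' Values are assumed to be on a continuous (typically log-intensity) scale;
#' no transformation is applied or enforced.
#'
#' @param values numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids); no missing values.
#' @param labels character vector of per-sample class labels, either named by
#'   sample id or in column order; exactly two distinct values, each with at
#'   least two samples.
#' @param positive_class one of the two label values. When `NULL`, the
#'   minority class is chosen (ties broken towards the lexicographically
#'   smaller label) and the choice is reported via `message()`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `labels` (named character), `positive_class`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' ds
#' @export
expression_dataset <- function(values, labels, positive_class = NULL) {
  fail_if(!is.matrix(values) || !is.numeric(values),
          "'values' must be a numeric matrix")
  fail_if(is.null(rownames(values)) || is.null(colnames(values)),
          "'values' must carry feature ids as rownames and sample ids as colnames")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  fail_if(length(dup_f) > 0, "duplicated feature id(s): %s",
          paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  fail_if(length(dup_s) > 0, "duplicated sample id(s): %s",
          paste(unique(dup_s), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  nm <- names(labels)
  labels <- stats::setNames(as.character(unlist(labels)), nm)
  if (is.null(names(labels))) {
    fail_if(length(labels) != ncol(values),
            "unnamed 'labels' must have one entry per sample (%d), got %d",
            ncol(values), length(labels))
    names(labels) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(labels))
  fail_if(length(missing) > 0, "no label for sample(s): %s",
          paste(missing, collapse = ", "))
  labels <- labels[colnames(values)]
  classes <- sort(unique(labels))
  fail_if(length(classes) != 2L,
          if (length(classes) > 2L) "more than two classes: %s" else
            "exactly two classes required, got: %s",
          paste(classes, collapse = ", "))
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  fail_if(length(small) > 0, "class '%s' has fewer than 2 samples", small[1L])
  if (is.null(positive_class)) {
    # minority class; tie -> lexicographically smaller label
    positive_class <- names(counts)[order(counts, names(counts))][1L]
    message(sprintf("positive class not given; using minority class '%s' (%d of %d samples)",
                    positive_class, counts[[positive_class]], sum(counts)))
  }
  fail_if(!positive_class %in% classes,
          "positive_class '%s' is not one of the labels (%s)",
          positive_class, paste(classes, collapse = ", "))
  structure(
    list(values = values, labels = labels, positive_class = positive_class),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  counts <- table(x$labels)
  cat(sprintf("ExpressionDataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  classes: %s | positive: '%s'\n",
              paste(sprintf("'%s' (n=%d)", names(counts), counts), collapse = ", "),
              x$positive_class))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Feature and sample identifiers of a dataset
#' @param ds an [ExpressionDataset][expression_dataset].
#' @return character vector of ids.
#' @export
feature_ids <- function(ds) rownames(ds$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' Subset a dataset by feature and/or sample ids
#'
#' Both indices accept ids or positions; class labels and the positive class
#' travel with the subset. Subsetting samples may not drop a class below two
#' members unless `check = FALSE` (used internally for prediction inputs).
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param features,samples ids (character) or indices; `NULL` keeps all.
#' @param check validate the two-class invariant on the result.
#' @return an `ExpressionDataset` (unchecked objects keep the class but may
#'   violate the constructor invariants, e.g. an empty sample set).
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL, check = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  v <- ds$values
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, rownames(v))
      fail_if(length(missing) > 0, "unknown feature id(s): %s",
              paste(missing, collapse = ", "))
    }
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, colnames(v))
      fail_if(length(missing) > 0, "unknown sample id(s): %s",
              paste(missing, collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  labels <- ds$labels[colnames(v)]
  if (check) {
    expression_dataset(v, labels, ds$positive_class)
  } else {
    structure(list(values = v, labels = labels,
                   positive_class = ds$positive_class),
              class = "ExpressionDataset")
  }
}

# ---------------------------------------------------------------------------
# Delimited IO

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix and sample labels from delimited files
#'
#' The matrix file has feature ids in the first column and sample ids in the
#' header row (set `transpose = TRUE` for samples-in-rows sources). The labels
#' file maps sample id to class label in its first two columns. The delimiter
#' is auto-detected from the header (tab preferred over comma) unless given.
#' Values are loaded as-is; no normalization or imputation is performed —
#' missing or non-numeric cells are errors naming the offending cell.
#'
#' @param matrix_path path to the delimited expression matrix.
#' @param labels_path path to the delimited sample-id/label table.
#' @param positive_class optional positive label; default: minority class.
#' @param transpose matrix file is samples x features.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @return an [ExpressionDataset][expression_dataset].
#' @export
read_dataset <- function(matrix_path, labels_path, positive_class = NULL,
                         transpose = FALSE, sep = NULL) {
  fail_if(!file.exists(matrix_path), "matrix file not found: %s", matrix_path)
  fail_if(!file.exists(labels_path), "labels file not found: %s", labels_path)
  if (is.null(sep)) sep <- detect_sep(matrix_path)
  dt <- data.table::fread(matrix_path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1))
  fail_if(ncol(dt) < 2L, "matrix file '%s' has no sample columns", matrix_path)
  ids <- dt[[1L]]
  num <- dt[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      suppressWarnings(conv <- as.numeric(num[[j]]))
      bad <- which(is.na(conv) & !is.na(num[[j]]))
      fail_if(length(bad) > 0,
              "non-numeric cell at row '%s', column '%s'",
              ids[bad[1L]], colnames(num)[j])
      num[[j]] <- conv
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  if (transpose) values <- t(values)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }

  lab <- data.table::fread(labels_path, sep = detect_sep(labels_path),
                           header = "auto", data.table = FALSE,
                           colClasses = "character")
  fail_if(ncol(lab) < 2L, "labels file '%s' needs two columns (sample id, label)",
          labels_path)
  labels <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  # header-less files auto-read with the first pair as names: recover it
  if (!is.null(colnames(lab)) && colnames(lab)[1L] %in% colnames(values) &&
      !colnames(lab)[1L] %in% names(labels)) {
    labels <- c(stats::setNames(colnames(lab)[2L], colnames(lab)[1L]), labels)
  }
  expression_dataset(values, labels, positive_class)
}

#' Write a dataset as a delimited matrix plus a label table
#'
#' Inverse of [read_dataset()]: `read_dataset(matrix_path, labels_path)`
#' recovers the dataset (values at full printed precision).
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param matrix_path,labels_path output paths.
#' @param sep field delimiter (default tab).
#' @return invisibly, `c(matrix_path, labels_path)`.
#' @export
write_dataset <- function(ds, matrix_path, labels_path, sep = "\t") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  df <- data.frame(feature_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, matrix_path, sep = sep)
  data.table::fwrite(
    data.frame(sample_id = names(ds$labels), label = unname(ds$labels)),
    labels_path, sep = sep
  )
  invisible(c(matrix_path, labels_path))
}
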