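#' Specification of a seeded random train/test split
#'
#' @param train_fraction fraction of samples assigned to training, in (0, 1).
#'   Model screens conventionally use 0.7, triplet screens 0.8.
#' @param stratified allocate the train set per class (default). Stratification
#'   guarantees both classes appear in both parts, which keeps test accuracy
#'   well-defined on small datasets; set `FALSE` for a plain random split.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return an object of class `SplitSpec`.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE, seed = 1L) {
  fail_if(!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "SplitSpec")
}

# Largest-remainder apportionment of the total train size across classes,
# clamped so each class keeps at least one sample on each side.
stratified_counts <- function(class_sizes, train_fraction) {
  n_train <- round(train_fraction * sum(class_sizes))
  base <- floor(train_fraction * class_sizes)
  rem <- train_fraction * class_sizes - base
  short <- n_train - sum(base)
  if (short > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    base[give] <- base[give] + 1L
  }
  pmin(pmax(base, 1L), class_sizes - 1L)
}

#' Split a dataset into train and test parts
#'
#' The train set size is `round(train_fraction * n)`; under stratification the
#' per-class sizes are apportioned by largest remainder and clamped so both
#' classes appear on both sides.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param spec a [split_spec()].
#' @return list with elements `train` and `test`, both `ExpressionDataset`s
#'   partitioning the samples.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(spec, "SplitSpec"))
  ids <- sample_ids(ds)
  n <- length(ids)
  train_ids <- with_seed(spec$seed, {
    if (spec$stratified) {
      sizes <- table(ds$labels)
      fail_if(any(sizes < 2L),
              "class '%s' has < 2 samples; cannot stratify",
              names(sizes)[which(sizes < 2L)[1L]])
      counts <- stratified_counts(as.integer(sizes), spec$train_fraction)
      unlist(lapply(seq_along(sizes), function(k) {
        members <- ids[ds$labels == names(sizes)[k]]
        sample(members, counts[k])
      }), use.names = FALSE)
    } else {
      sample(ids, round(spec$train_fraction * n))
    }
  })
  test_ids <- setdiff(ids, train_ids)
  fail_if(length(test_ids) == 0L, "split leaves an empty test set")
  list(train = subset_dataset(ds, samples = ids[ids %in% train_ids],
                              check = FALSE),
       test = subset_dataset(ds, samples = ids[ids %in% test_ids],
                             check = FALSE))
}

#' Confusion counts and derived metrics for binary predictions
#'
#' Implements the standard definitions with a declared positive class:
#' accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`.
#' Undefined ratios (zero denominator) are reported as `NA`, never silently
#' scored as 0 or 1; cutoff censuses exclude them with a logged count.
#' A balanced accuracy (mean of recall and specificity) is included as a
#' convenience.
#'
#' @param truth,predicted character vectors of equal length.
#' @param positive_class the label counted as positive.
#' @return an object of class `PerformanceMetrics`: list with `TP`, `FP`,
#'   `FN`, `TN`, `accuracy`, `precision`, `recall`, `balanced_accuracy`.
#' @examples
#' confusion_metrics(c("a","a","b","b"), c("a","b","b","b"), "a")
#' @export
confusion_metrics <- function(truth, predicted, positive_class) {
  fail_if(length(truth) != length(predicted),
          "truth (%d) and predicted (%d) differ in length",
          length(truth), length(predicted))
  fail_if(length(truth) == 0L, "empty test set")
  tp <- sum(truth == positive_class & predicted == positive_class)
  fp <- sum(truth != positive_class & predicted == positive_class)
  fn <- sum(truth == positive_class & predicted != positive_class)
  tn <- sum(truth != positive_class & predicted != positive_class)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(
    list(TP = tp, FP = fp, FN = fn, TN = tn,
         accuracy = (tp + tn) / length(truth),
         precision = precision, recall = recall,
         balanced_accuracy = mean(c(recall, specificity))),
    class = "PerformanceMetrics"
  )
}

#' @export
print.PerformanceMetrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("PerformanceMetrics: TP=%d FP=%d FN=%d TN=%d | acc=%s prec=%s rec=%s\n",
              x$TP, x$FP, x$FN, x$TN,
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall)))
  invisible(x)
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' Works for any model honoring the `predict(model, ds)` label contract
#' (e.g. [fit_elm()] models or [baseline classifiers][elm_adapter]).
#'
#' @param model the fitted model.
#' @param test non-empty test [ExpressionDataset][expression_dataset].
#' @return a [confusion_metrics()] object, scored against the test set's
#'   labels with its `positive_class`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "ExpressionDataset"))
  fail_if(ncol(test$values) == 0L, "empty test set")
  predicted <- predict(model, test)
  confusion_metrics(unname(test$labels), unname(predicted),
                    test$positive_class)
}
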