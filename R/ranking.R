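#' Rank features by a per-feature two-sample t-test
#'
#' Every feature is tested for a mean difference between the two classes and
#' the features are ordered by ascending p-value (rank 1 = smallest p). The
#' default is the Welch unequal-variance test, two-sided; `var_equal = TRUE`
#' switches to the pooled-variance Student test. Ties in p-value are broken
#' by input feature order, so ranks are deterministic. No multiple-testing
#' correction is applied: the p-values are used for ranking only.
#'
#' A feature with zero variance in both classes has no defined t statistic;
#' it is assigned `t = 0, p = 1` (reported via `message()`), ranking last.
#'
#' @param ds an [ExpressionDataset][expression_dataset]; each class must have
#'   at least two samples.
#' @param var_equal use the pooled-variance (Student) test.
#' @return a `RankedFeatures` data frame with columns `feature_id`, `t`, `p`,
#'   `rank`, ordered by rank; attribute `var_equal` records the variant.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_features = 100, seed = 3))
#' head(rank_features(ds))
#' @export
rank_features <- function(ds, var_equal = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pos <- ds$labels == ds$positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  fail_if(n1 < 2L || n2 < 2L, "each class needs >= 2 samples for the t-test")
  x1 <- ds$values[, pos, drop = FALSE]
  x2 <- ds$values[, !pos, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)

  degenerate <- se == 0
  if (any(degenerate)) {
    message(sprintf("%d feature(s) with zero variance in both classes; p set to 1",
                    sum(degenerate)))
    tt[degenerate] <- 0
    p[degenerate] <- 1
  }

  ord <- order(p, seq_along(p))          # ties broken by input feature order
  rf <- data.frame(
    feature_id = rownames(ds$values)[ord],
    t = unname(tt[ord]),
    p = unname(p[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  attr(rf, "var_equal") <- var_equal
  class(rf) <- c("RankedFeatures", "data.frame")
  rf
}

#' Keep the top-k ranked features
#'
#' @param rf a [rank_features()] result.
#' @param k positive integer, at most the number of features.
#' @return the first `k` rows (ranks `1..k` preserved), still of class
#'   `RankedFeatures`.
#' @export
top_k <- function(rf, k) {
  stopifnot(inherits(rf, "RankedFeatures"))
  fail_if(!is_count(k), "k must be a positive integer")
  fail_if(k > nrow(rf), "k (%d) exceeds the number of features (%d)",
          k, nrow(rf))
  out <- rf[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "var_equal") <- attr(rf, "var_equal")
  class(out) <- c("RankedFeatures", "data.frame")
  out
}

#' Export a feature ranking as TSV
#' @param rf a [rank_features()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ranked_features <- function(rf, path) {
  stopifnot(inherits(rf, "RankedFeatures"))
  data.table::fwrite(as.data.frame(rf), path, sep = "\t")
  invisible(path)
}
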