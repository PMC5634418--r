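#' Enumerate every unordered feature triplet of the top-k ranking
#'
#' Exhaustive, deterministic enumeration in lexicographic rank order:
#' `C(k, 3)` subsets, each exactly once, as rank triples `x < y < z`.
#'
#' @param rf a [rank_features()] result (use [top_k()] first, or pass `k`).
#' @param k number of top-ranked features to draw triplets from
#'   (default: all of `rf`); must be at least 3.
#' @return integer matrix with columns `x`, `y`, `z` (ranks, `x < y < z`) and
#'   one row per triplet.
#' @examples
#' nrow(enumerate_triplets(k = 50))   # 19600
#' @export
enumerate_triplets <- function(rf = NULL, k = if (is.null(rf)) 3L else nrow(rf)) {
  if (!is.null(rf)) {
    stopifnot(inherits(rf, "RankedFeatures"))
    fail_if(k > nrow(rf), "k (%d) exceeds the ranking size (%d)", k, nrow(rf))
  }
  fail_if(!is_count(k) || k < 3L, "need at least 3 features to form triplets")
  combos <- t(utils::combn(as.integer(k), 3L))
  colnames(combos) <- c("x", "y", "z")
  combos
}

#' Exhaustively screen all feature triplets of the top-k ranking
#'
#' Draws one seeded stratified 80/20 train/test split, shared by every
#' triplet so their metrics are directly comparable (set
#' `shared_split = FALSE` to draw a fresh split per triplet, seeded by the
#' triplet index, for sensitivity analysis). For each of the `C(k, 3)`
#' subsets an ELM is fitted on the 3-feature restriction of the training
#' samples and evaluated on the test samples for accuracy, precision and
#' recall. The census per metric counts triplets with `metric >= cutoff`
#' (non-strict, unlike the model screen); triplets whose precision or recall
#' is undefined are excluded from that metric's census, with the count of
#' exclusions logged in the report.
#'
#' The per-triplet fast path (hoisting the shared split, standardization and
#' the hidden-layer draw out of the loop) is exactly equivalent to calling
#' [fit_elm()]/[evaluate_model()] on each 3-feature restriction.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param rf its [rank_features()] ranking (computed if `NULL`).
#' @param k screen the triplets of the `k` smallest-p features (default 50).
#' @param cutoffs named numeric: cutoff per metric, any subset of
#'   `accuracy`, `precision`, `recall` (default 0.8 each).
#' @param elm_config an [elm_config()]; 150 hidden units comfortably
#'   over-parameterizes a 3-feature input.
#' @param split_spec a [split_spec()] (default 80/20 stratified).
#' @param shared_split share one split across triplets (default).
#' @return an object of class `TripletScreenReport`: `records` (data frame,
#'   one row per triplet: feature ids `a,b,c`, ranks `x <= y <= z`,
#'   `mean_rank`, confusion counts and metrics), `census` (count per metric),
#'   `n_undefined` per metric, `cutoffs`, and the split/config provenance.
#' @export
screen_triplets <- function(ds, rf = NULL, k = 50L,
                            cutoffs = c(accuracy = 0.8, precision = 0.8,
                                        recall = 0.8),
                            elm_config = multisol::elm_config(n_hidden = 150L),
                            split_spec = multisol::split_spec(0.8),
                            shared_split = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(elm_config, "ELMConfig"),
            inherits(split_spec, "SplitSpec"))
  if (is.null(rf)) rf <- rank_features(ds)
  fail_if(k > nrow(rf), "k (%d) exceeds the ranking size (%d)", k, nrow(rf))
  cutoffs <- unlist(cutoffs)
  rf_k <- top_k(rf, k)
  fail_if(!all(rf_k$feature_id %in% rownames(ds$values)),
          "ranking names features absent from the dataset")
  fail_if(length(cutoffs) == 0 || is.null(names(cutoffs)) ||
            !all(names(cutoffs) %in% c("accuracy", "precision", "recall")),
          "cutoffs must be named among accuracy/precision/recall")

  combos <- enumerate_triplets(rf_k)
  n_t <- nrow(combos)
  ds_k <- subset_dataset(ds, features = rf_k$feature_id)
  parts <- split_dataset(ds_k, split_spec)

  act <- activation_fun(elm_config$activation)
  nh <- elm_config$n_hidden
  # shared hidden layer: every 3-feature fit under this config draws the
  # same n_hidden x 3 weights, so draw them once
  wb <- with_seed(elm_config$seed, {
    list(W = matrix(stats::runif(nh * 3L, -elm_config$weight_scale,
                                 elm_config$weight_scale), nh, 3L),
         b = stats::runif(nh, -elm_config$weight_scale,
                          elm_config$weight_scale))
  })

  fit_one <- function(tr, te, idx) {
    ctr <- rowMeans(tr)
    scl <- apply(tr, 1L, stats::sd)
    scl[scl == 0] <- 1
    Htr <- act(wb$W %*% ((tr - ctr) / scl) + wb$b)
    beta <- min_norm_lsq(cbind(1, t(Htr)), ytr)
    Hte <- act(wb$W %*% ((te - ctr) / scl) + wb$b)
    score <- drop(crossprod(Hte, beta[-1L])) + beta[1L]
    ifelse(score >= 0.5, pos_label, neg_label)
  }

  pos_label <- ds$positive_class
  neg_label <- setdiff(sort(unique(ds$labels)), pos_label)
  tr_all <- parts$train$values
  te_all <- parts$test$values
  ytr <- as.numeric(parts$train$labels == pos_label)
  yte <- unname(parts$test$labels)

  out <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    ranks <- combos[i, ]
    fids <- rf_k$feature_id[ranks]
    if (shared_split) {
      tr <- tr_all[fids, , drop = FALSE]
      te <- te_all[fids, , drop = FALSE]
      truth <- yte
    } else {
      sp <- split_spec
      sp$seed <- split_spec$seed + i
      p_i <- split_dataset(subset_dataset(ds_k, features = fids), sp)
      tr <- p_i$train$values; te <- p_i$test$values
      ytr <- as.numeric(p_i$train$labels == pos_label)
      truth <- unname(p_i$test$labels)
    }
    pred <- tryCatch(fit_one(tr, te, i), error = function(e) stop(sprintf(
      "triplet %d (%s): %s", i, paste(fids, collapse = ","),
      conditionMessage(e)), call. = FALSE))
    met <- confusion_metrics(truth, pred, pos_label)
    out[[i]] <- c(met$TP, met$FP, met$FN, met$TN,
                  met$accuracy, met$precision, met$recall)
  }
  res <- do.call(rbind, out)
  records <- data.frame(
    a = rf_k$feature_id[combos[, 1L]],
    b = rf_k$feature_id[combos[, 2L]],
    c = rf_k$feature_id[combos[, 3L]],
    x = combos[, 1L], y = combos[, 2L], z = combos[, 3L],
    mean_rank = rowMeans(combos),
    TP = as.integer(res[, 1L]), FP = as.integer(res[, 2L]),
    FN = as.integer(res[, 3L]), TN = as.integer(res[, 4L]),
    accuracy = res[, 5L], precision = res[, 6L], recall = res[, 7L],
    stringsAsFactors = FALSE
  )

  census <- integer(0); n_undef <- integer(0)
  for (mname in names(cutoffs)) {
    v <- records[[mname]]
    n_undef[mname] <- sum(is.na(v))
    census[mname] <- sum(v >= cutoffs[[mname]], na.rm = TRUE)
  }
  if (any(n_undef > 0)) {
    message(sprintf("undefined metrics excluded from census: %s",
                    paste(sprintf("%s=%d", names(n_undef)[n_undef > 0],
                                  n_undef[n_undef > 0]), collapse = ", ")))
  }
  structure(
    list(records = records, census = census, n_undefined = n_undef,
         cutoffs = cutoffs, k = as.integer(k),
         shared_split = shared_split,
         elm_config = elm_config, split_spec = split_spec,
         feature_ranking = rf_k),
    class = "TripletScreenReport"
  )
}

#' @export
print.TripletScreenReport <- function(x, ...) {
  cat(sprintf("TripletScreenReport: %d triplets of top-%d features (shared split: %s)\n",
              nrow(x$records), x$k, x$shared_split))
  for (mname in names(x$census)) {
    cat(sprintf("  %s >= %.3f: %d triplets\n", mname, x$cutoffs[[mname]],
                x$census[[mname]]))
  }
  invisible(x)
}

#' The ten best triplets by a metric, with their rank dispersion
#'
#' Sorts the records by the metric (descending); ties are broken towards the
#' smaller `mean_rank`, then lexicographically by ranks `(x, y, z)`, so
#' repeated calls agree. Records with an undefined metric are dropped first;
#' if fewer than 10 defined records remain, all of them are returned with a
#' warning and attribute `short = TRUE`.
#'
#' @param report a [screen_triplets()] report.
#' @param metric `"accuracy"`, `"precision"` or `"recall"`.
#' @return the top (up to) 10 record rows; attributes `min_mean_rank` /
#'   `max_mean_rank` give the spread of their mean ranks.
#' @export
best10 <- function(report, metric = c("accuracy", "precision", "recall")) {
  stopifnot(inherits(report, "TripletScreenReport"))
  metric <- match.arg(metric)
  rec <- report$records[!is.na(report$records[[metric]]), , drop = FALSE]
  fail_if(nrow(rec) == 0L, "no record has a defined %s", metric)
  ord <- order(-rec[[metric]], rec$mean_rank, rec$x, rec$y, rec$z)
  n <- min(10L, nrow(rec))
  if (nrow(rec) < 10L) {
    warning(sprintf("only %d records with defined %s (10 requested)",
                    nrow(rec), metric))
  }
  out <- rec[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_mean_rank") <- min(out$mean_rank)
  attr(out, "max_mean_rank") <- max(out$mean_rank)
  attr(out, "short") <- nrow(rec) < 10L
  out
}

#' Held-out performance of a single feature (or any small feature subset)
#'
#' Applies the triplet-screen protocol to the 1-column restriction of the
#' dataset: same seeded split, same ELM settings. Supports complementarity
#' analysis — comparing a triplet's accuracy against what each member
#' achieves alone.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param feature_id a feature of `ds`.
#' @param elm_config an [elm_config()].
#' @param split_spec a [split_spec()] (default 80/20, as in the triplet
#'   screen).
#' @return a [confusion_metrics()] object.
#' @export
single_feature_accuracy <- function(ds, feature_id,
                                    elm_config = multisol::elm_config(n_hidden = 150L),
                                    split_spec = multisol::split_spec(0.8)) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  fail_if(length(feature_id) != 1L || !feature_id %in% rownames(ds$values),
          "unknown feature id: %s", paste(feature_id, collapse = ","))
  ds_1 <- subset_dataset(ds, features = feature_id)
  parts <- split_dataset(ds_1, split_spec)
  evaluate_model(fit_elm(parts$train, elm_config), parts$test)
}
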