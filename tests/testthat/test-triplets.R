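trip_ds <- function(seed = 90L) {
  generate_dataset(synthetic_spec(
    n_features = 100L, n_samples_per_class = c(15L, 15L),
    n_informative = 9L, effect_size = 2.5,
    n_redundant_blocks = 3L, block_size = 3L,
    within_block_correlation = 0.8, seed = seed))
}

test_that("enumeration is exhaustive, ordered and matches C(k,3)", {
  expect_identical(nrow(enumerate_triplets(k = 3L)), 1L)
  expect_identical(nrow(enumerate_triplets(k = 10L)), 120L)
  expect_identical(nrow(enumerate_triplets(k = 50L)), 19600L)

  # independent brute-force oracle at k = 6
  oracle <- NULL
  for (x in 1:4) for (y in (x + 1):5) for (z in (y + 1):6) {
    oracle <- rbind(oracle, c(x, y, z))
  }
  got <- enumerate_triplets(k = 6L)
  expect_identical(unname(got), unname(oracle))
  expect_true(all(got[, "x"] < got[, "y"] & got[, "y"] < got[, "z"]))

  expect_error(enumerate_triplets(k = 2L), "at least 3")
  rf <- rank_features(trip_ds())
  expect_error(enumerate_triplets(top_k(rf, 5L), k = 9L), "exceeds")
})

test_that("screen_triplets covers C(k,3) records with valid rank triples", {
  ds <- trip_ds()
  rf <- rank_features(ds)
  rep <- screen_triplets(ds, rf, k = 10L, cutoffs = c(accuracy = 0.8),
                         elm_config = elm_config(n_hidden = 60L, seed = 5L),
                         split_spec = split_spec(0.8, seed = 5L))
  rec <- rep$records
  expect_identical(nrow(rec), 120L)
  expect_true(all(rec$x < rec$y & rec$y < rec$z))
  expect_true(all(rec$x >= 1 & rec$z <= 10))
  expect_equal(rec$mean_rank, (rec$x + rec$y + rec$z) / 3)
  # rank -> feature-id mapping is bijective against the ranking
  expect_identical(rec$a, rf$feature_id[rec$x])
  expect_identical(rec$c, rf$feature_id[rec$z])
  # each unordered triple appears exactly once
  expect_identical(anyDuplicated(rec[, c("x", "y", "z")]), 0L)
})

test_that("the fast path equals the public fit/evaluate route per triplet", {
  ds <- trip_ds(seed = 91L)
  rf <- rank_features(ds)
  ec <- elm_config(n_hidden = 40L, seed = 13L)
  sp <- split_spec(0.8, seed = 21L)
  rep <- screen_triplets(ds, rf, k = 8L, cutoffs = c(accuracy = 0.8),
                         elm_config = ec, split_spec = sp)
  rf8 <- top_k(rf, 8L)
  parts <- split_dataset(subset_dataset(ds, features = rf8$feature_id), sp)
  for (i in c(1L, 20L, 56L)) {
    row <- rep$records[i, ]
    fids <- c(row$a, row$b, row$c)
    model <- fit_elm(subset_dataset(parts$train, features = fids), ec)
    met <- evaluate_model(model, subset_dataset(parts$test, features = fids,
                                                check = FALSE))
    expect_equal(row$accuracy, met$accuracy)
    expect_equal(row$TP, met$TP)
    expect_identical(is.na(row$precision), is.na(met$precision))
    if (!is.na(met$precision)) expect_equal(row$precision, met$precision)
  }
})

test_that("censuses use >= cutoff, are monotone, and vanish above 1", {
  ds <- trip_ds(seed = 92L)
  rf <- rank_features(ds)
  base <- screen_triplets(ds, rf, k = 10L,
                          cutoffs = c(accuracy = 0.8, precision = 0.8,
                                      recall = 0.8),
                          elm_config = elm_config(n_hidden = 60L, seed = 2L),
                          split_spec = split_spec(0.8, seed = 2L))
  for (mname in c("accuracy", "precision", "recall")) {
    v <- base$records[[mname]]
    expect_identical(base$census[[mname]],
                     sum(v >= 0.8, na.rm = TRUE))
  }
  counts <- vapply(c(0.5, 0.8, 0.9, 1.0, 1.01), function(cut) {
    screen_triplets(ds, rf, k = 6L, cutoffs = c(accuracy = cut),
                    elm_config = elm_config(n_hidden = 60L, seed = 2L),
                    split_spec = split_spec(0.8, seed = 2L))$census[["accuracy"]]
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[5], 0L)
})

test_that("best10 sorts by metric with deterministic tie-breaks (toy oracle)", {
  # hand-built 12-record report
  rec <- data.frame(
    a = paste0("fa", 1:12), b = paste0("fb", 1:12), c = paste0("fc", 1:12),
    x = c(1, 1, 2, 1, 3, 2, 4, 1, 5, 2, 6, 3),
    y = c(2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8),
    z = c(3, 4, 5, 6, 5, 6, 6, 7, 7, 8, 8, 9),
    TP = 3L, FP = 1L, FN = 1L, TN = 3L,
    accuracy = c(1, 1, 1, 0.9, 0.9, 0.9, 0.8, 0.8, 0.7, 0.7, 0.6, 0.5),
    precision = c(rep(1, 6), rep(NA, 6)),
    recall = 0.5,
    stringsAsFactors = FALSE
  )
  rec$mean_rank <- (rec$x + rec$y + rec$z) / 3
  rep <- structure(list(records = rec,
                        census = c(accuracy = 8L),
                        n_undefined = c(accuracy = 0L),
                        cutoffs = c(accuracy = 0.8), k = 12L,
                        shared_split = TRUE,
                        elm_config = elm_config(), split_spec = split_spec()),
                   class = "TripletScreenReport")
  b <- best10(rep, "accuracy")
  expect_identical(nrow(b), 10L)
  # brute-force oracle: order by (-metric, mean_rank, x, y, z)
  ord <- with(rec, order(-accuracy, mean_rank, x, y, z))[1:10]
  expect_equal(b$accuracy, rec$accuracy[ord])
  expect_equal(b$mean_rank, rec$mean_rank[ord])
  expect_equal(attr(b, "min_mean_rank"), min(rec$mean_rank[ord]))
  expect_equal(attr(b, "max_mean_rank"), max(rec$mean_rank[ord]))
  expect_gte(attr(b, "min_mean_rank"), 1.0)
  # repeated calls resolve ties identically
  expect_identical(best10(rep, "accuracy"), b)
  # fewer than 10 defined records: flagged, all returned
  expect_warning(bp <- best10(rep, "precision"), "only 6")
  expect_identical(nrow(bp), 6L)
  expect_true(attr(bp, "short"))
})

test_that("single_feature_accuracy follows the screen protocol and validates ids", {
  ds <- trip_ds(seed = 93L)
  met <- single_feature_accuracy(ds, "f0001",
                                 elm_config(n_hidden = 60L, seed = 3L),
                                 split_spec(0.8, seed = 3L))
  expect_s3_class(met, "PerformanceMetrics")
  # strongly informative planted feature: clearly above chance
  expect_gt(met$accuracy, 0.6)
  expect_error(single_feature_accuracy(ds, "nope"), "unknown feature")
  # a triplet may not contain a duplicated feature
  expect_error(expression_dataset(
    ds$values[c("f0001", "f0001", "f0002"), ], ds$labels, "case"),
    "duplicated feature")
})

test_that("per-triplet splits (shared_split = FALSE) remain deterministic", {
  ds <- trip_ds(seed = 94L)
  rf <- rank_features(ds)
  r1 <- screen_triplets(ds, rf, k = 5L, cutoffs = c(accuracy = 0.8),
                        elm_config = elm_config(n_hidden = 40L, seed = 1L),
                        split_spec = split_spec(0.8, seed = 1L),
                        shared_split = FALSE)
  r2 <- screen_triplets(ds, rf, k = 5L, cutoffs = c(accuracy = 0.8),
                        elm_config = elm_config(n_hidden = 40L, seed = 1L),
                        split_spec = split_spec(0.8, seed = 1L),
                        shared_split = FALSE)
  expect_identical(r1$records, r2$records)
})
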