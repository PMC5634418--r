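#' Configuration of a repeated-fit model screen
#'
#' A screen fits `n_runs` classifiers on a fixed feature set and counts the
#' runs whose held-out accuracy is strictly above `cutoff` (the census).
#' The two modes mirror the two conventional input regimes: the 20 features
#' with the smallest t-test p-values (`Top20Features`, default 150 hidden
#' units) or every feature (`AllFeatures`, default 290 hidden units).
#'
#' Two randomization policies are supported. `"fixed"` (the ELM default)
#' shares one train/test split across all runs, so runs differ only in their
#' randomly generated hidden-layer weights; `"per_run"` draws a fresh split
#' for every run, which is how deterministic baselines (SVM-like classifiers)
#' acquire run-to-run variability.
#'
#' @param mode `"Top20Features"` or `"AllFeatures"`.
#' @param n_runs number of independent fits (headline experiments use 10,000;
#'   desk-scale screens use hundreds).
#' @param cutoff census accuracy cutoff in (0, 1): 0.8 for difficult
#'   problems, 0.9 for easy ones. The census counts `accuracy > cutoff`
#'   (strict).
#' @param elm_config [elm_config()] template; its seed is ignored (run `i`
#'   uses `base_seed + i`). `NULL` selects the mode default `n_hidden`.
#' @param split_spec a [split_spec()] (default 70/30 stratified).
#' @param base_seed integer; run `i` uses seed `base_seed + i` for its model
#'   draw (and its split under `"per_run"`).
#' @param split_policy `"fixed"` or `"per_run"` (see above).
#' @return an object of class `ScreenConfig`.
#' @export
screen_config <- function(mode = c("Top20Features", "AllFeatures"),
                          n_runs = 500L, cutoff = 0.9,
                          elm_config = NULL,
                          split_spec = multisol::split_spec(0.7),
                          base_seed = 0L,
                          split_policy = c("fixed", "per_run")) {
  mode <- match.arg(mode)
  split_policy <- match.arg(split_policy)
  fail_if(!is_count(n_runs), "n_runs must be a positive integer")
  fail_if(!is_number(cutoff) || cutoff <= 0 || cutoff > 1,
          "cutoff must be in (0, 1]")
  if (is.null(elm_config)) {
    elm_config <- multisol::elm_config(
      n_hidden = if (mode == "Top20Features") 150L else 290L
    )
  }
  stopifnot(inherits(elm_config, "ELMConfig"), inherits(split_spec, "SplitSpec"))
  structure(
    list(mode = mode, n_runs = as.integer(n_runs), cutoff = cutoff,
         elm_config = elm_config, split_spec = split_spec,
         base_seed = as.integer(base_seed), split_policy = split_policy),
    class = "ScreenConfig"
  )
}

screen_feature_set <- function(ds, config) {
  if (config$mode == "Top20Features") {
    fail_if(nrow(ds$values) < 20L,
            "Top20Features mode needs >= 20 features, dataset has %d",
            nrow(ds$values))
    top_k(rank_features(ds), 20L)$feature_id
  } else {
    feature_ids(ds)
  }
}

# Shared engine behind run_screen() and baseline_screen(): the classifier is
# anything with fit(train, seed) -> model and predict(model, test) -> labels.
screen_engine <- function(ds, classifier, config) {
  features <- screen_feature_set(ds, config)
  ds_f <- subset_dataset(ds, features = features)
  fixed <- NULL
  if (config$split_policy == "fixed") {
    fixed <- split_dataset(ds_f, config$split_spec)
  }
  acc <- numeric(config$n_runs)
  split_seeds <- integer(config$n_runs)
  for (i in seq_len(config$n_runs)) {
    seed_i <- config$base_seed + i
    if (config$split_policy == "fixed") {
      parts <- fixed
      split_seeds[i] <- config$split_spec$seed
    } else {
      sp <- config$split_spec
      sp$seed <- seed_i
      parts <- split_dataset(ds_f, sp)
      split_seeds[i] <- seed_i
    }
    model <- tryCatch(classifier$fit(parts$train, seed_i),
                      error = function(e) stop(sprintf(
                        "run %d (seed %d): %s", i, seed_i, conditionMessage(e)),
                        call. = FALSE))
    acc[i] <- confusion_metrics(
      unname(parts$test$labels),
      unname(classifier$predict(model, parts$test)),
      parts$test$positive_class
    )$accuracy
  }
  above <- acc > config$cutoff               # strict: "larger than" the cutoff
  per_run_log <- data.frame(
    run = seq_len(config$n_runs),
    seed = config$base_seed + seq_len(config$n_runs),
    split_seed = split_seeds,
    accuracy = acc
  )
  best <- max(acc)
  structure(
    list(classifier = classifier$name,
         n_above_cutoff = sum(above),
         min_acc_above = if (any(above)) min(acc[above]) else NA_real_,
         max_acc_above = if (any(above)) max(acc[above]) else NA_real_,
         best_accuracy = best,
         best_seeds = per_run_log$seed[acc == best],
         per_run_log = per_run_log,
         feature_ids = features,
         config = config,
         dataset = ds_f),
    class = "ScreenReport"
  )
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat(sprintf("ScreenReport (%s, %s): %d runs, cutoff %.3f (strict)\n",
              x$classifier, x$config$mode, nrow(x$per_run_log), x$config$cutoff))
  cat(sprintf("  %d above cutoff; min/max above: %s / %s; best %.3f (%d tied)\n",
              x$n_above_cutoff,
              ifelse(is.na(x$min_acc_above), "-", sprintf("%.3f", x$min_acc_above)),
              ifelse(is.na(x$max_acc_above), "-", sprintf("%.3f", x$max_acc_above)),
              x$best_accuracy, length(x$best_seeds)))
  invisible(x)
}

#' Run a seeded multi-fit ELM screen and census the solutions
#'
#' Fits `config$n_runs` ELMs (run `i` with hidden-layer seed
#' `base_seed + i`) on the mode's feature set, records each run's held-out
#' accuracy, and counts the runs strictly above the cutoff. Deterministic
#' given `base_seed`.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param config a [screen_config()].
#' @return an object of class `ScreenReport`: census fields
#'   (`n_above_cutoff`, `min_acc_above`, `max_acc_above`), `best_accuracy`,
#'   `best_seeds` (runs tied at the best accuracy), the full `per_run_log`
#'   data frame (`run`, `seed`, `split_seed`, `accuracy`), the feature set,
#'   and enough state to refit any run (see [best_pair()]).
#' @seealso [best_pair()], [baseline_screen()]
#' @export
run_screen <- function(ds, config = screen_config()) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(config, "ScreenConfig"))
  screen_engine(ds, elm_adapter(config$elm_config), config)
}

#' Refit a screened run by its seed
#' @param report a [run_screen()] report.
#' @param seed one of the report's per-run seeds.
#' @return the refitted [ELMModel][fit_elm] of that run.
#' @export
refit_run <- function(report, seed) {
  stopifnot(inherits(report, "ScreenReport"))
  row <- report$per_run_log[report$per_run_log$seed == seed, , drop = FALSE]
  fail_if(nrow(row) == 0L, "seed %d is not in the per-run log", seed)
  sp <- report$config$split_spec
  sp$seed <- row$split_seed[1L]
  parts <- split_dataset(report$dataset, sp)
  cfg <- report$config$elm_config
  cfg$seed <- as.integer(seed)
  fit_elm(parts$train, cfg)
}

#' The two best models of a screen
#'
#' Picks the two runs with the highest accuracy; when more than two runs tie
#' at the best accuracy, two of them are chosen uniformly at random under
#' `tiebreak_seed`. The pair feeds [weight_difference()] for the
#' difference-matrix heatmap.
#'
#' @param report a [run_screen()] report with at least two runs.
#' @param tiebreak_seed integer seed for the random choice among ties.
#' @return list of two [ELMModel][fit_elm]s (attribute `seeds` gives their
#'   run seeds).
#' @export
best_pair <- function(report, tiebreak_seed = 0L) {
  stopifnot(inherits(report, "ScreenReport"))
  log <- report$per_run_log
  fail_if(nrow(log) < 2L, "best_pair needs at least 2 recorded runs")
  ord <- order(-log$accuracy, log$run)
  best_acc <- log$accuracy[ord[1L]]
  tied <- log$seed[log$accuracy == best_acc]
  seeds <- if (length(tied) >= 2L) {
    with_seed(tiebreak_seed, sample(tied, 2L))
  } else {
    log$seed[ord[1:2]]
  }
  models <- lapply(seeds, refit_run, report = report)
  attr(models, "seeds") <- seeds
  models
}

#' Run the screen machinery with a pluggable classifier
#'
#' Same census as [run_screen()] but for an arbitrary classifier honoring the
#' fit/predict contract (see [elm_adapter()]). Deterministic classifiers get
#' their run-to-run randomness from per-run splits, so the default config
#' here uses the `"per_run"` policy; a config passed explicitly is used
#' as-is. An ELM passed through this interface reproduces [run_screen()]
#' exactly under matched seeds and split policy.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param classifier a classifier adapter (list with `name`, `fit`,
#'   `predict`).
#' @param config a [screen_config()].
#' @return a `ScreenReport`.
#' @export
baseline_screen <- function(ds, classifier,
                            config = screen_config(split_policy = "per_run")) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(config, "ScreenConfig"))
  fail_if(!is.list(classifier) || !is.function(classifier$fit) ||
            !is.function(classifier$predict),
          "classifier must provide fit(train, seed) and predict(model, test)")
  screen_engine(ds, classifier, config)
}

# ---------------------------------------------------------------------------
# Classifier adapters (the contract: list(name, fit(train, seed) -> model,
# predict(model, test) -> labels)). Baselines wrap established
# implementations; none re-implements a learning algorithm.

#' Classifier adapters for the screen contract
#'
#' `elm_adapter()` wraps [fit_elm()] so the package's own classifier can run
#' through [baseline_screen()]; the run seed overrides the template's seed.
#' `logistic_adapter()` wraps `stats::glm` logistic regression (deterministic;
#' ridge-free, so intended for small feature sets). `majority_adapter()`
#' always predicts the training majority class — the chance-level control.
#'
#' @param config an [elm_config()] template for `elm_adapter`.
#' @return a list with elements `name`, `fit(train, seed)`, and
#'   `predict(model, test)`.
#' @export
elm_adapter <- function(config = elm_config()) {
  list(
    name = "ELM",
    fit = function(train, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      fit_elm(train, cfg)
    },
    predict = function(model, test) predict(model, test)
  )
}

#' @rdname elm_adapter
#' @export
logistic_adapter <- function() {
  list(
    name = "logistic",
    fit = function(train, seed) {
      df <- data.frame(t(train$values), check.names = FALSE)
      y <- as.numeric(train$labels == train$positive_class)
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, as.matrix(df)), y,
                       family = stats::binomial())
      )
      list(coef = fit$coefficients,
           features = rownames(train$values),
           positive = train$positive_class,
           negative = setdiff(sort(unique(train$labels)),
                              train$positive_class))
    },
    predict = function(model, test) {
      x <- cbind(1, t(test$values[model$features, , drop = FALSE]))
      coef <- model$coef
      coef[is.na(coef)] <- 0
      eta <- drop(x %*% coef)
      stats::setNames(ifelse(eta >= 0, model$positive, model$negative),
                      colnames(test$values))
    }
  )
}

#' @rdname elm_adapter
#' @export
majority_adapter <- function() {
  list(
    name = "majority",
    fit = function(train, seed) {
      counts <- table(train$labels)
      names(counts)[order(-counts, names(counts))][1L]
    },
    predict = function(model, test) {
      stats::setNames(rep(model, ncol(test$values)), colnames(test$values))
    }
  )
}
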