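# Report serialization: every number that appears in a rendered figure also
# lives in a machine-readable TSV, so plots are never the sole record.

#' Serialize a screen report as a key/value TSV
#'
#' One row per summary statistic (`key<TAB>value`); numeric values are
#' written at full precision so [read_report_table()] recovers them exactly.
#' An empty census writes count 0 with empty min/max fields.
#'
#' @param report a [run_screen()] `ScreenReport` or a [screen_triplets()]
#'   `TripletScreenReport`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_table <- function(report, path) UseMethod("write_report_table")

kv_write <- function(kv, path) {
  vals <- vapply(kv, function(v) {
    if (length(v) == 0 || is.na(v)) ""
    else if (is.numeric(v)) format(v, digits = 17)
    else as.character(v)
  }, character(1))
  data.table::fwrite(data.frame(key = names(kv), value = vals),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
write_report_table.ScreenReport <- function(report, path) {
  kv_write(list(
    report_type = "ScreenReport",
    classifier = report$classifier,
    mode = report$config$mode,
    n_runs = nrow(report$per_run_log),
    cutoff = report$config$cutoff,
    split_policy = report$config$split_policy,
    train_fraction = report$config$split_spec$train_fraction,
    n_hidden = report$config$elm_config$n_hidden,
    base_seed = report$config$base_seed,
    n_above_cutoff = report$n_above_cutoff,
    min_acc_above = report$min_acc_above,
    max_acc_above = report$max_acc_above,
    best_accuracy = report$best_accuracy
  ), path)
}

#' @export
write_report_table.TripletScreenReport <- function(report, path) {
  kv <- list(
    report_type = "TripletScreenReport",
    k = report$k,
    n_triplets = nrow(report$records),
    shared_split = report$shared_split,
    train_fraction = report$split_spec$train_fraction,
    split_seed = report$split_spec$seed,
    n_hidden = report$elm_config$n_hidden,
    elm_seed = report$elm_config$seed
  )
  for (mname in names(report$cutoffs)) {
    kv[[paste0("cutoff_", mname)]] <- report$cutoffs[[mname]]
    kv[[paste0("census_", mname)]] <- report$census[[mname]]
    kv[[paste0("n_undefined_", mname)]] <- report$n_undefined[[mname]]
    b10 <- suppressWarnings(best10(report, mname))
    kv[[paste0("best10_min_mean_rank_", mname)]] <- attr(b10, "min_mean_rank")
    kv[[paste0("best10_max_mean_rank_", mname)]] <- attr(b10, "max_mean_rank")
    kv[[paste0("best10_min_", mname)]] <- min(b10[[mname]])
    kv[[paste0("best10_max_", mname)]] <- max(b10[[mname]])
  }
  kv_write(kv, path)
}

#' Read back a key/value report TSV
#' @param path a file written by [write_report_table()].
#' @return named list; numeric-looking values are numeric, empty fields `NA`.
#' @export
read_report_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character",
                          na.strings = NULL)
  vals <- lapply(df$value, function(v) {
    if (identical(v, "") || is.na(v)) return(NA)
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, df$key)
}

#' Export the full per-run log / triplet records / difference matrix as TSV
#' @param report,diff the object to export.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_per_run_log <- function(report, path) {
  stopifnot(inherits(report, "ScreenReport"))
  data.table::fwrite(report$per_run_log, path, sep = "\t")
  invisible(path)
}

#' @rdname write_per_run_log
#' @export
write_triplet_records <- function(report, path) {
  stopifnot(inherits(report, "TripletScreenReport"))
  data.table::fwrite(report$records, path, sep = "\t")
  invisible(path)
}

#' @rdname write_per_run_log
#' @export
write_difference_matrix <- function(diff, path) {
  stopifnot(inherits(diff, "DifferenceMatrix"))
  df <- data.frame(hidden_unit = seq_len(nrow(diff$values)), diff$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run manifest

#' Build, write and read a run manifest
#'
#' The manifest captures everything needed to regenerate a pipeline's numeric
#' outputs exactly: the package version, all configuration (seeds included)
#' and digests of the input files.
#'
#' @param config the pipeline configuration list (see [full_pipeline()]).
#' @param inputs named character vector of input file paths (digested).
#' @param path JSON path.
#' @return `run_manifest()`: the manifest list; `write_manifest()`: invisibly
#'   `path`; `read_manifest()`: the manifest list.
#' @export
run_manifest <- function(config, inputs = character(0)) {
  digests <- if (length(inputs)) {
    vapply(inputs, function(p) as.character(tools::md5sum(p)), character(1))
  } else {
    character(0)
  }
  list(
    package = "multisol",
    version = as.character(utils::packageVersion("multisol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = as.list(digests)
  )
}

#' @rdname run_manifest
#' @export
write_manifest <- function(config, path, inputs = character(0)) {
  m <- if (is.list(config) && !is.null(config$package)) config
       else run_manifest(config, inputs)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---------------------------------------------------------------------------
# Pipeline orchestration

default_pipeline_config <- function(seed = 0L) {
  list(
    seed = as.integer(seed),
    positive_class = NULL,
    screen = list(mode = "Top20Features", n_runs = 500L, cutoff = 0.9,
                  n_hidden = 150L, train_fraction = 0.7,
                  split_policy = "fixed"),
    # cutoffs as a named list so JSON manifests keep the metric names
    triplets = list(k = 50L,
                    cutoffs = list(accuracy = 0.9, precision = 0.9,
                                   recall = 0.9),
                    n_hidden = 150L, train_fraction = 0.8),
    skip_plots = FALSE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full multiplicity analysis end to end
#'
#' Orchestrates the stages in their natural order: load (or accept) the
#' dataset, rank features by t-test, run the repeated-ELM model screen and
#' census, extract the best pair and its weight-difference matrix, run the
#' exhaustive triplet screen with a census per metric, and write every table
#' (plus optional plots) and a JSON manifest into `out_dir`. Rerunning with
#' the same manifest configuration reproduces every numeric output
#' byte-identically. Any stage failure aborts with the stage name.
#'
#' @param matrix_path,labels_path delimited inputs for [read_dataset()];
#'   alternatively pass a dataset via `ds`.
#' @param ds an [ExpressionDataset][expression_dataset] (overrides the
#'   paths).
#' @param out_dir output directory (created).
#' @param config nested configuration list; defaults from the single `seed`.
#'   See the manifest of any run for the full shape.
#' @param seed master seed used for every stage default.
#' @return invisibly, the output directory; side effects: `manifest.json`,
#'   `ranked_features.tsv`, `screen_report.tsv`, `per_run_log.tsv`,
#'   `difference_matrix.tsv`, `triplet_report.tsv`, `triplet_records.tsv`,
#'   and unless `skip_plots`, `difference_heatmap.png` +
#'   `scatter_<metric>.png` with coordinate sidecars.
#' @export
full_pipeline <- function(matrix_path = NULL, labels_path = NULL, ds = NULL,
                          out_dir, config = list(), seed = 0L) {
  cfg <- merge_config(default_pipeline_config(seed), config)
  # keep cutoffs a named list so the JSON manifest preserves metric names
  cfg$triplets$cutoffs <- as.list(unlist(cfg$triplets$cutoffs))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.null(ds)) {
    fail_if(is.null(matrix_path) || is.null(labels_path),
            "provide either 'ds' or both matrix_path and labels_path")
    inputs <- c(matrix = matrix_path, labels = labels_path)
    ds <- stage("load", read_dataset(matrix_path, labels_path,
                                     positive_class = cfg$positive_class))
  }
  write_manifest(run_manifest(cfg, inputs), file.path(out_dir, "manifest.json"))

  rf <- stage("rank", rank_features(ds))
  write_ranked_features(rf, file.path(out_dir, "ranked_features.tsv"))

  sc <- cfg$screen
  scfg <- stage("screen-config", screen_config(
    mode = sc$mode, n_runs = sc$n_runs, cutoff = sc$cutoff,
    elm_config = elm_config(n_hidden = sc$n_hidden),
    split_spec = split_spec(sc$train_fraction, seed = cfg$seed),
    base_seed = cfg$seed, split_policy = sc$split_policy
  ))
  screen <- stage("screen", run_screen(ds, scfg))
  write_report_table(screen, file.path(out_dir, "screen_report.tsv"))
  write_per_run_log(screen, file.path(out_dir, "per_run_log.tsv"))

  pair <- stage("best-pair", best_pair(screen, tiebreak_seed = cfg$seed))
  diff <- stage("difference", weight_difference(pair[[1L]], pair[[2L]]))
  write_difference_matrix(diff, file.path(out_dir, "difference_matrix.tsv"))

  tc <- cfg$triplets
  trip <- stage("triplets", screen_triplets(
    ds, rf, k = min(tc$k, nrow(rf)), cutoffs = tc$cutoffs,
    elm_config = elm_config(n_hidden = tc$n_hidden, seed = cfg$seed),
    split_spec = split_spec(tc$train_fraction, seed = cfg$seed)
  ))
  write_report_table(trip, file.path(out_dir, "triplet_report.tsv"))
  write_triplet_records(trip, file.path(out_dir, "triplet_records.tsv"))

  if (!isTRUE(cfg$skip_plots)) {
    stage("plots", {
      plot_difference_heatmap(diff, file.path(out_dir, "difference_heatmap.png"))
      for (mname in names(tc$cutoffs)) {
        plot_triplet_scatter(trip, mname,
                             file.path(out_dir, sprintf("scatter_%s.png", mname)))
      }
    })
  }
  invisible(out_dir)
}
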