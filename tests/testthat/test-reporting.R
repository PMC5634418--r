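pipe_ds <- function(seed = 70L) {
  generate_dataset(synthetic_spec(
    n_features = 60L, n_samples_per_class = c(12L, 12L),
    n_informative = 6L, effect_size = 2.5, seed = seed))
}

pipe_cfg <- list(
  screen = list(n_runs = 20L, n_hidden = 30L),
  triplets = list(k = 6L, n_hidden = 30L,
                  cutoffs = c(accuracy = 0.9, precision = 0.9, recall = 0.9))
)

test_that("screen report tables round-trip, including the empty census", {
  ds <- pipe_ds()
  cfg <- screen_config(n_runs = 10L, cutoff = 0.8,
                       elm_config = elm_config(n_hidden = 30L),
                       split_spec = split_spec(0.7, seed = 3L), base_seed = 3L)
  rep <- run_screen(ds, cfg)
  path <- tempfile(fileext = ".tsv")
  write_report_table(rep, path)
  back <- read_report_table(path)
  expect_identical(back$report_type, "ScreenReport")
  expect_equal(back$n_above_cutoff, rep$n_above_cutoff)
  expect_equal(back$min_acc_above, rep$min_acc_above)
  expect_equal(back$max_acc_above, rep$max_acc_above)
  expect_equal(back$cutoff, 0.8)
  expect_equal(back$n_runs, 10)

  # empty census: count 0, min/max empty -> NA on read-back
  empty <- run_screen(ds, screen_config(
    n_runs = 5L, cutoff = 1.0, elm_config = elm_config(n_hidden = 30L),
    split_spec = split_spec(0.7, seed = 3L), base_seed = 3L))
  p2 <- tempfile(fileext = ".tsv")
  write_report_table(empty, p2)
  b2 <- read_report_table(p2)
  expect_equal(b2$n_above_cutoff, 0)
  expect_true(is.na(b2$min_acc_above))
  raw <- readLines(p2)
  expect_true(any(grepl("^min_acc_above\t$", raw)))
})

test_that("triplet report tables round-trip their census and rank spreads", {
  ds <- pipe_ds(seed = 71L)
  rep <- screen_triplets(ds, k = 8L,
                         cutoffs = c(accuracy = 0.8, precision = 0.8),
                         elm_config = elm_config(n_hidden = 30L, seed = 1L),
                         split_spec = split_spec(0.8, seed = 1L))
  path <- tempfile(fileext = ".tsv")
  write_report_table(rep, path)
  back <- read_report_table(path)
  expect_equal(back$n_triplets, 56)
  expect_equal(back$census_accuracy, rep$census[["accuracy"]])
  b10 <- suppressWarnings(best10(rep, "accuracy"))
  expect_equal(back$best10_min_mean_rank_accuracy, attr(b10, "min_mean_rank"))
  expect_equal(back$best10_max_mean_rank_accuracy, attr(b10, "max_mean_rank"))
})

test_that("difference heatmap renders and annotates the TSV-exported maximum", {
  ds <- pipe_ds(seed = 72L)
  a <- fit_elm(ds, elm_config(n_hidden = 20L, seed = 1L))
  b <- fit_elm(ds, elm_config(n_hidden = 20L, seed = 2L))
  d <- weight_difference(a, b)

  tsv <- tempfile(fileext = ".tsv")
  write_difference_matrix(d, tsv)
  exported <- data.table::fread(tsv, data.table = FALSE)
  expect_equal(max(as.matrix(exported[, -1])), d$max_difference)

  img <- tempfile(fileext = ".png")
  plot_difference_heatmap(d, img)
  expect_true(file.exists(img) && file.size(img) > 0)

  # zero matrix renders too
  img0 <- tempfile(fileext = ".png")
  plot_difference_heatmap(weight_difference(a, a), img0)
  expect_true(file.exists(img0))
})

test_that("3-D scatter exports one coordinate row per record, bijectively", {
  ds <- pipe_ds(seed = 73L)
  rep <- screen_triplets(ds, k = 6L, cutoffs = c(accuracy = 0.8),
                         elm_config = elm_config(n_hidden = 30L, seed = 1L),
                         split_spec = split_spec(0.8, seed = 1L))
  img <- tempfile(fileext = ".png")
  out <- plot_triplet_scatter(rep, "accuracy", img)
  expect_true(file.exists(out[["image"]]))
  coords <- data.table::fread(out[["coords"]], data.table = FALSE)
  expect_identical(nrow(coords), nrow(rep$records))
  expect_identical(coords[, c("x", "y", "z")],
                   rep$records[, c("x", "y", "z")])
  # a single record still plots
  one <- rep; one$records <- rep$records[1, ]
  img1 <- tempfile(fileext = ".png")
  expect_no_error(plot_triplet_scatter(one, "accuracy", img1))
})

test_that("full_pipeline writes all artifacts; reruns are byte-identical; plots optional", {
  ds <- pipe_ds(seed = 74L)
  out1 <- file.path(tempdir(), "pipe1")
  full_pipeline(ds = ds, out_dir = out1, config = pipe_cfg, seed = 5L)
  tables <- c("manifest.json", "ranked_features.tsv", "screen_report.tsv",
              "per_run_log.tsv", "difference_matrix.tsv",
              "triplet_report.tsv", "triplet_records.tsv")
  expect_true(all(file.exists(file.path(out1, tables))))
  expect_true(file.exists(file.path(out1, "difference_heatmap.png")))
  expect_true(file.exists(file.path(out1, "scatter_accuracy.png")))

  # rerun with the manifest's configuration: numeric TSVs byte-identical
  manifest <- read_manifest(file.path(out1, "manifest.json"))
  out2 <- file.path(tempdir(), "pipe2")
  full_pipeline(ds = ds, out_dir = out2, config = manifest$config,
                seed = manifest$config$seed)
  for (f in setdiff(tables, "manifest.json")) {
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out1, f)),
                     label = f)
  }

  # --skip-plots: all tables, no images
  out3 <- file.path(tempdir(), "pipe3")
  full_pipeline(ds = ds, out_dir = out3,
                config = c(pipe_cfg, list(skip_plots = TRUE)), seed = 5L)
  expect_true(all(file.exists(file.path(out3, tables))))
  expect_false(any(grepl("\\.png$", list.files(out3))))
})

test_that("pipeline failures name the failing stage", {
  bad <- pipe_ds(seed = 75L)
  expect_error(
    full_pipeline(ds = bad, out_dir = file.path(tempdir(), "pipe_bad"),
                  config = list(screen = list(n_runs = 2L, n_hidden = 10L),
                                triplets = list(k = 2L)),
                  seed = 1L),
    "stage 'triplets'")
})

test_that("the CLI covers simulate -> rank -> screen -> triplets on disk", {
  sim_dir <- file.path(tempdir(), "cli_sim")
  suppressMessages(multisol_cli(c("simulate", "--preset", "easy",
                                  "--seed", "6", "--out", sim_dir)))
  mat <- file.path(sim_dir, "matrix.tsv")
  lab <- file.path(sim_dir, "labels.tsv")
  expect_true(file.exists(mat) && file.exists(lab))
  ds <- read_dataset(mat, lab, positive_class = "case")
  expect_identical(dim(ds), c(1000L, 60L))
  # identical to the in-memory generator under the same seed
  expect_equal(ds$values, generate_dataset(synthetic_preset("easy", 6L))$values)

  rank_out <- file.path(tempdir(), "cli_rank.tsv")
  suppressMessages(multisol_cli(c("rank", "--out", rank_out, mat, lab)))
  ranked <- data.table::fread(rank_out, data.table = FALSE)
  expect_identical(nrow(ranked), 1000L)

  scr_dir <- file.path(tempdir(), "cli_screen")
  capture.output(suppressMessages(multisol_cli(c(
    "screen", "--mode", "top20", "--runs", "8", "--cutoff", "0.9",
    "--seed", "3", "--skip-plots", "--out", scr_dir,
    "--positive-class", "case", mat, lab))))
  expect_true(file.exists(file.path(scr_dir, "per_run_log.tsv")))
  expect_true(file.exists(file.path(scr_dir, "difference_matrix.tsv")))

  tri_dir <- file.path(tempdir(), "cli_triplets")
  capture.output(suppressMessages(multisol_cli(c(
    "triplets", "--k", "6", "--cutoff-acc", "0.9", "--seed", "3",
    "--skip-plots", "--out", tri_dir, "--positive-class", "case", mat, lab))))
  rec <- data.table::fread(file.path(tri_dir, "triplet_records.tsv"),
                           data.table = FALSE)
  expect_identical(nrow(rec), 20L)
  expect_error(multisol_cli("nope"), "unknown subcommand")
})
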