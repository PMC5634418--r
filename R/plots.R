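# Figure renderers. Plots are always paired with a TSV holding the same
# numbers, so the images are presentation only.

open_device <- function(path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported image format: .", ext, " (use .png or .pdf)"))
}

#' Heatmap of a weight-difference matrix
#'
#' White encodes no difference (0) and red the maximum observed difference;
#' the color scale is anchored at exactly these two values and the maximum
#' difference is annotated in the title. A zero matrix renders as a uniform
#' white panel annotated 0.
#'
#' @param diff a [weight_difference()] result.
#' @param path output image path (`.png` or `.pdf`).
#' @return invisibly, `path`.
#' @export
plot_difference_heatmap <- function(diff, path) {
  stopifnot(inherits(diff, "DifferenceMatrix"))
  open_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  v <- diff$values
  maxd <- diff$max_difference
  pal <- grDevices::colorRampPalette(c("white", "red"))(256L)
  breaks <- if (maxd > 0) seq(0, maxd, length.out = 257L) else c(-1e-12, 1e-12)
  graphics::image(
    x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = t(v),
    col = if (maxd > 0) pal else "white", breaks = breaks,
    xlab = "feature", ylab = "hidden unit", useRaster = TRUE,
    main = sprintf("Weight difference |W1 - W2| (max = %.3g)", maxd)
  )
  invisible(path)
}

#' 3-D scatter of triplet ranks colored by a performance metric
#'
#' Each screened triplet is a point at its rank coordinates `(x, y, z)`
#' (`x <= y <= z`), colored from grey (worst observed) to red (best).
#' A coordinate sidecar TSV (`<path>_coords.tsv`, columns `x, y, z, metric`)
#' carries the exact plotted values; its rows map one-to-one onto the
#' report's records.
#'
#' @param report a [screen_triplets()] report (or its `records` subset).
#' @param metric `"accuracy"`, `"precision"` or `"recall"`.
#' @param path output image path (`.png` or `.pdf`).
#' @return invisibly, `c(image = path, coords = sidecar)`.
#' @export
plot_triplet_scatter <- function(report,
                                 metric = c("accuracy", "precision", "recall"),
                                 path) {
  metric <- match.arg(metric)
  rec <- if (inherits(report, "TripletScreenReport")) report$records else report
  fail_if(!is.data.frame(rec) || nrow(rec) == 0L, "no triplet records to plot")
  coords <- data.frame(x = rec$x, y = rec$y, z = rec$z,
                       metric = rec[[metric]])
  sidecar <- paste0(tools::file_path_sans_ext(path), "_coords.tsv")
  data.table::fwrite(coords, sidecar, sep = "\t")

  v <- coords$metric
  ok <- !is.na(v)
  col <- rep("grey80", nrow(coords))
  if (any(ok)) {
    rng <- range(v[ok])
    rel <- if (diff(rng) > 0) (v[ok] - rng[1L]) / diff(rng) else rep(1, sum(ok))
    pal <- grDevices::colorRampPalette(c("grey70", "orange", "red"))(101L)
    col[ok] <- pal[round(rel * 100) + 1L]
  }
  open_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(lattice::cloud(
    z ~ x * y, data = coords, col = col, pch = 16, cex = 0.4,
    main = sprintf("Triplet ranks colored by %s (grey = min, red = max)",
                   metric),
    xlab = "x", ylab = "y", zlab = "z"
  ))
  invisible(c(image = path, coords = sidecar))
}
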