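# Explainability and reporting: tile score records, top-tile retrieval,
# score export, tile galleries, lesion area fractions.
#
# MIPCL's per-instance Softmax probabilities of the Grad-CAM logits, paired
# with each tile's slide coordinates, are the raw material for review: the
# highest-probability tiles for the positive class point the cytopathologist
# at the most high-yield regions of the slide.

#' Per-tile score records for a fitted model
#'
#' Runs a MIPCL model in inference mode on one bag and returns one record
#' per tile: coordinates, CAM-derived class probabilities and the selection
#' flag. (For ABMIL/CLAM use `predict(fit, bag, type = "instance")`, which
#' reports attention weights instead.)
#'
#' @param object A fitted `mil_model` with `model = "mipcl"`.
#' @param bag A [feature_bag()].
#' @return Data frame with columns `slide_id`, `x`, `y`, `prob_negative`,
#'   `prob_positive`, `selected`; `prob_negative + prob_positive = 1` per
#'   row.
#' @export
instance_scores <- function(object, bag) {
  stopifnot(inherits(object, "mil_model"))
  if (object$model != "mipcl") {
    stop("instance_scores requires a MIPCL model; use predict(type = 'instance') for attention baselines")
  }
  predict(object, bag, type = "instance")[[1]]
}

#' Retrieve the top-ranked tiles for a class
#'
#' Filters the records whose probability for the requested class strictly
#' exceeds `threshold`, sorts them by probability (descending) with ties
#' broken by `y` then `x` ascending, and truncates to the top `k`. An empty
#' result is legal when nothing passes the threshold.
#'
#' @param records Data frame as from [instance_scores()].
#' @param class_id `"positive"` (default) or `"negative"`, or 1/0.
#' @param threshold Probability threshold (default 0.85, matching the
#'   selection thresholds).
#' @param k Maximum number of tiles returned (default 10, a one-screen
#'   gallery).
#' @return The ranked subset of `records`, with a `rank` column.
#' @export
top_tiles <- function(records, class_id = "positive", threshold = 0.85,
                      k = 10L) {
  stopifnot(nrow(records) >= 1L)
  if (is.numeric(class_id)) class_id <- c("negative", "positive")[class_id + 1L]
  class_id <- match.arg(class_id, c("positive", "negative"))
  col <- paste0("prob_", class_id)
  keep <- records[records[[col]] > threshold, , drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- keep
    out$rank <- integer(0)
    return(out)
  }
  ord <- order(-keep[[col]], keep$y, keep$x)
  keep <- keep[ord, , drop = FALSE][seq_len(min(k, nrow(keep))), , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}

#' Export tile score records to CSV
#'
#' Fixed column order `slide_id, x, y, prob_negative, prob_positive,
#' selected`; probabilities are written with 6 decimal places and
#' round-trip losslessly at that precision through [read_scores()].
#'
#' @param records Data frame as from [instance_scores()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_scores <- function(records, path) {
  cols <- c("slide_id", "x", "y", "prob_negative", "prob_positive", "selected")
  stopifnot(all(cols %in% colnames(records)))
  out <- records[, cols, drop = FALSE]
  out$prob_negative <- sprintf("%.6f", out$prob_negative)
  out$prob_positive <- sprintf("%.6f", out$prob_positive)
  out$selected <- as.integer(out$selected)
  utils::write.csv(out, path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' @rdname export_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    slide_id = "character", x = "integer", y = "integer",
    prob_negative = "numeric", prob_positive = "numeric",
    selected = "integer"
  ))
  df$selected <- df$selected == 1L
  df
}

#' Render a gallery of top tiles
#'
#' Crops each ranked tile out of the slide image and arranges the crops in
#' a grid annotated with their probabilities. Purely presentational: scores
#' are not modified. With an empty ranking no file is written and a warning
#' is raised.
#'
#' @param image H x W x 3 RGB slide image.
#' @param ranked Data frame from [top_tiles()] (needs `x`, `y` and a
#'   `prob_*` column).
#' @param path Output PNG path.
#' @param tile_size Tile edge length in pixels (default 256).
#' @param ncol Gallery columns (default 5).
#' @param class_id Which probability to annotate (default `"positive"`).
#' @return `path` invisibly, or `NULL` if nothing was rendered.
#' @export
render_gallery <- function(image, ranked, path, tile_size = 256L, ncol = 5L,
                           class_id = "positive") {
  if (nrow(ranked) == 0L) {
    warning("no tiles to render; gallery not written")
    return(invisible(NULL))
  }
  img <- as_rgb01(image)
  col <- paste0("prob_", match.arg(class_id, c("positive", "negative")))
  crops <- lapply(seq_len(nrow(ranked)), function(i) {
    crop_tile(img, c(ranked$x[i], ranked$y[i]), tile_size)
  })
  n <- length(crops)
  nc <- min(ncol, n)
  nr <- ceiling(n / nc)
  grDevices::png(path, width = nc * 220L, height = nr * 240L)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 1.5, 0.5))
  for (i in seq_len(n)) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
    graphics::rasterImage(crops[[i]], 0, 0, 1, 1)
    graphics::title(sprintf("#%d  p=%.3f  (%d,%d)", i, ranked[[col]][i],
                            ranked$x[i], ranked$y[i]), cex.main = 0.9)
  }
  invisible(path)
}

#' Percent slide area occupied by a region
#'
#' `100 * (region_w * region_h) / (wsi_w * wsi_h)` with units normalized
#' before division, rounded to 2 significant figures. A lesion of tens of
#' micrometres on a millimetre-scale slide occupies a vanishing fraction of
#' the area — the scale of findings the tile ranking is meant to surface.
#'
#' @param region_w,region_h Region dimensions.
#' @param wsi_w,wsi_h Slide dimensions.
#' @param region_unit,wsi_unit Length units, `"um"` or `"mm"` (defaults:
#'   region in micrometres, slide in millimetres).
#' @return Percentage, rounded to 2 significant figures.
#' @examples
#' area_fraction(69.85, 31.8, 3.5, 2.0)  # 0.032
#' @export
area_fraction <- function(region_w, region_h, wsi_w, wsi_h,
                          region_unit = "um", wsi_unit = "mm") {
  to_um <- function(x, unit) {
    switch(match.arg(unit, c("um", "mm")), um = x, mm = x * 1000)
  }
  if (any(c(region_w, region_h, wsi_w, wsi_h) <= 0)) {
    stop("all dimensions must be positive")
  }
  rw <- to_um(region_w, region_unit)
  rh <- to_um(region_h, region_unit)
  ww <- to_um(wsi_w, wsi_unit)
  wh <- to_um(wsi_h, wsi_unit)
  signif(100 * (rw * rh) / (ww * wh), 2)
}
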