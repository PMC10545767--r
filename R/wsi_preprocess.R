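# Slide preprocessing: HSV color-filter masking, mask-guided tessellation
# into fixed-size tiles, and feature extraction through a pluggable backbone.
#
# Cytology smears carry abundant preparation noise, so foreground detection
# is done with per-stain color filters in hue-saturation-value space rather
# than intensity thresholding; the filters select nuclear and cytoplasmic
# color ranges and, as a side effect, eliminate marker-ink annotations whose
# colors fall outside both ranges. The masked slide is tessellated into
# non-overlapping 256 x 256 pixel tiles at the masked locations and each
# retained tile is reduced to a feature vector by a pretrained backbone
# followed by global average pooling (here a pluggable interface; a
# deterministic color-statistics stub ships for tests).

#' HSV color filter specification for one stain
#'
#' Each of `nucleus_range` and `cytoplasm_range` is a list with components
#' `h`, `s`, `v`, each a length-2 interval. Hue is in degrees `[0, 360)` and
#' may wrap around (`lo > hi` means `[lo, 360) U [0, hi]`); saturation and
#' value are in `[0, 1]`.
#'
#' The published Diff-Quik and Pap filter ranges were tuned empirically on
#' institutional slides and are not public; the `diffquik` and `pap`
#' defaults shipped by [default_hsv_filters()] are illustrative starting
#' points only and must be re-tuned for real scanners/stain batches. The
#' `synthetic` filter is exact for the built-in smear renderer.
#'
#' @param stain One of `"diffquik"`, `"pap"`, `"synthetic"`.
#' @param nucleus_range,cytoplasm_range HSV interval triples (see Details).
#' @return An object of class `hsv_filter_spec`.
#' @export
hsv_filter_spec <- function(stain, nucleus_range, cytoplasm_range) {
  stain <- match.arg(stain, c("diffquik", "pap", "synthetic"))
  check_range <- function(r, what) {
    if (!is.list(r) || !all(c("h", "s", "v") %in% names(r))) {
      stop(sprintf("%s must be a list with components h, s, v", what))
    }
    stopifnot(length(r$h) == 2L, length(r$s) == 2L, length(r$v) == 2L)
    if (any(r$h < 0) || any(r$h >= 360)) {
      stop(sprintf("%s: hue bounds must lie in [0, 360)", what))
    }
    if (r$s[1] > r$s[2] || r$v[1] > r$v[2] ||
        any(c(r$s, r$v) < 0) || any(c(r$s, r$v) > 1)) {
      stop(sprintf("%s: s and v must be ordered intervals within [0, 1]", what))
    }
    r
  }
  structure(
    list(
      stain = stain,
      nucleus_range = check_range(nucleus_range, "nucleus_range"),
      cytoplasm_range = check_range(cytoplasm_range, "cytoplasm_range")
    ),
    class = "hsv_filter_spec"
  )
}

#' Default HSV filters per stain
#'
#' @param stain One of `"synthetic"`, `"diffquik"`, `"pap"`.
#' @return An [hsv_filter_spec()].
#' @export
default_hsv_filters <- function(stain = c("synthetic", "diffquik", "pap")) {
  stain <- match.arg(stain)
  switch(stain,
    synthetic = hsv_filter_spec(
      "synthetic",
      nucleus_range = list(h = c(255, 295), s = c(0.45, 0.80), v = c(0.28, 0.62)),
      cytoplasm_range = list(h = c(190, 230), s = c(0.28, 0.62), v = c(0.60, 0.92))
    ),
    # Illustrative only: Romanowsky-type stain, blue-purple nuclei on
    # blue-gray cytoplasm.
    diffquik = hsv_filter_spec(
      "diffquik",
      nucleus_range = list(h = c(220, 300), s = c(0.25, 1), v = c(0.15, 0.75)),
      cytoplasm_range = list(h = c(170, 260), s = c(0.08, 0.6), v = c(0.45, 0.95))
    ),
    # Illustrative only: Papanicolaou stain, dark blue nuclei, green-orange
    # cytoplasm.
    pap = hsv_filter_spec(
      "pap",
      nucleus_range = list(h = c(200, 290), s = c(0.2, 1), v = c(0.1, 0.7)),
      cytoplasm_range = list(h = c(20, 180), s = c(0.1, 0.9), v = c(0.35, 0.95))
    )
  )
}

## Interval membership with hue wrap-around.
hue_in <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

hsv_in_range <- function(h, s, v, range) {
  hue_in(h, range$h[1], range$h[2]) &
    s >= range$s[1] & s <= range$s[2] &
    v >= range$v[1] & v <= range$v[2]
}

## Coerce an image to an H x W x 3 array in [0, 1].
as_rgb01 <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be an H x W x 3 RGB array")
  }
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) > 1) img <- img / 255
  img
}

#' Compute the binary HSV foreground mask of an RGB image
#'
#' A pixel is foreground (1) iff its HSV value falls inside the filter's
#' nucleus range or cytoplasm range. Colors outside both ranges — slide
#' background and marker-ink annotations — map to 0.
#'
#' @param image H x W x 3 RGB array, either in `[0, 1]` or 8-bit `[0, 255]`.
#' @param filter An [hsv_filter_spec()].
#' @return H x W binary (integer) matrix.
#' @export
hsv_mask <- function(image, filter) {
  stopifnot(inherits(filter, "hsv_filter_spec"))
  img <- as_rgb01(image)
  h <- dim(img)[1]
  w <- dim(img)[2]
  px <- rbind(
    as.vector(img[, , 1]),
    as.vector(img[, , 2]),
    as.vector(img[, , 3])
  )
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  hh <- hsv[1, ] * 360
  ss <- hsv[2, ]
  vv <- hsv[3, ]
  sel <- hsv_in_range(hh, ss, vv, filter$nucleus_range) |
    hsv_in_range(hh, ss, vv, filter$cytoplasm_range)
  matrix(as.integer(sel), h, w)
}

#' Tessellate a binary mask into retained fixed-size tiles
#'
#' Lays a non-overlapping raster grid of `tile_size` x `tile_size` tiles
#' (stride = tile size, trailing partial tiles dropped) over the mask and
#' retains a tile iff its masked-pixel fraction is at least
#' `min_occupancy`. Tile origins are 0-based `(x, y)` = (column, row)
#' top-left corners; tiles are half-open `[x, x + tile_size) x [y, y +
#' tile_size)`.
#'
#' @param mask H x W binary matrix (as from [hsv_mask()]).
#' @param tile_size Tile edge length in pixels (default 256).
#' @param min_occupancy Minimum masked fraction for a tile to be retained
#'   (default 0.10; a small floor that avoids effectively empty tiles).
#' @return An object of class `tile_grid`: list with `tile_size`, `origins`
#'   (M x 2 integer matrix, columns `x`, `y`, raster order), `occupancy`
#'   (length-M vector in `[0, 1]`).
#' @export
tessellate <- function(mask, tile_size = 256L, min_occupancy = 0.1) {
  stopifnot(is.matrix(mask), tile_size >= 1)
  h <- nrow(mask)
  w <- ncol(mask)
  nx <- w %/% tile_size
  ny <- h %/% tile_size
  if (nx < 1L || ny < 1L) {
    warning("mask is smaller than one tile; returning an empty grid")
    return(structure(
      list(tile_size = as.integer(tile_size),
           origins = matrix(integer(0), 0L, 2L,
                            dimnames = list(NULL, c("x", "y"))),
           occupancy = numeric(0)),
      class = "tile_grid"
    ))
  }
  m <- mask[seq_len(ny * tile_size), seq_len(nx * tile_size), drop = FALSE]
  # block sums: collapse rows into ny groups, then columns into nx groups
  rgrp <- rep(seq_len(ny), each = tile_size)
  cgrp <- rep(seq_len(nx), each = tile_size)
  rs <- rowsum(m, rgrp)                    # ny x (nx*ts)
  occ_mat <- t(rowsum(t(rs), cgrp))        # ny x nx tile sums
  occ_mat <- occ_mat / (tile_size^2)
  # raster order: y outer, x inner
  origins <- cbind(
    x = rep(seq_len(nx) - 1L, times = ny) * tile_size,
    y = rep(seq_len(ny) - 1L, each = nx) * tile_size
  )
  occ <- as.vector(t(occ_mat))
  keep <- occ >= min_occupancy
  structure(
    list(
      tile_size = as.integer(tile_size),
      origins = matrix(as.integer(origins[keep, , drop = FALSE]),
                       sum(keep), 2L, dimnames = list(NULL, c("x", "y"))),
      occupancy = occ[keep]
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d x %d px\n",
              nrow(x$origins), x$tile_size, x$tile_size))
  invisible(x)
}

#' Construct a feature extractor
#'
#' A feature extractor maps a list of tile arrays (each `tile_size x
#' tile_size x 3`, values in `[0, 1]`) to a finite numeric feature matrix
#' with one row per tile — the analogue of a pretrained CNN backbone
#' followed by global average pooling. Extractors must be deterministic in
#' inference.
#'
#' @param name Extractor name (stored with bags).
#' @param output_dim Feature dimensionality C.
#' @param apply Function `(list of tiles) -> N x output_dim matrix`.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(name, output_dim, apply) {
  stopifnot(is.character(name), is_count(output_dim), is.function(apply))
  structure(
    list(name = name, output_dim = as.integer(output_dim), apply = apply),
    class = "feature_extractor"
  )
}

#' Deterministic color-statistics stub extractor
#'
#' Reduces each tile to its per-channel mean (`output_dim = 3`), optionally
#' augmented with per-channel standard deviations (`output_dim = 6`). Used
#' in tests and anywhere a pretrained backbone is unavailable; the global
#' average pooling step of a CNN backbone degenerates to exactly this per-
#' channel mean for a 1 x 1 convolutional identity "network".
#'
#' @param with_sd Append per-channel standard deviations.
#' @return A [feature_extractor()].
#' @export
stub_extractor <- function(with_sd = FALSE) {
  dim_out <- if (with_sd) 6L else 3L
  feature_extractor(
    name = if (with_sd) "stub_mean_sd" else "stub_mean",
    output_dim = dim_out,
    apply = function(tiles) {
      t(vapply(tiles, function(tl) {
        m <- apply(tl, 3L, mean)
        if (with_sd) c(m, apply(tl, 3L, stats::sd)) else m
      }, numeric(dim_out)))
    }
  )
}

## Crop a half-open tile [x, x+ts) x [y, y+ts) from an RGB array
## (0-based x = column, y = row).
crop_tile_internal <- function(img, x, y, ts) {
  img[(y + 1L):(y + ts), (x + 1L):(x + ts), , drop = FALSE]
}

#' Crop one tile out of an image
#'
#' @param image H x W x 3 RGB array.
#' @param origin Length-2 vector, 0-based `(x, y)` top-left corner.
#' @param tile_size Tile edge length in pixels.
#' @return `tile_size x tile_size x 3` array.
#' @export
crop_tile <- function(image, origin, tile_size = 256L) {
  img <- as_rgb01(image)
  x <- origin[1]
  y <- origin[2]
  if (x < 0 || y < 0 || x + tile_size > dim(img)[2] ||
      y + tile_size > dim(img)[1]) {
    stop(sprintf("tile at (%d, %d) lies outside the image", x, y))
  }
  crop_tile_internal(img, x, y, tile_size)
}

#' Convert a slide image to a tile feature bag
#'
#' Runs the full preprocessing front-end: HSV foreground mask, mask-guided
#' tessellation, per-tile feature extraction. Row `i` of the resulting
#' features corresponds to row `i` of the tile origins.
#'
#' @param image H x W x 3 RGB array.
#' @param filter An [hsv_filter_spec()]; its `stain` is stored in the bag.
#' @param extractor A [feature_extractor()].
#' @param min_occupancy Minimum masked tile fraction (see [tessellate()]).
#' @param tile_size Tile edge length in pixels (default 256).
#' @param slide_id Identifier stored in the bag.
#' @param bag_label Slide-level label (0/1); `NA` for unlabeled slides is
#'   not supported by [feature_bag()], so default is 0.
#' @return A [feature_bag()].
#' @export
extract_bag <- function(image, filter, extractor, min_occupancy = 0.1,
                        tile_size = 256L, slide_id = "slide", bag_label = 0L) {
  stopifnot(inherits(extractor, "feature_extractor"))
  img <- as_rgb01(image)
  mask <- hsv_mask(img, filter)
  grid <- tessellate(mask, tile_size, min_occupancy)
  if (nrow(grid$origins) == 0L) {
    stop("no tiles retained; consider lowering min_occupancy")
  }
  tiles <- lapply(seq_len(nrow(grid$origins)), function(i) {
    crop_tile_internal(img, grid$origins[i, 1], grid$origins[i, 2], tile_size)
  })
  feats <- extractor$apply(tiles)
  stopifnot_finite(feats, "extracted features")
  if (ncol(feats) != extractor$output_dim) {
    stop("extractor returned the wrong feature dimensionality")
  }
  feature_bag(
    features = feats,
    coords = grid$origins,
    bag_label = bag_label,
    slide_id = slide_id,
    stain = filter$stain,
    tile_size = tile_size,
    extractor_name = extractor$name
  )
}

#' Read a slide image from PNG or TIFF
#'
#' @param path Image file path; format inferred from the extension.
#' @return H x W x 3 RGB array in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  as_rgb01(img)
}
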