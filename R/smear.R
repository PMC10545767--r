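# Synthetic smear-image renderer.
#
# A deliberately simple fixture generator for the preprocessing front-end:
# disk-shaped cell clusters (cytoplasm with nucleus-colored speckles) on a
# pale background, plus a few marker-ink dots of a color lying outside the
# nucleus/cytoplasm HSV filter ranges — emulating the cytotechnologist dots
# that the color filter must eliminate. It makes no attempt at realistic
# cytomorphology; its role is to give the HSV mask and tessellation code a
# ground truth to be checked against.

#' Specification of a synthetic smear image
#'
#' Colors are HSV triples `c(h, s, v)` with hue in `[0, 360)` and
#' saturation/value in `[0, 1]`. The defaults are paired with
#' `default_hsv_filters("synthetic")`: nucleus and cytoplasm colors fall
#' inside the filter ranges, background and ink fall outside.
#'
#' @param width,height Image size in pixels.
#' @param n_clusters Number of cell clusters to paint.
#' @param cluster_radius_range Pixel interval for cluster radii.
#' @param nucleus_color_hsv,cytoplasm_color_hsv,background_color_hsv,ink_color_hsv
#'   HSV color triples.
#' @param n_ink_range Integer interval for the number of ink dots (1-3 by
#'   default).
#' @param seed Optional integer seed.
#' @return An object of class `smear_spec`.
#' @export
smear_spec <- function(width = 512, height = 512,
                       n_clusters = 6,
                       cluster_radius_range = c(20, 45),
                       nucleus_color_hsv = c(275, 0.62, 0.45),
                       cytoplasm_color_hsv = c(210, 0.45, 0.78),
                       background_color_hsv = c(40, 0.02, 0.97),
                       ink_color_hsv = c(120, 0.85, 0.30),
                       n_ink_range = c(1, 3),
                       seed = NULL) {
  stopifnot(
    is_count(width, 32), is_count(height, 32),
    is_count(n_clusters, 0),
    length(cluster_radius_range) == 2L,
    cluster_radius_range[1] >= 2,
    cluster_radius_range[1] <= cluster_radius_range[2]
  )
  for (col in list(nucleus_color_hsv, cytoplasm_color_hsv,
                   background_color_hsv, ink_color_hsv)) {
    stopifnot(length(col) == 3L, col[1] >= 0, col[1] < 360,
              all(col[2:3] >= 0), all(col[2:3] <= 1))
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      n_clusters = as.integer(n_clusters),
      cluster_radius_range = cluster_radius_range,
      nucleus_color_hsv = nucleus_color_hsv,
      cytoplasm_color_hsv = cytoplasm_color_hsv,
      background_color_hsv = background_color_hsv,
      ink_color_hsv = ink_color_hsv,
      n_ink_range = as.integer(n_ink_range),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "smear_spec"
  )
}

hsv_to_rgb01 <- function(hsv_triple) {
  as.vector(grDevices::col2rgb(
    grDevices::hsv(hsv_triple[1] / 360, hsv_triple[2], hsv_triple[3])
  )) / 255
}

## Paint a disk into an H x W x 3 array; returns the updated array.
paint_disk <- function(img, cx, cy, r, rgb01, rowm, colm) {
  sel <- (rowm - cy)^2 + (colm - cx)^2 <= r^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- rgb01[ch]
    img[, , ch] <- plane
  }
  img
}

disk_mask <- function(h, w, cx, cy, r, rowm, colm) {
  (rowm - cy)^2 + (colm - cx)^2 <= r^2
}

#' Render a synthetic smear image with ground-truth cell mask
#'
#' Paints `n_clusters` disk-shaped cell clusters (cytoplasm color with
#' nucleus-colored speckles) on the background color, then 1-3 ink dots in
#' the ink color at positions not overlapping any cluster. Pixel values are
#' quantized to 8 bits so that the rendered image round-trips through PNG
#' exactly. Deterministic when `spec$seed` is set.
#'
#' @param spec A [smear_spec()].
#' @param filter Optional [hsv_filter_spec()]; when supplied, a warning is
#'   raised if the ink color falls inside the filter's nucleus or cytoplasm
#'   range (which would defeat ink elimination).
#' @return A list with `image` (H x W x 3 array in `[0, 1]`, 8-bit
#'   quantized), `mask` (H x W binary matrix of painted cell pixels; ink
#'   dots are not cell pixels), `clusters` (matrix of cluster `cx`, `cy`,
#'   `r`) and `ink` (matrix of ink-dot `cx`, `cy`, `r`).
#' @export
render_smear_image <- function(spec, filter = NULL) {
  stopifnot(inherits(spec, "smear_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height
  w <- spec$width
  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- array(0, dim = c(h, w, 3))
  bg <- hsv_to_rgb01(spec$background_color_hsv)
  for (ch in 1:3) img[, , ch] <- bg[ch]
  cellmask <- matrix(FALSE, h, w)

  cyt <- hsv_to_rgb01(spec$cytoplasm_color_hsv)
  nuc <- hsv_to_rgb01(spec$nucleus_color_hsv)
  centers <- NULL
  if (spec$n_clusters > 0) {
    rmax <- spec$cluster_radius_range[2]
    if (2 * rmax + 4 > min(h, w)) {
      stop("cluster radius too large for the image size")
    }
    for (k in seq_len(spec$n_clusters)) {
      r <- stats::runif(1, spec$cluster_radius_range[1],
                        spec$cluster_radius_range[2])
      cx <- stats::runif(1, r + 1, w - r)
      cy <- stats::runif(1, r + 1, h - r)
      centers <- rbind(centers, c(cx, cy, r))
      dm <- disk_mask(h, w, cx, cy, r, rowm, colm)
      cellmask <- cellmask | dm
      img <- paint_disk(img, cx, cy, r, cyt, rowm, colm)
      # nucleus speckles inside the cluster
      n_spk <- max(3L, round(r / 4))
      for (s in seq_len(n_spk)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.6 * r)
        sr <- stats::runif(1, 2, max(2.5, r / 8))
        img <- paint_disk(img, cx + rad * cos(ang), cy + rad * sin(ang),
                          sr, nuc, rowm, colm)
      }
    }
  }

  # ink dots, rejection-sampled away from clusters
  if (!is.null(filter)) {
    ink <- spec$ink_color_hsv
    if (hsv_in_range(ink[1], ink[2], ink[3], filter$nucleus_range) ||
        hsv_in_range(ink[1], ink[2], ink[3], filter$cytoplasm_range)) {
      warning("ink color falls inside the paired HSV filter ranges; ink dots will not be eliminated")
    }
  }
  ink_rgb <- hsv_to_rgb01(spec$ink_color_hsv)
  n_ink <- if (spec$n_ink_range[1] == spec$n_ink_range[2]) {
    spec$n_ink_range[1]
  } else {
    sample(spec$n_ink_range[1]:spec$n_ink_range[2], 1L)
  }
  ink <- NULL
  for (d in seq_len(n_ink)) {
    for (try in seq_len(200L)) {
      r <- stats::runif(1, 5, 10)
      cx <- stats::runif(1, r + 1, w - r)
      cy <- stats::runif(1, r + 1, h - r)
      clear <- TRUE
      if (!is.null(centers)) {
        clear <- all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                       centers[, 3] + r + 2)
      }
      if (clear) {
        img <- paint_disk(img, cx, cy, r, ink_rgb, rowm, colm)
        ink <- rbind(ink, c(cx, cy, r))
        break
      }
    }
  }

  img <- round(img * 255) / 255
  dn <- list(NULL, c("cx", "cy", "r"))
  list(
    image = img,
    mask = cellmask * 1L,
    clusters = if (is.null(centers)) {
      matrix(numeric(0), 0L, 3L, dimnames = dn)
    } else {
      matrix(centers, ncol = 3L, dimnames = dn)
    },
    ink = if (is.null(ink)) {
      matrix(numeric(0), 0L, 3L, dimnames = dn)
    } else {
      matrix(ink, ncol = 3L, dimnames = dn)
    }
  )
}
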