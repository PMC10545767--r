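# Preprocessing front-end: HSV masking, tessellation, feature extraction,
# HDF5 persistence.

uniform_image <- function(h, w, hsv_triple) {
  rgb <- as.vector(grDevices::col2rgb(
    grDevices::hsv(hsv_triple[1] / 360, hsv_triple[2], hsv_triple[3])
  )) / 255
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  round(img * 255) / 255
}

test_that("hsv_mask keeps stain colors and rejects background and ink", {
  filt <- default_hsv_filters("synthetic")
  bg <- uniform_image(8, 8, c(40, 0.02, 0.97))
  expect_true(all(hsv_mask(bg, filt) == 0L))
  nucleus_center <- c(mean(filt$nucleus_range$h), mean(filt$nucleus_range$s),
                      mean(filt$nucleus_range$v))
  nuc <- uniform_image(8, 8, nucleus_center)
  expect_true(all(hsv_mask(nuc, filt) == 1L))
  ink <- uniform_image(8, 8, c(120, 0.85, 0.30))
  expect_true(all(hsv_mask(ink, filt) == 0L))
  expect_error(hsv_mask(matrix(0, 4, 4), filt), "RGB")
})

test_that("the smear fixture mask matches ground truth and a per-pixel reference", {
  filt <- default_hsv_filters("synthetic")
  sm <- render_smear_image(smear_spec(width = 96, height = 96, n_clusters = 2,
                                      cluster_radius_range = c(10, 16),
                                      seed = 21), filter = filt)
  m <- hsv_mask(sm$image, filt)
  # ink pixels are never masked
  ink_px <- matrix(FALSE, 96, 96)
  for (k in seq_len(nrow(sm$ink))) {
    for (i in 1:96) {
      for (j in 1:96) {
        if ((i - sm$ink[k, "cy"])^2 + (j - sm$ink[k, "cx"])^2 <=
              sm$ink[k, "r"]^2) {
          ink_px[i, j] <- TRUE
        }
      }
    }
  }
  expect_true(any(ink_px))
  expect_true(all(m[ink_px] == 0L))
  # high agreement with the ground-truth cell mask
  jac <- sum(m == 1 & sm$mask == 1) / sum(m == 1 | sm$mask == 1)
  expect_gte(jac, 0.95)
  # exact agreement with the per-pixel reference loop
  expect_identical(m, reference_hsv_mask(sm$image, filt))
})

test_that("hsv_mask is idempotent under in-range reduction", {
  filt <- default_hsv_filters("synthetic")
  sm <- render_smear_image(smear_spec(width = 64, height = 64, n_clusters = 2,
                                      cluster_radius_range = c(6, 10),
                                      seed = 4))
  m1 <- hsv_mask(sm$image, filt)
  # blank out every non-masked pixel with an out-of-range color (black)
  img2 <- sm$image
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[m1 == 0L] <- 0
    img2[, , ch] <- plane
  }
  expect_identical(hsv_mask(img2, filt), m1)
})

test_that("tessellation retains exactly the tiles meeting the occupancy floor", {
  g <- tessellate(matrix(1L, 1024, 1024), 256, 0.1)
  expect_identical(nrow(g$origins), 16L)
  expect_true(all(g$occupancy == 1))
  expect_identical(nrow(tessellate(matrix(0L, 1024, 1024), 256, 0.1)$origins), 0L)
  expect_warning(tessellate(matrix(1L, 100, 100), 256), "smaller than one tile")

  # checkerboard of 128-px squares against a direct per-tile count
  blk <- matrix(0L, 512, 512)
  for (bi in 0:3) {
    for (bj in 0:3) {
      if ((bi + bj) %% 2 == 0) {
        blk[bi * 128 + 1:128, bj * 128 + 1:128] <- 1L
      }
    }
  }
  g2 <- tessellate(blk, 128, 0.4)
  ref_keep <- NULL
  for (y in seq(0, 384, by = 128)) {
    for (x in seq(0, 384, by = 128)) {
      frac <- sum(blk[y + 1:128, x + 1:128]) / 128^2
      if (frac >= 0.4) ref_keep <- rbind(ref_keep, c(x, y))
    }
  }
  expect_identical(nrow(g2$origins), nrow(ref_keep))
  expect_true(all(g2$origins == ref_keep[order(ref_keep[, 2], ref_keep[, 1]), ]))

  # coordinate convention: half-open tiles inside bounds, unique origins
  expect_true(all(g2$origins[, 1] + 128 <= 512))
  expect_true(all(g2$origins[, 2] + 128 <= 512))
  expect_false(any(duplicated(g2$origins)))
})

test_that("extract_bag features equal per-tile means from a reference loop", {
  filt <- default_hsv_filters("synthetic")
  sm <- render_smear_image(smear_spec(width = 96, height = 96, n_clusters = 4,
                                      cluster_radius_range = c(10, 16),
                                      seed = 9))
  bag <- extract_bag(sm$image, filt, stub_extractor(), min_occupancy = 0.05,
                     tile_size = 32, slide_id = "fixture")
  expect_s3_class(bag, "feature_bag")
  expect_identical(ncol(bag$features), 3L)
  for (i in seq_len(nrow(bag$coords))) {
    x <- bag$coords[i, 1]
    y <- bag$coords[i, 2]
    tile <- sm$image[(y + 1):(y + 32), (x + 1):(x + 32), , drop = FALSE]
    ref <- c(mean(tile[, , 1]), mean(tile[, , 2]), mean(tile[, , 3]))
    expect_equal(unname(bag$features[i, ]), ref, tolerance = 1e-12)
  }
  # a fully masked single tile yields a one-instance bag
  nucleus_center <- c(mean(filt$nucleus_range$h), mean(filt$nucleus_range$s),
                      mean(filt$nucleus_range$v))
  one <- uniform_image(32, 32, nucleus_center)
  b1 <- extract_bag(one, filt, stub_extractor(), tile_size = 32)
  expect_identical(nrow(b1$features), 1L)
  # empty grid errors with advice
  bg <- uniform_image(64, 64, c(40, 0.02, 0.97))
  expect_error(extract_bag(bg, filt, stub_extractor(), tile_size = 32),
               "min_occupancy")
})

test_that("bags round-trip bit-exactly through the HDF5 container", {
  set.seed(8)
  bag <- sample_bag(bag_spec(feature_dim = 6, bag_size_range = c(5, 5),
                             witness_rate = 0.5), 1, slide_id = "rt")
  path <- tempfile(fileext = ".h5")
  write_bag(bag, path)
  back <- read_bag(path)
  expect_identical(back$features, bag$features)
  expect_identical(back$coords, bag$coords)
  expect_identical(back$instance_truth, bag$instance_truth)
  expect_identical(back$bag_label, bag$bag_label)
  expect_identical(back$slide_id, bag$slide_id)
  expect_identical(back$stain, bag$stain)
  expect_identical(back$tile_size, bag$tile_size)
  unlink(path)

  # large bag: stored features identical to the source matrix
  set.seed(9)
  big <- sample_bag(bag_spec(feature_dim = 16, bag_size_range = c(1000, 1000),
                             witness_rate = 0.1), 1)
  p2 <- tempfile(fileext = ".h5")
  write_bag(big, p2)
  expect_identical(read_bag(p2)$features, big$features)
  unlink(p2)
})

test_that("schema violations name the missing dataset", {
  p <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(p)
  rhdf5::h5write(matrix(1, 2, 2), p, "features")
  rhdf5::h5closeAll()
  expect_error(read_bag(p), "coords")
  unlink(p)
  expect_error(read_bag(tempfile()), "no such file")
})

test_that("identical preprocessing inputs give identical stored datasets", {
  filt <- default_hsv_filters("synthetic")
  sm <- render_smear_image(smear_spec(width = 64, height = 64, n_clusters = 2,
                                      cluster_radius_range = c(6, 10),
                                      seed = 13))
  b1 <- extract_bag(sm$image, filt, stub_extractor(), min_occupancy = 0.05,
                    tile_size = 32)
  b2 <- extract_bag(sm$image, filt, stub_extractor(), min_occupancy = 0.05,
                    tile_size = 32)
  p1 <- tempfile(fileext = ".h5")
  p2 <- tempfile(fileext = ".h5")
  write_bag(b1, p1)
  write_bag(b2, p2)
  expect_identical(read_bag(p1)$features, read_bag(p2)$features)
  expect_identical(read_bag(p1)$coords, read_bag(p2)$coords)
  unlink(c(p1, p2))
})
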