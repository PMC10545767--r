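# Synthetic bag generator: MIL structure, witness counts, determinism,
# class separation.

test_that("every generated bag satisfies the MIL label assumption", {
  set.seed(1)
  spec <- bag_spec(feature_dim = 4, bag_size_range = c(3, 9),
                   witness_rate = 0.3, separation = 2)
  for (i in 1:1000) {
    label <- rbinom(1, 1, 0.5)
    b <- sample_bag(spec, label)
    expect_identical(b$bag_label, as.integer(label))
    expect_identical(b$bag_label, as.integer(any(b$instance_truth == 1L)))
    expect_true(all(is.finite(b$features)))
    if (label == 0) expect_true(all(b$instance_truth == 0L))
  }
  # vanishing witness rate still yields exactly one witness
  spec_lo <- bag_spec(feature_dim = 4, bag_size_range = c(10, 10),
                      witness_rate = 1e-9)
  for (i in 1:20) {
    expect_identical(sum(sample_bag(spec_lo, 1)$instance_truth), 1L)
  }
  expect_error(sample_bag(bag_spec(witness_rate = 0), 1), "witness_rate")
})

test_that("witness counts follow the max(1, Binomial(N, r)) law", {
  spec <- bag_spec(feature_dim = 8, bag_size_range = c(20, 20),
                   witness_rate = 0.3, seed = 7)
  set.seed(spec$seed)
  counts <- replicate(1e4, sum(sample_bag(spec, 1)$instance_truth))
  # exact pmf by enumeration: mass at 0 moves to 1
  pmf <- dbinom(0:20, 20, 0.3)
  expected <- c(pmf[1] + pmf[2], pmf[-(1:2)])
  names(expected) <- 1:20
  emp <- tabulate(counts, nbins = 20) / 1e4
  tol <- 4 * sqrt(expected * (1 - expected) / 1e4) + 1e-6
  expect_true(all(abs(emp - expected) < tol))
  expect_gte(min(counts), 1)
})

test_that("dataset sampling is deterministic and always yields both classes", {
  spec <- bag_spec(feature_dim = 5, bag_size_range = c(3, 6), seed = 123)
  d1 <- sample_dataset(spec, 100)
  d2 <- sample_dataset(spec, 100)
  expect_identical(d1, d2)
  labs <- vapply(d1, function(b) b$bag_label, integer(1))
  expect_true(all(c(0L, 1L) %in% labs))
  # default imbalance mirrors a 3:1 positive:negative cohort
  expect_identical(bag_spec()$pos_fraction, 0.75)
  # forced presence with an extreme fraction
  spec_hi <- bag_spec(feature_dim = 3, bag_size_range = c(2, 3),
                      pos_fraction = 0.999, seed = 5)
  labs_hi <- vapply(sample_dataset(spec_hi, 10), function(b) b$bag_label,
                    integer(1))
  expect_true(all(c(0L, 1L) %in% labs_hi))
  expect_error(sample_dataset(spec, 1), "n_bags")
})

test_that("class separation controls the single-instance Bayes error", {
  # closed-form LDA oracle for two isotropic Gaussians at distance d:
  # projecting onto the mean difference gives error pnorm(-d / (2 * sd))
  errors <- sapply(c(0, 2, 6), function(sep) {
    spec <- bag_spec(feature_dim = 10, bag_size_range = c(50, 50),
                     witness_rate = 0.5, separation = sep, seed = 42)
    set.seed(spec$seed)
    bags <- lapply(1:40, function(i) sample_bag(spec, 1))
    mu1 <- colMeans(do.call(rbind, lapply(bags, function(b) {
      b$features[b$instance_truth == 1, , drop = FALSE]
    })))
    # oracle direction: all-ones (the generator's displacement direction)
    dir <- rep(1 / sqrt(10), 10)
    mid <- sep / 2
    err <- mean(unlist(lapply(bags, function(b) {
      proj <- as.vector(b$features %*% dir)
      pred <- as.integer(proj > mid)
      pred != b$instance_truth
    })))
    c(err = err, closed = pnorm(-sep / 2))
  })
  expect_true(all(diff(errors["err", ]) < 0))
  expect_equal(errors["err", ], errors["closed", ], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("smear rendering is deterministic with a verifiable cell mask", {
  spec0 <- smear_spec(width = 96, height = 96, n_clusters = 0, seed = 3)
  r0 <- render_smear_image(spec0)
  expect_true(all(r0$mask == 0L))

  spec <- smear_spec(width = 128, height = 128, n_clusters = 3,
                     cluster_radius_range = c(8, 14), seed = 11)
  r1 <- render_smear_image(spec)
  r2 <- render_smear_image(spec)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$mask, r2$mask)

  # brute-force pixel loop over the returned disk geometry
  ref <- matrix(0L, 128, 128)
  for (i in 1:128) {
    for (j in 1:128) {
      for (k in seq_len(nrow(r1$clusters))) {
        if ((i - r1$clusters[k, "cy"])^2 + (j - r1$clusters[k, "cx"])^2 <=
              r1$clusters[k, "r"]^2) {
          ref[i, j] <- 1L
        }
      }
    }
  }
  expect_identical(r1$mask, ref)
  expect_identical(sum(r1$mask), sum(ref))
  # ink dots exist and do not overlap clusters
  expect_gte(nrow(r1$ink), 1)
})

test_that("feature_bag enforces the MIL consistency invariant", {
  x <- matrix(rnorm(6), 3, 2)
  co <- cbind(c(0L, 256L, 512L), 0L)
  expect_error(feature_bag(x, co, bag_label = 1, instance_truth = c(0, 0, 0)),
               "MIL label inconsistency")
  expect_error(feature_bag(x, co, bag_label = 0, instance_truth = c(0, 1, 0)),
               "MIL label inconsistency")
  x[1, 1] <- NA
  expect_error(feature_bag(x, co, bag_label = 0), "non-finite")
})
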