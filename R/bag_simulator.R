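# Synthetic feature-bag simulator.
#
# The simulator realizes the standard MIL assumption: a bag (one slide's set
# of tile feature vectors) is negative iff every instance is negative, and
# positive iff it contains at least one positive ("witness") instance.
# Instances live directly in feature space — negatives are drawn from an
# isotropic Gaussian N(mu0, noise_sd^2 I) and witnesses from N(mu1,
# noise_sd^2 I) with ||mu1 - mu0|| equal to `separation` — because the MIL
# heads consume pretrained-CNN feature vectors, not pixels; this lets every
# head be exercised independently of any feature extractor.

#' Specification of a synthetic MIL bag generator
#'
#' Defines the generative model for synthetic tile-feature bags. Negative
#' instances are drawn from an isotropic Gaussian; witness instances from a
#' second Gaussian whose mean is `separation` feature units away. A positive
#' bag contains `max(1, Binomial(N, witness_rate))` witnesses, so the MIL
#' existential assumption (at least one witness in every positive bag) holds
#' by construction. The default positive-bag fraction of 0.75 mirrors the
#' roughly 3:1 positive:negative slide imbalance typical of referral-center
#' pancreatic FNA cohorts.
#'
#' @param feature_dim Number of feature channels C per instance.
#' @param bag_size_range Integer interval `c(n_min, n_max)`; the bag size N
#'   is drawn uniformly from it.
#' @param witness_rate Expected fraction of witness instances within a
#'   positive bag, in `[0, 1]`; must be positive to sample positive bags.
#' @param separation Euclidean distance between the negative and witness
#'   class means, in feature units.
#' @param noise_sd Isotropic instance noise standard deviation.
#' @param pos_fraction Fraction of positive bags in a sampled dataset.
#' @param seed Optional integer seed making [sample_dataset()] deterministic.
#' @return An object of class `bag_spec`.
#' @seealso [sample_bag()], [sample_dataset()]
#' @examples
#' spec <- bag_spec(feature_dim = 8, bag_size_range = c(5, 10), seed = 1)
#' bags <- sample_dataset(spec, n_bags = 4)
#' sapply(bags, function(b) b$bag_label)
#' @export
bag_spec <- function(feature_dim = 50,
                     bag_size_range = c(20, 50),
                     witness_rate = 0.2,
                     separation = 6,
                     noise_sd = 1,
                     pos_fraction = 0.75,
                     seed = NULL) {
  stopifnot(is_count(feature_dim))
  if (length(bag_size_range) != 2L || !is_count(bag_size_range[1]) ||
      !is_count(bag_size_range[2]) || bag_size_range[1] > bag_size_range[2]) {
    stop("bag_size_range must be an integer interval c(n_min, n_max) with 1 <= n_min <= n_max")
  }
  stopifnot(
    witness_rate >= 0, witness_rate <= 1,
    separation >= 0, noise_sd > 0,
    pos_fraction > 0, pos_fraction < 1
  )
  structure(
    list(
      feature_dim = as.integer(feature_dim),
      bag_size_range = as.integer(bag_size_range),
      witness_rate = witness_rate,
      separation = separation,
      noise_sd = noise_sd,
      pos_fraction = pos_fraction,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "bag_spec"
  )
}

## Class means: mu0 at the origin, mu1 displaced by `separation` along the
## normalized all-ones direction.
bag_spec_means <- function(spec) {
  mu0 <- rep(0, spec$feature_dim)
  dir <- rep(1 / sqrt(spec$feature_dim), spec$feature_dim)
  list(mu0 = mu0, mu1 = mu0 + spec$separation * dir)
}

## Raster-grid tile coordinates (0-based, 256-pixel stride) so that
## explainability code paths run unchanged on synthetic bags.
synthetic_coords <- function(n, tile_size = 256L) {
  g <- max(1L, ceiling(sqrt(n)))
  i <- seq_len(n) - 1L
  cbind(x = (i %% g) * tile_size, y = (i %/% g) * tile_size)
}

#' Sample one synthetic feature bag
#'
#' Draws a bag of the requested label from a [bag_spec()] generative model
#' using the session RNG (seed beforehand, e.g. with `set.seed()`, for
#' reproducibility). Positive bags receive `max(1, Binomial(N,
#' witness_rate))` witness instances at random positions; `instance_truth`
#' records the witness mask.
#'
#' @param spec A [bag_spec()].
#' @param label Bag label, 0 (negative) or 1 (positive).
#' @param slide_id Identifier stored in the bag.
#' @return A [feature_bag()].
#' @examples
#' set.seed(1)
#' b <- sample_bag(bag_spec(feature_dim = 4, bag_size_range = c(5, 8)), label = 1)
#' sum(b$instance_truth) >= 1
#' @export
sample_bag <- function(spec, label, slide_id = "synthetic") {
  stopifnot(inherits(spec, "bag_spec"), label %in% c(0, 1))
  if (label == 1 && spec$witness_rate <= 0) {
    stop("cannot sample a positive bag when witness_rate is 0")
  }
  n <- if (spec$bag_size_range[1] == spec$bag_size_range[2]) {
    spec$bag_size_range[1]
  } else {
    sample(spec$bag_size_range[1]:spec$bag_size_range[2], 1L)
  }
  mu <- bag_spec_means(spec)
  x <- matrix(stats::rnorm(n * spec$feature_dim, sd = spec$noise_sd),
              n, spec$feature_dim)
  x <- sweep(x, 2L, mu$mu0, "+")
  truth <- integer(n)
  if (label == 1) {
    n_wit <- max(1L, stats::rbinom(1L, n, spec$witness_rate))
    idx <- if (n_wit >= n) seq_len(n) else sample.int(n, n_wit)
    shift <- matrix(mu$mu1 - mu$mu0, length(idx), spec$feature_dim, byrow = TRUE)
    x[idx, ] <- x[idx, , drop = FALSE] + shift
    truth[idx] <- 1L
  }
  feature_bag(
    features = x,
    coords = synthetic_coords(n),
    bag_label = label,
    instance_truth = truth,
    slide_id = slide_id,
    stain = "synthetic"
  )
}

#' Sample a synthetic MIL dataset
#'
#' Draws `n_bags` bags with labels `Bernoulli(pos_fraction)`. If either class
#' is absent after the draw, the last bag is re-labelled to the missing class
#' so that both classes are always represented. Deterministic when
#' `spec$seed` is set.
#'
#' @param spec A [bag_spec()].
#' @param n_bags Number of bags, at least 2.
#' @return A list of [feature_bag()] objects.
#' @export
sample_dataset <- function(spec, n_bags) {
  stopifnot(inherits(spec, "bag_spec"))
  if (!is_count(n_bags, min = 2L)) {
    stop("n_bags must be an integer >= 2")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  labels <- stats::rbinom(n_bags, 1L, spec$pos_fraction)
  for (cls in c(0L, 1L)) {
    if (!any(labels == cls)) labels[n_bags] <- cls
  }
  lapply(seq_len(n_bags), function(i) {
    sample_bag(spec, labels[i], slide_id = sprintf("bag_%03d", i))
  })
}

#' Construct and validate a tile feature bag
#'
#' The unit of training and inference: one slide's tile feature matrix with
#' tile coordinates and the slide-level label. Enforces the MIL label
#' consistency invariant when instance-level ground truth is available
#' (simulator only): a bag is positive iff at least one instance is a
#' witness.
#'
#' @param features Numeric matrix N x C of per-tile features; must be finite.
#' @param coords Integer matrix N x 2 of 0-based tile top-left `(x, y)` pixel
#'   coordinates.
#' @param bag_label 0 (negative for carcinoma) or 1 (positive).
#' @param instance_truth Optional binary vector of length N marking witness
#'   instances.
#' @param slide_id Slide identifier.
#' @param stain One of `"diffquik"`, `"pap"`, `"synthetic"`.
#' @param tile_size Tile edge length in pixels.
#' @param extractor_name Name of the feature extractor that produced
#'   `features`.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(features, coords, bag_label,
                        instance_truth = NULL,
                        slide_id = "slide", stain = "synthetic",
                        tile_size = 256L, extractor_name = "unknown") {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  if (nrow(features) < 1L) stop("a bag must contain at least one instance")
  stopifnot_finite(features, "features")
  if (!identical(dim(coords), c(nrow(features), 2L)) &&
      !(nrow(coords) == nrow(features) && ncol(coords) == 2L)) {
    stop("coords must be an N x 2 matrix matching features")
  }
  if (!bag_label %in% c(0, 1)) stop("bag_label must be 0 or 1")
  stain <- match.arg(stain, c("diffquik", "pap", "synthetic"))
  if (!is.null(instance_truth)) {
    instance_truth <- as.integer(instance_truth)
    if (length(instance_truth) != nrow(features) ||
        !all(instance_truth %in% c(0L, 1L))) {
      stop("instance_truth must be a binary vector of length N")
    }
    if ((bag_label == 1) != any(instance_truth == 1L)) {
      stop("MIL label inconsistency: bag_label must equal OR over instance_truth")
    }
  }
  structure(
    list(
      features = features,
      coords = matrix(as.integer(coords), nrow(coords), 2L,
                      dimnames = list(NULL, c("x", "y"))),
      bag_label = as.integer(bag_label),
      instance_truth = instance_truth,
      slide_id = as.character(slide_id),
      stain = stain,
      tile_size = as.integer(tile_size),
      extractor_name = as.character(extractor_name)
    ),
    class = "feature_bag"
  )
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf(
    "<feature_bag> %s: %d instances x %d features, label %d (%s stain)\n",
    x$slide_id, nrow(x$features), ncol(x$features), x$bag_label, x$stain
  ))
  if (!is.null(x$instance_truth)) {
    cat(sprintf("  witnesses: %d\n", sum(x$instance_truth)))
  }
  invisible(x)
}
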