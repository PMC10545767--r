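# Shared instance encoder.
#
# Every MIL head first embeds the (pretrained-backbone) tile features into a
# lower-dimensional space with a simple encoder: fully-connected layer,
# dropout, group normalization, Mish activation.

#' Create encoder parameters
#'
#' Initializes the shared instance encoder: a fully-connected layer followed
#' by dropout, group normalization and a Mish activation. Weights are drawn
#' from the session RNG (He-scaled Gaussians); seed beforehand for
#' reproducibility.
#'
#' @param input_dim Input feature dimensionality C_in.
#' @param embed_dim Embedding dimensionality C (default 64); must be
#'   divisible by `groupnorm_groups`.
#' @param dropout_rate Dropout probability applied in training mode only
#'   (default 0.25).
#' @param groupnorm_groups Number of group-normalization groups (default 8).
#' @return A list of encoder parameters (class `encoder_params`).
#' @export
encoder_params <- function(input_dim, embed_dim = 64L, dropout_rate = 0.25,
                           groupnorm_groups = 8L) {
  stopifnot(is_count(input_dim), is_count(embed_dim),
            dropout_rate >= 0, dropout_rate < 1,
            is_count(groupnorm_groups))
  if (embed_dim %% groupnorm_groups != 0L) {
    stop("embed_dim must be divisible by groupnorm_groups")
  }
  structure(
    list(
      W = matrix(stats::rnorm(input_dim * embed_dim, sd = sqrt(2 / input_dim)),
                 input_dim, embed_dim),
      b = rep(0, embed_dim),
      gamma = rep(1, embed_dim),
      beta = rep(0, embed_dim),
      dropout_rate = dropout_rate,
      groups = as.integer(groupnorm_groups)
    ),
    class = "encoder_params"
  )
}

encoder_forward <- function(x, ep, train = FALSE) {
  fc <- fc_forward(x, ep$W, ep$b)
  dr <- dropout_forward(fc$y, ep$dropout_rate, train)
  gn <- gn_forward(dr$y, ep$gamma, ep$beta, ep$groups)
  z <- mish(gn$y)
  list(z = z, fc = fc, dr = dr, gn = gn, gn_y = gn$y)
}

## Returns gradients named dW, db, dgamma, dbeta plus dx.
encoder_backward <- function(dz, cache, ep) {
  dgn_y <- dz * mish_grad(cache$gn_y)
  gnb <- gn_backward(dgn_y, cache$gn, ep$gamma)
  ddr <- dropout_backward(gnb$dx, cache$dr)
  fcb <- fc_backward(ddr, cache$fc, ep$W)
  list(dW = fcb$dW, db = fcb$db, dgamma = gnb$dgamma, dbeta = gnb$dbeta,
       dx = fcb$dx)
}

#' Encode a bag's instance features
#'
#' Applies the shared encoder `Mish(GroupNorm(Dropout(FC(x))))` to each
#' instance. Inference mode (`train_mode = FALSE`) disables dropout and is
#' deterministic.
#'
#' @param bag_features N x C_in numeric matrix.
#' @param params An [encoder_params()].
#' @param train_mode Apply dropout (training) or not (inference).
#' @return N x embed_dim matrix of embedded instances.
#' @export
encode <- function(bag_features, params, train_mode = FALSE) {
  stopifnot(inherits(params, "encoder_params"))
  bag_features <- as.matrix(bag_features)
  stopifnot_finite(bag_features, "bag_features")
  if (ncol(bag_features) != nrow(params$W)) {
    stop(sprintf("input_dim mismatch: features have %d columns, encoder expects %d",
                 ncol(bag_features), nrow(params$W)))
  }
  encoder_forward(bag_features, params, train = train_mode)$z
}
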