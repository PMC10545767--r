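# Building-block layers with explicit forward/backward passes.
#
# The MIL heads in this package are small multilayer perceptrons over tile
# feature vectors. No deep-learning framework is assumed: each layer exposes
# a forward function returning (output, cache) and a backward function that
# consumes the upstream gradient and the cache. All backward passes are
# validated against central finite differences in the test suite.

## Fully connected layer: Y = X W + b  (X: N x in, W: in x out, b: out)
fc_forward <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = y, x = x)
}

fc_backward <- function(dy, cache, W) {
  list(
    dx = dy %*% t(W),
    dW = crossprod(cache$x, dy),
    db = colSums(dy)
  )
}

## Group normalization over the channel axis, per instance (row).
## Channels are split into `groups` contiguous groups; mean/variance are the
## biased per-(row, group) statistics; gamma/beta are per-channel.
gn_forward <- function(x, gamma, beta, groups, eps = 1e-5) {
  c <- ncol(x)
  if (c %% groups != 0L) {
    stop("number of channels must be divisible by the number of groups")
  }
  gs <- c %/% groups
  grp <- rep(seq_len(groups), each = gs)
  # per-row, per-group statistics via a channel->group indicator matmul
  ind <- diag(groups)[grp, , drop = FALSE] / gs      # c x groups
  mu <- x %*% ind                                    # n x groups
  var <- (x * x) %*% ind - mu^2
  inv_sd <- 1 / sqrt(var + eps)
  xhat <- (x - mu[, grp, drop = FALSE]) * inv_sd[, grp, drop = FALSE]
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(y = y, xhat = xhat, inv_sd = inv_sd, grp = grp, groups = groups,
       ind = ind)
}

gn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  grp <- cache$grp
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = nrow(dy))
  m1 <- (dxhat %*% cache$ind)[, grp, drop = FALSE]         # group mean of dxhat
  m2 <- ((dxhat * xhat) %*% cache$ind)[, grp, drop = FALSE]
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd[, grp, drop = FALSE]
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## Inverted dropout; identity in inference mode. Uses the session RNG.
dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(x), 1L, keep), nrow(x), ncol(x)) / keep
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## --- Adam optimizer with classic L2 weight decay -------------------------

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1, beta2,
                      weight_decay = 0, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    # keep vector parameters vectors (compiled kernels return n x 1 matrices)
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## --- OneCycle learning-rate schedule with cosine annealing ----------------
##
## Linear warm-up in cosine shape from lr_max/div to lr_max over pct_start of
## the run, then cosine annealing down to lr_max/final_div. Momentum (Adam
## beta1) is cycled inversely: high at low learning rate, low at the peak.
onecycle_schedule <- function(step, total_steps, lr_max,
                              pct_start = 0.3, div_factor = 25,
                              final_div_factor = 1e4,
                              mom_max = 0.95, mom_min = 0.85) {
  step <- min(step, total_steps)
  warm <- max(1, round(total_steps * pct_start))
  cosine_interp <- function(a, b, pct) b + (a - b) * (1 + cos(pi * pct)) / 2
  if (step <= warm) {
    pct <- step / warm
    lr <- cosine_interp(lr_max / div_factor, lr_max, pct)
    mom <- cosine_interp(mom_max, mom_min, pct)
  } else {
    pct <- (step - warm) / max(1, total_steps - warm)
    lr <- cosine_interp(lr_max, lr_max / final_div_factor, pct)
    mom <- cosine_interp(mom_min, mom_max, pct)
  }
  list(lr = lr, momentum = mom)
}
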