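# Shared fixtures and independent reference implementations.
#
# The reference implementations here are deliberately written as plain
# scalar loops over the published formulas, independent of the package's
# vectorized/compiled code paths, so they can serve as oracles.

## A tiny deterministic bag.
tiny_bag <- function(n = 5, c = 4, label = 1L, seed = 99) {
  set.seed(seed)
  spec <- bag_spec(feature_dim = c, bag_size_range = c(n, n),
                   witness_rate = 0.4, separation = 3)
  sample_bag(spec, label)
}

tiny_config <- function(...) {
  mil_config(embed_dim = 8, attn_dim = 4, groups = 2, dropout = 0,
             clam_B = 2, ...)
}

## Brute-force InfoNCE: triple loop over anchors and pairs, straight from
## the loss definition.
reference_infonce <- function(v_f, v_b, tau = 0.07) {
  X <- rbind(v_f, v_b)
  n <- nrow(v_f)
  m <- 2 * n
  U <- t(apply(X, 1, function(r) r / max(sqrt(sum(r^2)), 1e-12)))
  total <- 0
  for (i in seq_len(m)) {
    grp_i <- i <= n
    num <- 0
    den <- 0
    for (j in seq_len(m)) {
      if (j == i) next
      s <- exp(sum(U[i, ] * U[j, ]) / tau)
      if ((j <= n) == grp_i) num <- num + s
      den <- den + s
    }
    total <- total - log(num / den)
  }
  total / m
}

## Scalar-loop attention pooling, term by term from the formula.
reference_attention <- function(H, w, V) {
  K <- nrow(H)
  e <- numeric(K)
  for (k in seq_len(K)) {
    hv <- numeric(length(w))
    for (l in seq_along(w)) {
      hv[l] <- tanh(sum(V[l, ] * H[k, ]))
    }
    e[k] <- sum(w * hv)
  }
  a <- exp(e - max(e))
  a <- a / sum(a)
  z <- numeric(ncol(H))
  for (k in seq_len(K)) z <- z + a[k] * H[k, ]
  list(z = z, a = a)
}

## Per-pixel HSV range check mirroring the documented mask definition.
reference_hsv_mask <- function(image, filter) {
  h <- dim(image)[1]
  w <- dim(image)[2]
  out <- matrix(0L, h, w)
  in_iv <- function(x, iv) x >= iv[1] & x <= iv[2]
  in_hue <- function(x, iv) {
    if (iv[1] <= iv[2]) x >= iv[1] & x <= iv[2] else x >= iv[1] | x <= iv[2]
  }
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      hsv <- grDevices::rgb2hsv(image[i, j, 1], image[i, j, 2],
                                image[i, j, 3], maxColorValue = 1)
      hh <- hsv[1] * 360
      ss <- hsv[2]
      vv <- hsv[3]
      ok <- FALSE
      for (rg in list(filter$nucleus_range, filter$cytoplasm_range)) {
        if (in_hue(hh, rg$h) && in_iv(ss, rg$s) && in_iv(vv, rg$v)) ok <- TRUE
      }
      out[i, j] <- as.integer(ok)
    }
  }
  out
}

## Central finite differences of a scalar function of one parameter list
## entry; used to validate analytic gradients.
fd_grad <- function(loss_fn, params, nm, idx, eps = 1e-6) {
  pp <- params
  pp[[nm]][idx] <- pp[[nm]][idx] + eps
  lp <- loss_fn(pp)
  pm <- params
  pm[[nm]][idx] <- pm[[nm]][idx] - eps
  lm <- loss_fn(pm)
  (lp - lm) / (2 * eps)
}

## Per-bag precision-at-witness-count of MIPCL positive-class instance
## probabilities over the positive bags in `bags`.
witness_precision <- function(fit, bags) {
  prec <- c()
  for (b in bags) {
    if (b$bag_label != 1 || is.null(b$instance_truth)) next
    sc <- predict(fit, b, type = "instance")[[1]]
    w <- sum(b$instance_truth)
    top <- order(-sc$prob_positive)[seq_len(w)]
    prec <- c(prec, mean(b$instance_truth[top] == 1))
  }
  prec
}
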