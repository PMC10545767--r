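# CLAM: clustering-constrained attention MIL.
#
# Extends ABMIL with (a) a gated attention module, a_k proportional to
# exp(w' (tanh(V h_k') . sigmoid(U h_k'))), and (b) an instance-level
# clustering regularizer: the B instances with the highest attention receive
# a positive cluster pseudo-label, the B with the lowest a negative one, and
# a shared 2-class instance classifier is trained on them with a smooth
# top-1 SVM loss. The total loss is bag_weight * CE_bag +
# (1 - bag_weight) * SVM_instances.

clam_init <- function(input_dim, cfg) {
  enc <- encoder_params(input_dim, cfg$embed_dim, cfg$dropout, cfg$groups)
  C <- cfg$embed_dim
  L <- cfg$attn_dim
  list(
    enc_W = enc$W, enc_b = enc$b, enc_gamma = enc$gamma, enc_beta = enc$beta,
    att_V = matrix(stats::rnorm(L * C, sd = sqrt(1 / C)), L, C),
    att_U = matrix(stats::rnorm(L * C, sd = sqrt(1 / C)), L, C),
    att_w = stats::rnorm(L, sd = sqrt(1 / L)),
    cls_W = matrix(stats::rnorm(C * 2L, sd = sqrt(1 / C)), C, 2L),
    cls_b = rep(0, 2L),
    inst_W = matrix(stats::rnorm(C * 2L, sd = sqrt(1 / C)), C, 2L),
    inst_b = rep(0, 2L)
  )
}

clam_views <- function(params, cfg) {
  list(
    enc = structure(list(W = params$enc_W, b = params$enc_b,
                         gamma = params$enc_gamma, beta = params$enc_beta,
                         dropout_rate = cfg$dropout, groups = cfg$groups),
                    class = "encoder_params"),
    att = list(w = params$att_w, V = params$att_V, U = params$att_U),
    cls = list(W = params$cls_W, b = params$cls_b),
    inst = list(W = params$inst_W, b = params$inst_b)
  )
}

gated_attention_forward <- function(H, w, V, U) {
  Tm <- tanh(H %*% t(V))
  Gm <- sigmoid(H %*% t(U))
  e <- as.vector((Tm * Gm) %*% w)
  a <- softmax_vec(e)
  z <- as.vector(crossprod(H, a))
  list(z = z, a = a, Tm = Tm, Gm = Gm, e = e)
}

#' Attention-derived cluster pseudo-labels
#'
#' Returns the indices of the `B` instances with the highest attention
#' (positive cluster) and the `B` with the lowest (negative cluster). When
#' the bag has fewer than `2B` instances, `B` is reduced to `floor(K / 2)`;
#' a single-instance bag yields empty sets with a warning (the instance
#' loss is then skipped). Ties are broken by the lowest index.
#'
#' @param a Length-K attention weight vector.
#' @param B Pseudo-label count per pole (default 8).
#' @return List with integer `pos_idx` and `neg_idx` (1-based).
#' @export
clam_pseudo_labels <- function(a, B = 8L) {
  stopifnot(length(a) >= 1L, is_count(B))
  K <- length(a)
  B_eff <- min(B, K %/% 2L)
  if (B_eff < 1L) {
    warning("bag has fewer than 2 instances; instance clustering loss skipped")
    return(list(pos_idx = integer(0), neg_idx = integer(0)))
  }
  ord_desc <- order(-a, seq_along(a))
  ord_asc <- order(a, seq_along(a))
  list(pos_idx = as.integer(ord_desc[seq_len(B_eff)]),
       neg_idx = as.integer(ord_asc[seq_len(B_eff)]))
}

#' Smooth top-1 multiclass SVM loss
#'
#' Log-sum-exp smoothed multiclass hinge:
#' `L = smoothing * log(sum_c exp((margin * 1[c != y] + s_c) / smoothing)) - s_y`.
#' With `smoothing -> 0` this recovers the hard top-1 margin loss
#' `max_c(margin * 1[c != y] + s_c) - s_y`.
#'
#' @param logits Score vector `s` over classes.
#' @param true_class Integer class in `{0, 1, ...}`.
#' @param margin Margin added to every wrong class (default 1).
#' @param smoothing Temperature of the log-sum-exp smoothing (default 1).
#' @return Scalar loss (non-negative).
#' @export
smooth_top1_svm_loss <- function(logits, true_class, margin = 1, smoothing = 1) {
  stopifnot(smoothing > 0, margin >= 0,
            true_class %in% (seq_along(logits) - 1L))
  delta <- rep(margin, length(logits))
  delta[true_class + 1L] <- 0
  z <- (delta + logits) / smoothing
  zmax <- max(z)
  smoothing * (zmax + log(sum(exp(z - zmax)))) - logits[true_class + 1L]
}

smooth_top1_svm_grad <- function(logits, true_class, margin = 1, smoothing = 1) {
  delta <- rep(margin, length(logits))
  delta[true_class + 1L] <- 0
  p <- softmax_vec((delta + logits) / smoothing)
  p[true_class + 1L] <- p[true_class + 1L] - 1
  p
}

#' Combine CLAM bag and instance losses
#'
#' @param bag_ce Bag-level cross-entropy.
#' @param instance_svm Instance-level smooth top-1 SVM loss.
#' @param bag_weight Weight of the bag term (default 0.7).
#' @return `bag_weight * bag_ce + (1 - bag_weight) * instance_svm`.
#' @export
clam_loss <- function(bag_ce, instance_svm, bag_weight = 0.7) {
  stopifnot(bag_ce >= 0, instance_svm >= 0,
            bag_weight > 0, bag_weight <= 1)
  bag_weight * bag_ce + (1 - bag_weight) * instance_svm
}

#' CLAM forward pass on one bag
#'
#' Encode, gated-attention pool, classify; additionally pseudo-label the
#' extreme-attention instances and score them with the instance classifier
#' under the smooth top-1 SVM loss.
#'
#' @inheritParams abmil_forward
#' @return List with `bag_logits`, `bag_probs`, `loss` (`l_bag`,
#'   `l_instances`, `l_total`), `attention`, `pseudo` (pseudo-label index
#'   sets) and an internal `cache`.
#' @export
clam_forward <- function(bag, params, config, train_mode = FALSE) {
  stopifnot(inherits(bag, "feature_bag"))
  v <- clam_views(params, config)
  enc <- encoder_forward(bag$features, v$enc, train = train_mode)
  H <- enc$z
  att <- gated_attention_forward(H, v$att$w, v$att$V, v$att$U)
  logits <- as.vector(att$z %*% v$cls$W) + v$cls$b
  l_bag <- cross_entropy(logits, bag$bag_label)
  pseudo <- if (nrow(H) >= 2L) {
    clam_pseudo_labels(att$a, config$clam_B)
  } else {
    list(pos_idx = integer(0), neg_idx = integer(0))
  }
  lab_idx <- c(pseudo$pos_idx, pseudo$neg_idx)
  lab_cls <- c(rep(1L, length(pseudo$pos_idx)), rep(0L, length(pseudo$neg_idx)))
  inst_logits <- NULL
  l_inst <- 0
  if (length(lab_idx) > 0L) {
    inst_logits <- sweep(H[lab_idx, , drop = FALSE] %*% v$inst$W, 2L,
                         v$inst$b, "+")
    l_inst <- mean(vapply(seq_along(lab_idx), function(j) {
      smooth_top1_svm_loss(inst_logits[j, ], lab_cls[j],
                           config$svm_margin, config$svm_smoothing)
    }, numeric(1)))
  }
  l_total <- if (length(lab_idx) > 0L) {
    clam_loss(l_bag, l_inst, config$clam_bag_weight)
  } else {
    l_bag
  }
  list(
    bag_logits = logits,
    bag_probs = softmax_vec(logits),
    loss = list(l_bag = l_bag, l_instances = l_inst, l_total = l_total),
    attention = att$a,
    pseudo = pseudo,
    cache = list(enc = enc, att = att, logits = logits, lab_idx = lab_idx,
                 lab_cls = lab_cls, inst_logits = inst_logits)
  )
}

clam_backward <- function(fw, params, config, bag) {
  ca <- fw$cache
  v <- clam_views(params, config)
  H <- ca$enc$z
  has_inst <- length(ca$lab_idx) > 0L
  w_bag <- if (has_inst) config$clam_bag_weight else 1
  w_inst <- 1 - config$clam_bag_weight

  dlogits <- w_bag * cross_entropy_grad(ca$logits, bag$bag_label)
  dcls_W <- outer(ca$att$z, dlogits)
  dcls_b <- dlogits
  dz <- as.vector(v$cls$W %*% dlogits)
  da <- as.vector(H %*% dz)

  # gated attention backward
  att <- ca$att
  de <- att$a * (da - sum(att$a * da))
  dTG <- outer(de, v$att$w)
  dw <- as.vector(crossprod(att$Tm * att$Gm, de))
  dT <- dTG * att$Gm
  dG <- dTG * att$Tm
  dpre_t <- dT * (1 - att$Tm^2)
  dpre_g <- dG * att$Gm * (1 - att$Gm)
  dV <- crossprod(dpre_t, H)
  dU <- crossprod(dpre_g, H)
  dH <- outer(att$a, dz) + dpre_t %*% v$att$V + dpre_g %*% v$att$U

  dinst_W <- v$inst$W * 0
  dinst_b <- v$inst$b * 0
  if (has_inst) {
    n_lab <- length(ca$lab_idx)
    dinst_logits <- t(vapply(seq_len(n_lab), function(j) {
      smooth_top1_svm_grad(ca$inst_logits[j, ], ca$lab_cls[j],
                           config$svm_margin, config$svm_smoothing)
    }, numeric(2))) * (w_inst / n_lab)
    Hlab <- H[ca$lab_idx, , drop = FALSE]
    dinst_W <- crossprod(Hlab, dinst_logits)
    dinst_b <- colSums(dinst_logits)
    dH[ca$lab_idx, ] <- dH[ca$lab_idx, , drop = FALSE] +
      dinst_logits %*% t(v$inst$W)
  }

  encb <- encoder_backward(dH, ca$enc, v$enc)
  list(
    enc_W = encb$dW, enc_b = encb$db,
    enc_gamma = encb$dgamma, enc_beta = encb$dbeta,
    att_V = dV, att_U = dU, att_w = dw,
    cls_W = dcls_W, cls_b = dcls_b,
    inst_W = dinst_W, inst_b = dinst_b
  )
}
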