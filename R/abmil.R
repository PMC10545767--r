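# ABMIL: attention-based multiple-instance pooling.
#
# The bag representation is the attention-weighted average of the encoded
# instances, z = sum_k a_k h_k with a_k = softmax_k(w' tanh(V h_k')); the
# attention weights are normalized to sum to one so the pooled
# representation is invariant to bag size. A linear classifier over z gives
# the bag logits; cross-entropy is the training loss.

abmil_init <- function(input_dim, cfg) {
  enc <- encoder_params(input_dim, cfg$embed_dim, cfg$dropout, cfg$groups)
  C <- cfg$embed_dim
  L <- cfg$attn_dim
  list(
    enc_W = enc$W, enc_b = enc$b, enc_gamma = enc$gamma, enc_beta = enc$beta,
    att_V = matrix(stats::rnorm(L * C, sd = sqrt(1 / C)), L, C),
    att_w = stats::rnorm(L, sd = sqrt(1 / L)),
    cls_W = matrix(stats::rnorm(C * 2L, sd = sqrt(1 / C)), C, 2L),
    cls_b = rep(0, 2L)
  )
}

abmil_views <- function(params, cfg) {
  list(
    enc = structure(list(W = params$enc_W, b = params$enc_b,
                         gamma = params$enc_gamma, beta = params$enc_beta,
                         dropout_rate = cfg$dropout, groups = cfg$groups),
                    class = "encoder_params"),
    att = list(w = params$att_w, V = params$att_V),
    cls = list(W = params$cls_W, b = params$cls_b)
  )
}

attention_forward <- function(H, w, V) {
  Tm <- tanh(H %*% t(V))               # K x L
  e <- as.vector(Tm %*% w)
  a <- softmax_vec(e)
  z <- as.vector(crossprod(H, a))
  list(z = z, a = a, Tm = Tm, e = e)
}

#' Attention-based MIL pooling
#'
#' Computes `a_k = softmax_k(w' tanh(V h_k'))` and the pooled bag
#' representation `z = sum_k a_k h_k`. The attention weights always sum to
#' one.
#'
#' @param H K x M matrix of instance embeddings (rows `h_k`).
#' @param params List with `w` (length L) and `V` (L x M).
#' @return List with `z` (length M) and `a` (length K).
#' @export
abmil_attention_pool <- function(H, params) {
  H <- as.matrix(H)
  stopifnot(nrow(H) >= 1L, length(params$w) == nrow(params$V),
            ncol(params$V) == ncol(H))
  fw <- attention_forward(H, params$w, params$V)
  list(z = fw$z, a = fw$a)
}

#' ABMIL forward pass on one bag
#'
#' Encode, attention-pool, classify. Cross-entropy against the bag label is
#' the training loss.
#'
#' @param bag A [feature_bag()].
#' @param params Parameter list from the model initializer (see
#'   [mil_fit()]).
#' @param config A [mil_config()].
#' @param train_mode Apply dropout.
#' @return List with `bag_logits`, `bag_probs`, `loss` (`l_total` =
#'   `l_bag`), `attention` (per-instance weights) and an internal `cache`.
#' @export
abmil_forward <- function(bag, params, config, train_mode = FALSE) {
  stopifnot(inherits(bag, "feature_bag"))
  v <- abmil_views(params, config)
  enc <- encoder_forward(bag$features, v$enc, train = train_mode)
  att <- attention_forward(enc$z, v$att$w, v$att$V)
  logits <- as.vector(att$z %*% v$cls$W) + v$cls$b
  l_bag <- cross_entropy(logits, bag$bag_label)
  list(
    bag_logits = logits,
    bag_probs = softmax_vec(logits),
    loss = list(l_bag = l_bag, l_total = l_bag),
    attention = att$a,
    cache = list(enc = enc, att = att, logits = logits)
  )
}

## Backward through softmax attention shared by ABMIL and (gated) CLAM.
## Returns dH plus the attention parameter gradients.
attention_backward <- function(da, dz, att, H, w, V) {
  de <- att$a * (da - sum(att$a * da))
  dTm <- outer(de, w)
  dw <- as.vector(crossprod(att$Tm, de))
  dpre <- dTm * (1 - att$Tm^2)
  dV <- crossprod(dpre, H)
  dH <- outer(att$a, dz) + dpre %*% V
  list(dH = dH, dw = dw, dV = dV)
}

abmil_backward <- function(fw, params, config, bag) {
  ca <- fw$cache
  v <- abmil_views(params, config)
  H <- ca$enc$z
  dlogits <- cross_entropy_grad(ca$logits, bag$bag_label)
  dcls_W <- outer(ca$att$z, dlogits)
  dcls_b <- dlogits
  dz <- as.vector(v$cls$W %*% dlogits)
  da <- as.vector(H %*% dz)
  attb <- attention_backward(da, dz, ca$att, H, v$att$w, v$att$V)
  encb <- encoder_backward(attb$dH, ca$enc, v$enc)
  list(
    enc_W = encb$dW, enc_b = encb$db,
    enc_gamma = encb$dgamma, enc_beta = encb$dbeta,
    att_V = attb$dV, att_w = attb$dw,
    cls_W = dcls_W, cls_b = dcls_b
  )
}
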