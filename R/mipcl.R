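# MIPCL: multiple-instance learning with contrastive instance disentangling.
#
# Pipeline per bag (N encoded instances Z, embedding width C):
#   1. a disentangler head phi predicts one class-agnostic foreground
#      activation map P_i in (0,1)^C per instance (a per-channel gate),
#      splitting each embedding into a foreground part v_f = P (x) Z and
#      background part v_b = (1-P) (x) Z (so v_f + v_b = Z exactly);
#   2. foreground and background sets are contrasted with an InfoNCE loss
#      (temperature 0.07) over L2-normalized embeddings;
#   3. the activated instances A = Z (x) P = v_f are scored by the linear
#      bag classifier under sum pooling, and Grad-CAM — pooled gradients
#      alpha^c_k of the bag class score w.r.t. A, linearly recombined and
#      ReLU'd — yields per-instance, per-class CAM logits;
#   4. row-wise Softmax of the CAM logits gives instance class
#      probabilities; instances whose probability exceeds delta0 (negative
#      class) or delta1 (positive class), default 0.85, are selected;
#   5. the selected foreground instances are pooled class-wise, weighted by
#      their Softmax probabilities, and classified; cross-entropy against
#      the bag label gives the bag loss. Total loss is the plain sum of the
#      instance-contrast and bag losses (optionally the convex combination
#      (1-beta) * L_instances + beta * L_bag).
#
# The bag class score used for Grad-CAM comes from a preliminary sum-pooled
# pass over ALL activated instances; the selected instances are then
# re-pooled for the final classification — this resolves the circularity
# between selection (needs class scores) and the bag score (needs a pooled
# set). Before the CAM probabilities saturate past the thresholds the
# pooling set falls back to the whole bag, so early training behaves like
# probability-weighted mean-pooling MIL rather than starving the bag loss
# on arbitrary champions.

#' Create disentangler parameters
#'
#' The disentangler is a fully-connected layer, a group-normalization layer
#' and a sigmoid head producing one class-agnostic foreground activation
#' map per instance: a per-channel gate `P_i` in `(0, 1)^C` that routes
#' each part of the embedding to the foreground (`P`) or background
#' (`1 - P`). A per-channel map — rather than a single scalar per
#' instance — is what makes the foreground/background contrast
#' non-degenerate: under L2 normalization a scalar gate would leave both
#' halves pointing in the identical direction `Z_i / |Z_i|`, making the
#' InfoNCE term blind to the gate.
#'
#' @param embed_dim Embedding dimensionality C.
#' @param groupnorm_groups Group-normalization groups.
#' @return A list of parameters (class `disentangler_params`).
#' @export
disentangler_params <- function(embed_dim, groupnorm_groups = 8L) {
  stopifnot(is_count(embed_dim), is_count(groupnorm_groups),
            embed_dim %% groupnorm_groups == 0L)
  structure(
    list(
      W = matrix(stats::rnorm(embed_dim^2, sd = sqrt(2 / embed_dim)),
                 embed_dim, embed_dim),
      b = rep(0, embed_dim),
      gamma = rep(1, embed_dim),
      beta = rep(0, embed_dim),
      groups = as.integer(groupnorm_groups)
    ),
    class = "disentangler_params"
  )
}

disentangler_forward <- function(z, dp) {
  fc <- fc_forward(z, dp$W, dp$b)
  gn <- gn_forward(fc$y, dp$gamma, dp$beta, dp$groups)
  P <- sigmoid(gn$y)
  list(P = P, v_f = z * P, v_b = z * (1 - P),
       fc = fc, gn = gn, z = z)
}

#' Disentangle encoded instances into foreground and background
#'
#' Computes the foreground activation map `P = phi(GN(FC(Z)))` (an N x C
#' matrix of per-channel gates in `(0, 1)`) and splits each embedding into
#' `v_f = P * Z` and `v_b = (1 - P) * Z`, so that `v_f + v_b = Z` holds
#' exactly.
#'
#' @param Z N x C matrix of encoded instances.
#' @param params A [disentangler_params()].
#' @return List with `P`, `v_f`, `v_b` (all N x C).
#' @export
disentangle <- function(Z, params) {
  stopifnot(inherits(params, "disentangler_params"))
  Z <- as.matrix(Z)
  stopifnot_finite(Z, "Z")
  fw <- disentangler_forward(Z, params)
  list(P = fw$P, v_f = fw$v_f, v_b = fw$v_b)
}

## --- InfoNCE contrast ------------------------------------------------------

infonce_forward <- function(v_f, v_b, temperature) {
  n <- nrow(v_f)
  X <- rbind(v_f, v_b)
  m <- 2L * n
  norms <- pmax(sqrt(rowSums(X^2)), 1e-12)
  U <- X / norms
  S <- tcrossprod(U) / temperature
  E <- exp(S)
  diag(E) <- 0
  same <- matrix(FALSE, m, m)
  same[seq_len(n), seq_len(n)] <- TRUE
  same[(n + 1L):m, (n + 1L):m] <- TRUE
  A <- rowSums(E * same)          # positives (self excluded via diag 0)
  B <- rowSums(E * !same)         # negatives
  loss <- mean(-log(A / (A + B)))
  list(loss = loss, U = U, E = E, same = same, A = A, B = B,
       norms = norms, n = n, temperature = temperature)
}

infonce_backward <- function(cache) {
  n <- cache$n
  m <- 2L * n
  invAB <- 1 / (cache$A + cache$B)
  invA <- 1 / cache$A
  # dL/dS[i, j], anchors along rows; loss is the mean over m anchors
  G <- cache$E * (invAB - ifelse(cache$same, invA, 0)) / m
  diag(G) <- 0
  dU <- (G + t(G)) %*% cache$U / cache$temperature
  # through the row L2 normalization
  proj <- rowSums(dU * cache$U)
  dX <- (dU - cache$U * proj) / cache$norms
  list(dv_f = dX[seq_len(n), , drop = FALSE],
       dv_b = dX[(n + 1L):m, , drop = FALSE])
}

#' InfoNCE contrast between foreground and background instance sets
#'
#' Embeddings are L2-normalized and compared by cosine similarity scaled by
#' `1 / temperature`. For each anchor, the positives are the other members
#' of its own set (foreground or background) and the negatives are all
#' members of the opposite set; the loss is the mean over all `2N` anchors
#' of `-log(sum_pos e^(s/t) / (sum_pos e^(s/t) + sum_neg e^(s/t)))`.
#'
#' @param v_f,v_b N x C foreground and background feature matrices.
#' @param temperature Softmax temperature (default 0.07).
#' @return Scalar loss.
#' @export
info_nce_loss <- function(v_f, v_b, temperature = 0.07) {
  v_f <- as.matrix(v_f)
  v_b <- as.matrix(v_b)
  stopifnot(identical(dim(v_f), dim(v_b)), temperature > 0)
  if (nrow(v_f) < 2L) {
    stop("InfoNCE needs at least 2 instances (no contrast is possible with 1)")
  }
  infonce_forward(v_f, v_b, temperature)$loss
}

## --- Grad-CAM instance attribution ----------------------------------------

#' Grad-CAM logits for every instance
#'
#' Scores a bag of activated instances `A` (the elementwise product of the
#' encoded features with the foreground features) with the linear bag
#' classifier under sum pooling, then attributes the bag class scores back
#' to instances: the pooled gradient `alpha[k, c]` is the average over
#' instances of `d y^c / d A[i, k]`, and the CAM logit of instance `i` for
#' class `c` is `ReLU(sum_k alpha[k, c] * A[i, k])`.
#'
#' Sum pooling in this preliminary pass (rather than a mean) keeps the
#' attribution scale independent of the bag size: the gradient of a
#' sum-pooled score w.r.t. each instance is the classifier weight itself,
#' so the CAM logit of an instance is exactly its own class score under
#' the bag classifier. With mean pooling the `1/N` of the pooling would
#' compound with the `1/N` of the gradient averaging and the class
#' probabilities of large bags could never reach the selection thresholds.
#'
#' @param activated N x C matrix of activated instance features.
#' @param classifier_params List with `W` (C x 2) and `b` (length 2), the
#'   linear bag classifier.
#' @return List with `cam_logits` (N x 2), `alpha` (C x 2 pooled
#'   gradients), and `bag_scores` (length-2 preliminary bag class scores).
#' @export
instance_cam <- function(activated, classifier_params) {
  A <- as.matrix(activated)
  stopifnot_finite(A, "activated")
  W <- classifier_params$W
  b <- classifier_params$b
  if (nrow(W) != ncol(A) || ncol(W) != 2L) {
    stop("classifier_params$W must be C x 2")
  }
  bag_scores <- as.vector(colSums(A) %*% W + b)
  # d y^c / d A[i, k] = W[k, c] for every i, so the instance average is W
  alpha <- W
  cam <- pmax(A %*% alpha, 0)
  list(cam_logits = cam, alpha = alpha, bag_scores = bag_scores)
}

#' Convert CAM logits to instance class probabilities
#'
#' @param cam_logits N x 2 matrix.
#' @return N x 2 matrix of row-wise Softmax probabilities.
#' @export
cam_to_probabilities <- function(cam_logits) {
  cam_logits <- as.matrix(cam_logits)
  stopifnot_finite(cam_logits, "cam_logits")
  row_softmax(cam_logits)
}

#' Select instances by thresholded class probability
#'
#' Instance `i` is selected iff `probs[i, 1] > delta0` (negative class) or
#' `probs[i, 2] > delta1` (positive class). If no instance qualifies, the
#' fallback selects each class's champion — the argmax of each probability
#' column (ties to the lowest row) — so the pooled set is never empty and
#' both classes keep their best-guess evidence. When the two champions
#' coincide (e.g. fully tied probabilities) the fallback is a single
#' index.
#'
#' @param probs N x 2 instance probability matrix.
#' @param delta0,delta1 Class probability thresholds (default 0.85 each).
#' @return Integer vector of selected instance indices (1-based).
#' @export
select_instances <- function(probs, delta0 = 0.85, delta1 = 0.85) {
  probs <- as.matrix(probs)
  sel <- which(probs[, 1] > delta0 | probs[, 2] > delta1)
  if (length(sel) == 0L) {
    sel <- sort(unique(c(which.max(probs[, 1]), which.max(probs[, 2]))))
  }
  as.integer(sel)
}

## --- Full MIPCL head -------------------------------------------------------

mipcl_init <- function(input_dim, cfg) {
  enc <- encoder_params(input_dim, cfg$embed_dim, cfg$dropout, cfg$groups)
  dis <- disentangler_params(cfg$embed_dim, cfg$groups)
  C <- cfg$embed_dim
  list(
    enc_W = enc$W, enc_b = enc$b, enc_gamma = enc$gamma, enc_beta = enc$beta,
    dis_W = dis$W, dis_b = dis$b, dis_gamma = dis$gamma, dis_beta = dis$beta,
    cls_W = matrix(stats::rnorm(C * 2L, sd = sqrt(1 / C)), C, 2L),
    cls_b = rep(0, 2L)
  )
}

## Reassemble typed parameter views from the flat parameter list.
mipcl_views <- function(params, cfg) {
  list(
    enc = structure(list(W = params$enc_W, b = params$enc_b,
                         gamma = params$enc_gamma, beta = params$enc_beta,
                         dropout_rate = cfg$dropout, groups = cfg$groups),
                    class = "encoder_params"),
    dis = structure(list(W = params$dis_W, b = params$dis_b,
                         gamma = params$dis_gamma, beta = params$dis_beta,
                         groups = cfg$groups),
                    class = "disentangler_params"),
    cls = list(W = params$cls_W, b = params$cls_b)
  )
}

#' MIPCL forward pass on one bag
#'
#' Executes the five MIPCL steps (disentangle, contrast, activate +
#' Grad-CAM, threshold-select, pool + classify) and returns the bag logits,
#' the loss terms and the per-instance probabilities kept for
#' explainability. Deterministic in inference mode.
#'
#' @param bag A [feature_bag()].
#' @param params Parameter list from the model initializer (see
#'   [mil_fit()]).
#' @param config A [mil_config()].
#' @param train_mode Apply dropout.
#' @return List with `bag_logits` (length 2), `bag_probs`, `loss`
#'   (`l_instances`, `l_bag`, `l_total`, `mode`, `beta`),
#'   `instance_probs` (list: `cam_logits`, `probs`, `selected_idx`,
#'   `thresholds`), `P` (foreground activations) and an internal `cache`.
#' @export
mipcl_forward <- function(bag, params, config, train_mode = FALSE) {
  stopifnot(inherits(bag, "feature_bag"))
  v <- mipcl_views(params, config)
  n <- nrow(bag$features)
  enc <- encoder_forward(bag$features, v$enc, train = train_mode)
  Z <- enc$z
  dis <- disentangler_forward(Z, v$dis)
  nce <- if (n >= 2L) {
    infonce_forward(dis$v_f, dis$v_b, config$temperature)
  }
  l_inst <- if (is.null(nce)) 0 else nce$loss
  # activated instances: the original encoded features Einstein-summed with
  # the foreground activation map, Z (x) P = v_f — the same feature space
  # the final pooled classifier sees
  A <- dis$v_f
  cam <- instance_cam(A, v$cls)
  probs <- cam_to_probabilities(cam$cam_logits)
  sel <- select_instances(probs, config$delta0, config$delta1)
  # pooling set: the threshold-selected instances when any exist, else the
  # whole bag — before the CAM probabilities saturate, thresholded pooling
  # degenerates gracefully to probability-weighted mean pooling instead of
  # starving the bag loss on one or two arbitrary champions
  pool_idx <- if (any(probs[, 1] > config$delta0 | probs[, 2] > config$delta1)) {
    sel
  } else {
    seq_len(n)
  }
  # class-wise probability-weighted pooling of the selected foreground
  # instances: the evidence vector for class c is the mean of the selected
  # v_f weighted by the instances' class-c Softmax probabilities, and is
  # scored by the classifier's class-c row. This keeps confident
  # negative-class instances from diluting the positive-class evidence of
  # a positive bag (and vice versa).
  Psel <- probs[pool_idx, , drop = FALSE]
  qs <- sweep(Psel, 2L, colSums(Psel), "/")
  pooled <- crossprod(dis$v_f[pool_idx, , drop = FALSE], qs)   # C x 2
  logits <- colSums(pooled * v$cls$W) + v$cls$b
  l_bag <- cross_entropy(logits, bag$bag_label)
  wts <- if (config$loss_mode == "beta") {
    c(inst = 1 - config$beta, bag = config$beta)
  } else {
    c(inst = 1, bag = 1)
  }
  loss <- list(
    l_instances = l_inst, l_bag = l_bag,
    beta = config$beta, mode = config$loss_mode,
    l_total = unname(wts["inst"] * l_inst + wts["bag"] * l_bag)
  )
  list(
    bag_logits = logits,
    bag_probs = softmax_vec(logits),
    loss = loss,
    instance_probs = list(
      cam_logits = cam$cam_logits, probs = probs,
      selected_idx = sel,
      thresholds = c(delta0 = config$delta0, delta1 = config$delta1)
    ),
    P = dis$P,
    cache = list(enc = enc, dis = dis, nce = nce, A = A, cam = cam,
                 probs = probs, sel = sel, pool_idx = pool_idx, Psel = Psel,
                 qs = qs, pooled = pooled, logits = logits, wts = wts, n = n)
  )
}

## Full analytic gradient of the MIPCL total loss, including the path
## through the Grad-CAM-derived Softmax pooling weights. The discrete
## choices (selection set, per-instance argmax class) are piecewise constant
## and carry no gradient almost everywhere.
mipcl_backward <- function(fw, params, config, bag) {
  ca <- fw$cache
  v <- mipcl_views(params, config)
  n <- ca$n
  Z <- ca$enc$z
  v_f <- ca$dis$v_f
  sel <- ca$pool_idx
  wts <- ca$wts

  dlogits <- wts["bag"] * cross_entropy_grad(ca$logits, bag$bag_label)
  # logit_c = sum_k pooled[k, c] W[k, c] + b_c
  dcls_W <- sweep(ca$pooled, 2L, dlogits, "*")
  dcls_b <- dlogits
  dpooled <- sweep(v$cls$W, 2L, dlogits, "*")             # C x 2

  # pooled[, c] = sum_i qs[i, c] v_f[i, ] over selected
  Vsel <- v_f[sel, , drop = FALSE]
  dv_f <- matrix(0, n, ncol(Z))
  dv_f[sel, ] <- dv_f[sel, , drop = FALSE] + ca$qs %*% t(dpooled)
  dq <- Vsel %*% dpooled                                   # s x 2
  # qs[, c] = Psel[, c] / sum(Psel[, c])
  dprobs <- matrix(0, n, 2L)
  for (cc in 1:2) {
    dprobs[sel, cc] <- (dq[, cc] - sum(ca$qs[, cc] * dq[, cc])) /
      sum(ca$Psel[, cc])
  }
  # row softmax backward
  dcam <- ca$probs * (dprobs - rowSums(dprobs * ca$probs))
  # ReLU backward (pre-activation = A %*% alpha); A = v_f
  pre <- ca$A %*% ca$cam$alpha
  dM <- dcam * (pre > 0)
  dalpha <- crossprod(ca$A, dM)
  dcls_W <- dcls_W + dalpha
  dZ <- matrix(0, n, ncol(Z))
  dv_f <- dv_f + dM %*% t(ca$cam$alpha)

  dv_b <- matrix(0, n, ncol(Z))
  if (!is.null(ca$nce)) {
    nceb <- infonce_backward(ca$nce)
    dv_f <- dv_f + wts["inst"] * nceb$dv_f
    dv_b <- dv_b + wts["inst"] * nceb$dv_b
  }

  # v_f = P * Z ; v_b = (1 - P) * Z   (elementwise, per channel)
  P <- ca$dis$P
  dP <- (dv_f - dv_b) * Z
  dZ <- dZ + dv_f * P + dv_b * (1 - P)

  # disentangler: P = sigmoid(GN(FC(Z))), per-channel
  dgn_y <- dP * P * (1 - P)
  gnb <- gn_backward(dgn_y, ca$dis$gn, v$dis$gamma)
  fcb <- fc_backward(gnb$dx, ca$dis$fc, v$dis$W)
  dZ <- dZ + fcb$dx

  encb <- encoder_backward(dZ, ca$enc, v$enc)

  list(
    enc_W = encb$dW, enc_b = encb$db,
    enc_gamma = encb$dgamma, enc_beta = encb$dbeta,
    dis_W = fcb$dW, dis_b = fcb$db,
    dis_gamma = gnb$dgamma, dis_beta = gnb$dbeta,
    cls_W = dcls_W, cls_b = dcls_b
  )
}
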