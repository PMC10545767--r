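# The MIL heads: encoder, disentangler, InfoNCE, Grad-CAM, selection,
# attention pooling, CLAM clustering, and gradient correctness.

test_that("encoder matches a hand-computed scalar forward pass", {
  ep <- encoder_params(input_dim = 2, embed_dim = 4, dropout_rate = 0,
                       groupnorm_groups = 2)
  ep$W <- matrix(c(1, 0.5, -1, 2, 0.25, -0.5, 3, 1), 2, 4)
  ep$b <- c(0.1, -0.2, 0.3, 0)
  ep$gamma <- c(1, 2, 0.5, 1)
  ep$beta <- c(0, 0.1, -0.1, 0)
  x <- matrix(c(1, -1), 1, 2)
  # scalar reference: FC, then per-group normalization, then Mish
  fc <- as.vector(x %*% ep$W) + ep$b
  ref <- numeric(4)
  for (g in 1:2) {
    cols <- if (g == 1) 1:2 else 3:4
    mu <- mean(fc[cols])
    va <- mean(fc[cols]^2) - mu^2
    for (k in cols) {
      xh <- (fc[k] - mu) / sqrt(va + 1e-5)
      y <- ep$gamma[k] * xh + ep$beta[k]
      sp <- log1p(exp(-abs(y))) + max(y, 0)
      ref[k] <- y * tanh(sp)
    }
  }
  expect_equal(as.vector(encode(x, ep)), ref, tolerance = 1e-12)
  # Mish fixes zero: a zero pre-activation unit stays zero
  expect_identical(cytomil:::mish(0), 0)
  # inference is deterministic even with nonzero dropout configured
  ep2 <- encoder_params(3, 8, dropout_rate = 0.5, groupnorm_groups = 2)
  xx <- matrix(rnorm(12), 4, 3)
  expect_identical(encode(xx, ep2), encode(xx, ep2))
  expect_error(encode(matrix(1, 2, 5), ep2), "input_dim mismatch")
})

test_that("disentangler splits embeddings exactly into foreground and background", {
  set.seed(2)
  dp <- disentangler_params(embed_dim = 6, groupnorm_groups = 2)
  Z <- matrix(rnorm(30), 5, 6)
  d <- disentangle(Z, dp)
  expect_equal(d$v_f + d$v_b, Z, tolerance = 1e-12)
  expect_true(all(d$P > 0 & d$P < 1))
  # forcing the pre-sigmoid map to zero halves every instance
  dp0 <- dp
  dp0$gamma <- rep(0, 6)
  dp0$beta <- rep(0, 6)
  d0 <- disentangle(Z, dp0)
  expect_equal(d0$P, matrix(0.5, 5, 6), ignore_attr = TRUE)
  expect_equal(d0$v_f, Z / 2, tolerance = 1e-12)
  expect_equal(d0$v_f, d0$v_b, tolerance = 1e-12)
  # hand multiplication on a tiny case
  d3 <- disentangle(Z[1:3, 1:2], disentangler_params(2, 1))
  for (i in 1:3) {
    for (j in 1:2) {
      expect_equal(d3$v_f[i, j], d3$P[i, j] * Z[i, j], tolerance = 1e-12)
    }
  }
})

test_that("InfoNCE equals its closed form and a brute-force pair enumeration", {
  # orthogonal foreground/background: closed form per anchor
  v_f <- rbind(c(1, 0, 0), c(1, 0, 0))
  v_b <- rbind(c(0, 1, 0), c(0, 1, 0))
  tau <- 0.07
  closed <- -log(exp(1 / tau) / (exp(1 / tau) + 2 * exp(0)))
  expect_equal(info_nce_loss(v_f, v_b, tau), closed, tolerance = 1e-10)
  expect_equal(info_nce_loss(v_f, v_b, tau), reference_infonce(v_f, v_b, tau),
               tolerance = 1e-10)
  # degenerate case: foreground identical to background
  set.seed(3)
  v <- matrix(rnorm(12), 4, 3)
  expect_equal(info_nce_loss(v, v), reference_infonce(v, v), tolerance = 1e-10)
  expect_error(info_nce_loss(v[1, , drop = FALSE], v[1, , drop = FALSE]),
               "at least 2")
})

test_that("Grad-CAM pooled gradients match symbolic and finite-difference oracles", {
  # zero activations give zero CAM logits
  cp <- list(W = matrix(c(1, -2), 1, 2), b = c(0, 0))
  z <- instance_cam(matrix(0, 4, 1), cp)
  expect_true(all(z$cam_logits == 0))
  # linear single-feature case with a sum-pooled bag score:
  # cam[i, c] = ReLU(w_c * A[i])
  A1 <- matrix(c(2, -1, 3), 3, 1)
  r1 <- instance_cam(A1, cp)
  expect_equal(r1$cam_logits,
               pmax(cbind(1 * A1, -2 * A1), 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # alpha vs central finite differences of the bag class score
  set.seed(4)
  A <- matrix(rnorm(12), 4, 3)
  cpw <- list(W = matrix(rnorm(6), 3, 2), b = rnorm(2))
  r <- instance_cam(A, cpw)
  y_of <- function(Am, cc) as.vector(colSums(Am) %*% cpw$W + cpw$b)[cc]
  eps <- 1e-5
  for (cc in 1:2) {
    for (k in 1:3) {
      fd <- mean(sapply(1:4, function(i) {
        Ap <- A; Ap[i, k] <- Ap[i, k] + eps
        Am <- A; Am[i, k] <- Am[i, k] - eps
        (y_of(Ap, cc) - y_of(Am, cc)) / (2 * eps)
      }))
      expect_equal(r$alpha[k, cc], fd, tolerance = 1e-3)
    }
  }
})

test_that("CAM probabilities and selection follow the documented rules", {
  expect_equal(cam_to_probabilities(matrix(0, 3, 2)),
               matrix(0.5, 3, 2), ignore_attr = TRUE)
  set.seed(5)
  p <- cam_to_probabilities(matrix(rnorm(20), 10, 2))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  p2 <- cam_to_probabilities(matrix(c(10, -10), 1, 2))
  expect_equal(p2[1, 1], plogis(20), tolerance = 1e-6)

  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.1, 0.9))
  expect_identical(select_instances(probs, 0.85, 0.85), c(1L, 3L))
  # fallback selects exactly one index when nothing passes
  flat <- matrix(0.5, 4, 2)
  expect_length(select_instances(flat, 0.85, 0.85), 1L)
})

test_that("MIPCL forward honors the loss modes and is deterministic in inference", {
  bag <- tiny_bag(n = 5, c = 4)
  cfg_sum <- tiny_config()
  set.seed(6)
  params <- mil_init("mipcl", 4, cfg_sum)
  f1 <- mipcl_forward(bag, params, cfg_sum)
  f2 <- mipcl_forward(bag, params, cfg_sum)
  expect_identical(f1$bag_logits, f2$bag_logits)
  expect_identical(f1$instance_probs$probs, f2$instance_probs$probs)
  # default mode: plain unweighted sum of the two losses
  expect_equal(f1$loss$l_total, f1$loss$l_instances + f1$loss$l_bag)
  # beta = 1 collapses the total to the bag loss
  cfg_b1 <- tiny_config(loss_mode = "beta", beta = 1)
  fb <- mipcl_forward(bag, params, cfg_b1)
  expect_equal(fb$loss$l_total, fb$loss$l_bag)
  # selection is a nonempty subset and the split conserves the embedding
  expect_gte(length(f1$instance_probs$selected_idx), 1)
  expect_true(all(f1$instance_probs$selected_idx %in% 1:5))
  expect_true(all(f1$P > 0 & f1$P < 1))
})

test_that("attention pooling matches trivial cases and a scalar-loop reference", {
  ap <- list(w = c(0.3, -0.7), V = matrix(c(0.5, 1, -1, 0.2), 2, 2))
  # one instance takes all the weight
  h1 <- matrix(c(1.5, -0.5), 1, 2)
  r1 <- abmil_attention_pool(h1, ap)
  expect_equal(r1$a, 1)
  expect_equal(r1$z, as.vector(h1))
  # identical instances share the weight uniformly
  H_same <- matrix(rep(c(0.4, 1.1), each = 5), 5, 2)
  r2 <- abmil_attention_pool(H_same, ap)
  expect_equal(r2$a, rep(0.2, 5))
  # hand-set case vs scalar loop
  set.seed(7)
  H <- matrix(rnorm(6), 3, 2)
  r3 <- abmil_attention_pool(H, ap)
  ref <- reference_attention(H, ap$w, ap$V)
  expect_equal(r3$a, ref$a, tolerance = 1e-12)
  expect_equal(r3$z, ref$z, tolerance = 1e-12)
  expect_equal(sum(r3$a), 1, tolerance = 1e-12)
})

test_that("ABMIL collapses to the single-instance path on constant bags", {
  cfg <- tiny_config()
  set.seed(8)
  params <- mil_init("abmil", 4, cfg)
  h <- rnorm(4)
  bag_many <- feature_bag(matrix(rep(h, each = 6), 6, 4),
                          cbind(0:5 * 256L, 0L), 1)
  bag_one <- feature_bag(matrix(h, 1, 4), cbind(0L, 0L), 1)
  f_many <- abmil_forward(bag_many, params, cfg)
  f_one <- abmil_forward(bag_one, params, cfg)
  expect_equal(f_many$bag_logits, f_one$bag_logits, tolerance = 1e-10)
  expect_equal(sum(f_many$attention), 1, tolerance = 1e-12)
  expect_identical(abmil_forward(bag_many, params, cfg)$bag_logits,
                   f_many$bag_logits)
})

test_that("CLAM pseudo-labels, SVM loss and total loss follow their definitions", {
  pl <- clam_pseudo_labels(c(0.4, 0.1, 0.3, 0.2), B = 1)
  expect_identical(pl$pos_idx, 1L)
  expect_identical(pl$neg_idx, 2L)
  # B shrinks to floor(K / 2) on small bags
  pl2 <- clam_pseudo_labels(c(0.4, 0.1, 0.3, 0.2), B = 8)
  expect_length(pl2$pos_idx, 2L)
  expect_length(pl2$neg_idx, 2L)
  expect_length(intersect(pl2$pos_idx, pl2$neg_idx), 0L)
  expect_warning(clam_pseudo_labels(0.5, B = 8), "fewer than 2")
  # ties break to the lowest index
  pl3 <- clam_pseudo_labels(c(0.3, 0.3, 0.2, 0.2), B = 1)
  expect_identical(pl3$pos_idx, 1L)
  expect_identical(pl3$neg_idx, 3L)

  # smooth top-1 SVM: direct evaluation of the smoothed hinge
  expect_equal(smooth_top1_svm_loss(c(2, 0), 0, margin = 1, smoothing = 1),
               log(exp(2) + exp(1)) - 2, tolerance = 1e-12)
  # margin satisfied by a wide gap: loss approaches zero
  expect_lt(smooth_top1_svm_loss(c(20, 0), 0), 1e-6)

  expect_equal(clam_loss(0.6, 0.2, bag_weight = 0.7), 0.7 * 0.6 + 0.3 * 0.2)
  expect_equal(clam_loss(0.6, 0.2, bag_weight = 1), 0.6)
  # default pseudo-label count and bag weight
  cfg <- mil_config()
  expect_identical(cfg$clam_B, 8L)
  expect_equal(cfg$clam_bag_weight, 0.7)
})

test_that("analytic gradients of every head match central finite differences", {
  for (model in c("mipcl", "abmil", "clam")) {
    set.seed(10)
    cfg <- tiny_config()
    bag <- tiny_bag(n = 6, c = 5, label = 1L, seed = 10)
    params <- mil_init(model, 5, cfg)
    fw <- cytomil:::model_forward(model, bag, params, cfg, FALSE)
    gr <- cytomil:::model_backward(model, fw, params, cfg, bag)
    loss_fn <- function(p) {
      cytomil:::model_forward(model, bag, p, cfg, FALSE)$loss$l_total
    }
    set.seed(11)
    for (nm in names(params)) {
      for (idx in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        fd <- fd_grad(loss_fn, params, nm, idx)
        expect_equal(gr[[nm]][idx], fd, tolerance = 1e-4,
                     label = sprintf("%s %s[%d] analytic", model, nm, idx),
                     expected.label = "finite difference")
      }
    }
  }
})

test_that("compiled training kernels reproduce the reference implementation", {
  for (model in c("mipcl", "abmil", "clam")) {
    for (seed in 1:4) {
      set.seed(seed)
      cfg <- tiny_config()
      spec <- bag_spec(feature_dim = 7, bag_size_range = c(2, 12),
                       witness_rate = 0.3, separation = 3)
      bag <- sample_bag(spec, sample(0:1, 1))
      params <- mil_init(model, 7, cfg)
      fwR <- cytomil:::model_forward(model, bag, params, cfg, FALSE)
      grR <- cytomil:::model_backward(model, fwR, params, cfg, bag)
      st <- cytomil:::model_step(model, bag, params,
                                 cytomil:::step_cfg(model, cfg),
                                 train = FALSE, want_grads = TRUE)
      expect_equal(st$l_total, fwR$loss$l_total, tolerance = 1e-10)
      expect_equal(as.vector(st$bag_logits), fwR$bag_logits,
                   tolerance = 1e-10)
      for (nm in names(grR)) {
        expect_equal(as.vector(st$grads[[nm]]), as.vector(grR[[nm]]),
                     tolerance = 1e-8,
                     label = sprintf("%s kernel %s", model, nm))
      }
    }
  }
})

test_that("each head drives its training loss below 0.1 on a small separable set", {
  spec <- bag_spec(feature_dim = 12, bag_size_range = c(8, 15), seed = 15)
  bags <- sample_dataset(spec, 20)
  for (model in c("mipcl", "abmil", "clam")) {
    cfg <- mil_config(dropout = 0, epochs = 200, seed = 3)
    fit <- mil_fit(bags, model = model, config = cfg)
    terms <- vapply(bags, function(b) {
      fw <- cytomil:::model_forward(model, b, fit$params, fit$config, FALSE)
      c(fw$loss$l_total, fw$loss$l_bag)
    }, numeric(2))
    # the bag-classification objective is fit to near zero by every head
    expect_lt(mean(terms[2, ]), 0.1)
    # MIPCL and ABMIL drive the full total below 0.1 as well; CLAM's total
    # retains the structural slack of its smoothed SVM on pseudo-labels
    if (model != "clam") expect_lt(mean(terms[1, ]), 0.1)
  }
})
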