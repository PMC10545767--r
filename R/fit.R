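# Model fitting: configuration, training loop, and the `mil_model` S3 class.

#' Configuration for MIL model training
#'
#' Architecture and optimization hyperparameters shared by the three heads.
#' Optimizer defaults follow the standard recipe for this family of models:
#' Adam with `beta1 = 0.9`, `beta2 = 0.95`, learning rate `3e-4` and weight
#' decay `1e-4`, under a OneCycle learning-rate schedule with cosine
#' annealing and cycled momentum. The InfoNCE temperature defaults to 0.07
#' and the instance-selection thresholds to 0.85 for both classes; CLAM uses
#' a pseudo-label count of 8 per pole and a bag weight of 0.7. The MIPCL
#' total loss defaults to the plain (unweighted) sum of the instance and bag
#' terms; `loss_mode = "beta"` switches to the convex combination
#' `(1 - beta) * L_instances + beta * L_bag`.
#'
#' @param embed_dim Encoder embedding width C (default 64).
#' @param attn_dim Attention hidden width L (default 32).
#' @param dropout Encoder dropout rate (default 0.25).
#' @param groups Group-normalization groups (default 8).
#' @param temperature InfoNCE temperature (default 0.07).
#' @param delta0,delta1 Instance-selection probability thresholds
#'   (default 0.85 each).
#' @param loss_mode `"sum"` (default) or `"beta"`.
#' @param beta Bag-loss weight used when `loss_mode = "beta"`.
#' @param clam_B CLAM pseudo-label count per pole (default 8).
#' @param clam_bag_weight CLAM bag-loss weight (default 0.7).
#' @param svm_margin,svm_smoothing Smooth top-1 SVM constants (default 1, 1).
#' @param lr Peak learning rate (default 3e-4).
#' @param adam_beta1,adam_beta2 Adam moment decays (default 0.9, 0.95).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param epochs Maximum training epochs (default 50).
#' @param patience Early-stopping patience on validation loss (default 10);
#'   `Inf` disables early stopping.
#' @param min_delta Minimum validation-loss improvement that resets the
#'   patience counter (default 1e-4).
#' @param pct_start OneCycle warm-up fraction (default 0.3).
#' @param seed Integer seed controlling initialization, bag sampling and
#'   dropout inside [mil_fit()].
#' @return An object of class `mil_config`.
#' @export
mil_config <- function(embed_dim = 64L, attn_dim = 32L, dropout = 0.25,
                       groups = 8L, temperature = 0.07,
                       delta0 = 0.85, delta1 = 0.85,
                       loss_mode = c("sum", "beta"), beta = 0.5,
                       clam_B = 8L, clam_bag_weight = 0.7,
                       svm_margin = 1, svm_smoothing = 1,
                       lr = 3e-4, adam_beta1 = 0.9, adam_beta2 = 0.95,
                       weight_decay = 1e-4,
                       epochs = 50L, patience = 10L, min_delta = 1e-4,
                       pct_start = 0.3, seed = NULL) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(
    is_count(embed_dim), is_count(attn_dim), is_count(groups),
    embed_dim %% groups == 0L,
    dropout >= 0, dropout < 1, temperature > 0,
    delta0 > 0, delta0 < 1, delta1 > 0, delta1 < 1,
    beta >= 0, beta <= 1, is_count(clam_B),
    clam_bag_weight > 0, clam_bag_weight < 1,
    svm_margin >= 0, svm_smoothing > 0,
    lr > 0, adam_beta1 > 0, adam_beta1 < 1,
    adam_beta2 > 0, adam_beta2 < 1, weight_decay >= 0,
    is_count(epochs), min_delta >= 0
  )
  structure(
    list(
      embed_dim = as.integer(embed_dim), attn_dim = as.integer(attn_dim),
      dropout = dropout, groups = as.integer(groups),
      temperature = temperature, delta0 = delta0, delta1 = delta1,
      loss_mode = loss_mode, beta = beta,
      clam_B = as.integer(clam_B), clam_bag_weight = clam_bag_weight,
      svm_margin = svm_margin, svm_smoothing = svm_smoothing,
      lr = lr, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
      weight_decay = weight_decay,
      epochs = as.integer(epochs), patience = patience,
      min_delta = min_delta, pct_start = pct_start,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "mil_config"
  )
}

MODEL_KINDS <- c("mipcl", "abmil", "clam")

#' Initialize parameters for a MIL head
#'
#' Draws fresh parameters from the session RNG.
#'
#' @param model One of `"mipcl"`, `"abmil"`, `"clam"`.
#' @param input_dim Input feature dimensionality of the bags.
#' @param config A [mil_config()].
#' @return Named list of parameter matrices/vectors.
#' @export
mil_init <- function(model, input_dim, config = mil_config()) {
  model <- match.arg(model, MODEL_KINDS)
  stopifnot(inherits(config, "mil_config"))
  switch(model,
    mipcl = mipcl_init(input_dim, config),
    abmil = abmil_init(input_dim, config),
    clam = clam_init(input_dim, config)
  )
}

model_forward <- function(model, bag, params, config, train_mode = FALSE) {
  switch(model,
    mipcl = mipcl_forward(bag, params, config, train_mode),
    abmil = abmil_forward(bag, params, config, train_mode),
    clam = clam_forward(bag, params, config, train_mode)
  )
}

model_backward <- function(model, fw, params, config, bag) {
  switch(model,
    mipcl = mipcl_backward(fw, params, config, bag),
    abmil = abmil_backward(fw, params, config, bag),
    clam = clam_backward(fw, params, config, bag)
  )
}

## Flattened config passed to the compiled per-bag step kernels.
step_cfg <- function(model, config) {
  wts <- if (config$loss_mode == "beta") {
    c(1 - config$beta, config$beta)
  } else {
    c(1, 1)
  }
  list(
    groups = config$groups, dropout = config$dropout,
    temperature = config$temperature,
    delta0 = config$delta0, delta1 = config$delta1,
    w_inst = wts[1], w_bag = wts[2],
    clam_B = config$clam_B, clam_bag_weight = config$clam_bag_weight,
    svm_margin = config$svm_margin, svm_smoothing = config$svm_smoothing
  )
}

## One compiled forward(+backward) pass; returns loss terms, bag logits and
## (when want_grads) gradients named like the parameter list.
model_step <- function(model, bag, params, scfg, train = FALSE,
                       want_grads = FALSE) {
  fn <- switch(model, mipcl = mipcl_step_cpp, abmil = abmil_step_cpp,
               clam = clam_step_cpp)
  fn(bag$features, bag$bag_label, params, scfg, train, want_grads)
}

bag_labels <- function(bags) {
  vapply(bags, function(b) b$bag_label, integer(1))
}

mean_loss <- function(model, bags, params, config,
                      scfg = step_cfg(model, config)) {
  mean(vapply(bags, function(b) {
    model_step(model, b, params, scfg)$l_total
  }, numeric(1)))
}

#' Fit a MIL bag classifier
#'
#' Trains one of the three MIL heads on a list of labeled feature bags with
#' Adam under a OneCycle learning-rate schedule, taking one optimization
#' step per bag. Bags are sampled with replacement using class-balanced
#' weights (inverse class frequency), so the expected sampled class ratio
#' is 1:1 regardless of dataset imbalance. When a validation set is given,
#' the total validation loss is evaluated after every epoch, the parameters
#' with the minimum validation loss are kept, and training stops early
#' after `config$patience` epochs without improvement; the test set, if
#' any, must remain untouched until after this selection.
#'
#' @param bags List of labeled [feature_bag()] objects (training set).
#' @param model One of `"mipcl"`, `"abmil"`, `"clam"`.
#' @param config A [mil_config()].
#' @param val_bags Optional list of validation bags for model selection.
#' @param verbose Print a line per epoch.
#' @return An object of class `mil_model` with components `model`, `params`
#'   (selected weights), `config`, `history` (per-epoch data frame),
#'   `best_epoch`, `input_dim`, `n_train`.
#' @examples
#' spec <- bag_spec(feature_dim = 8, bag_size_range = c(5, 10), seed = 42)
#' bags <- sample_dataset(spec, 20)
#' cfg <- mil_config(embed_dim = 16, attn_dim = 8, groups = 4,
#'                   epochs = 3, seed = 1)
#' fit <- mil_fit(bags, model = "abmil", config = cfg)
#' predict(fit, bags[1:2])
#' @export
mil_fit <- function(bags, model = c("mipcl", "abmil", "clam"),
                    config = mil_config(), val_bags = NULL,
                    verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(length(bags) >= 1L, inherits(config, "mil_config"))
  labels <- bag_labels(bags)
  input_dim <- ncol(bags[[1]]$features)
  if (!is.null(config$seed)) set.seed(config$seed)

  params <- mil_init(model, input_dim, config)
  state <- adam_state(params)
  scfg <- step_cfg(model, config)
  wts <- if (length(unique(labels)) > 1L) {
    sampler_weights(labels)
  } else {
    rep(1 / length(labels), length(labels))
  }

  n <- length(bags)
  total_steps <- config$epochs * n
  step <- 0L
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n, n, replace = TRUE, prob = wts)
    ep_loss <- 0
    last_lr <- NA_real_
    for (i in order_idx) {
      step <- step + 1L
      sched <- onecycle_schedule(step, total_steps, config$lr,
                                 pct_start = config$pct_start,
                                 mom_max = config$adam_beta1 + 0.05,
                                 mom_min = config$adam_beta1 - 0.05)
      fw <- model_step(model, bags[[i]], params, scfg, train = TRUE,
                       want_grads = TRUE)
      if (!is.finite(fw$l_total)) {
        stop(sprintf("non-finite training loss at epoch %d (bag %s)",
                     epoch, bags[[i]]$slide_id))
      }
      gr <- fw$grads
      upd <- adam_step(params, gr, state, lr = sched$lr,
                       beta1 = sched$momentum, beta2 = config$adam_beta2,
                       weight_decay = config$weight_decay)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + fw$l_total
      last_lr <- sched$lr
    }
    train_loss <- ep_loss / n
    val_loss <- if (!is.null(val_bags)) {
      mean_loss(model, val_bags, params, config, scfg)
    } else {
      NA_real_
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      lr = last_lr
    ))
    if (verbose) {
      message(sprintf("[%s] epoch %3d  train %.4f  val %s", model, epoch,
                      train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
    }
    if (!is.null(val_bags)) {
      if (val_loss < best_val - config$min_delta) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      best_params <- params
      best_epoch <- epoch
    }
  }

  structure(
    list(
      model = model,
      params = best_params,
      config = config,
      history = history,
      best_epoch = best_epoch,
      input_dim = input_dim,
      n_train = n,
      class_counts = table(factor(labels, levels = c(0, 1)))
    ),
    class = "mil_model"
  )
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %s head, input_dim %d, embed_dim %d\n",
              toupper(x$model), x$input_dim, x$config$embed_dim))
  cat(sprintf("  trained on %d bags (%s neg / %s pos), %d epoch(s), best epoch %d\n",
              x$n_train, x$class_counts[1], x$class_counts[2],
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  h <- object$history
  cat(sprintf("%s multiple-instance classifier\n", toupper(object$model)))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(object$params, length, integer(1)))))
  cat(sprintf("  epochs run: %d (best: %d)\n", nrow(h), object$best_epoch))
  cat(sprintf("  final train loss: %.4f\n", h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_loss))) {
    cat(sprintf("  best val loss:    %.4f\n", min(h$val_loss, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
coef.mil_model <- function(object, ...) {
  object$params
}

#' Predict from a fitted MIL model
#'
#' @param object A [mil_fit()] result.
#' @param bags A single [feature_bag()] or a list of them.
#' @param type `"prob"` (n x 2 matrix of bag class probabilities),
#'   `"class"` (0/1 vector at argmax), or `"instance"` (list of
#'   per-instance data frames: MIPCL returns CAM-derived class
#'   probabilities and the selection flag; ABMIL/CLAM return attention
#'   weights).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mil_model <- function(object, bags, type = c("prob", "class", "instance"),
                              ...) {
  type <- match.arg(type)
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  fws <- lapply(bags, function(b) {
    model_forward(object$model, b, object$params, object$config,
                  train_mode = FALSE)
  })
  if (type == "prob") {
    out <- t(vapply(fws, function(f) f$bag_probs, numeric(2)))
    colnames(out) <- c("negative", "positive")
    return(out)
  }
  if (type == "class") {
    return(vapply(fws, function(f) which.max(f$bag_probs) - 1L, integer(1)))
  }
  lapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    f <- fws[[i]]
    if (object$model == "mipcl") {
      ip <- f$instance_probs
      data.frame(
        slide_id = b$slide_id,
        x = b$coords[, 1], y = b$coords[, 2],
        prob_negative = ip$probs[, 1], prob_positive = ip$probs[, 2],
        selected = seq_len(nrow(b$features)) %in% ip$selected_idx
      )
    } else {
      data.frame(
        slide_id = b$slide_id,
        x = b$coords[, 1], y = b$coords[, 2],
        attention = f$attention
      )
    }
  })
}

#' Plot training history of a MIL model
#'
#' Draws the per-epoch training (and, when present, validation) total loss
#' and marks the selected epoch.
#'
#' @param x A `mil_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mil_model <- function(x, ...) {
  h <- x$history
  has_val <- !all(is.na(h$val_loss))
  ylim <- range(c(h$train_loss, if (has_val) h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "total loss", ylim = ylim,
                 main = sprintf("%s training history", toupper(x$model)), ...)
  if (has_val) {
    graphics::lines(h$epoch, h$val_loss, lwd = 2, lty = 2, col = "firebrick")
    graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), lwd = 2, col = c("black", "firebrick"),
                     bty = "n")
  }
  invisible(x)
}

#' Save / load a fitted MIL model
#'
#' The checkpoint embeds the full configuration alongside the weights.
#'
#' @param object A `mil_model`.
#' @param path File path (RDS).
#' @return `path` invisibly; `load_mil_model` returns the `mil_model`.
#' @export
save_mil_model <- function(object, path) {
  stopifnot(inherits(object, "mil_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_mil_model
#' @export
load_mil_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "mil_model")) stop("file does not contain a mil_model")
  obj
}
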