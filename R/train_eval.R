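# Experimental harness: stratified 10-fold cross-validation with 80/10/10
# splits, class-weighted bag sampling, per-fold metric computation and
# paired statistical comparison across models.
#
# "10-fold with 80/10/10" is realized as: the dataset is partitioned into
# 10 disjoint stratified test folds (each ~10% and covering the dataset in
# union); within each fold the remaining 90% is split 8:1 stratified into
# training and validation sets. This is the only arrangement satisfying
# both "10-fold cross-validation" and "80/10/10 splits".

#' Stratified k-fold train/validation/test splits
#'
#' @param labels Integer 0/1 vector of bag labels.
#' @param k Number of folds (default 10).
#' @param fractions Target train/val/test fractions (default
#'   `c(0.8, 0.1, 0.1)`); test size is driven by `k`, the remainder is
#'   split `fractions[1]:fractions[2]` stratified.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List of `k` fold splits, each a list with `fold_id` (0-based),
#'   `train_idx`, `val_idx`, `test_idx` (disjoint 1-based index vectors
#'   covering the dataset).
#' @export
stratified_kfold <- function(labels, k = 10L, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)), is_count(k, 2L),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) {
    stop(sprintf("each class needs at least k = %d members (have %d neg, %d pos)",
                 k, counts[1], counts[2]))
  }
  set.seed(seed)
  # per-class shuffled indices dealt round-robin into k test chunks
  chunks <- vector("list", k)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    fold_of <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) {
      chunks[[f]] <- c(chunks[[f]], idx[fold_of == f])
    }
  }
  val_share <- fractions[2] / (fractions[1] + fractions[2])
  lapply(seq_len(k), function(f) {
    test_idx <- sort(chunks[[f]])
    rest <- setdiff(seq_along(labels), test_idx)
    val_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      rc <- rest[labels[rest] == cls]
      n_val <- round(length(rc) * val_share)
      if (length(rc) > 0L && n_val > 0L) {
        val_idx <- c(val_idx, sample(rc, n_val))
      }
    }
    val_idx <- sort(val_idx)
    train_idx <- sort(setdiff(rest, val_idx))
    list(fold_id = f - 1L, train_idx = train_idx, val_idx = val_idx,
         test_idx = test_idx)
  })
}

#' Class-balancing bag sampling weights
#'
#' Each bag's weight is inversely proportional to its class frequency and
#' the weights are normalized to sum to one, so sampling bags with these
#' weights yields an expected 1:1 class ratio. For the typical 3:1
#' positive:negative slide imbalance, each negative bag receives three
#' times the weight of each positive bag.
#'
#' @param labels Integer 0/1 vector.
#' @return Numeric weight vector summing to 1.
#' @export
sampler_weights <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) {
    stop("both classes must be present to balance sampling weights")
  }
  w <- 1 / as.numeric(counts)[labels + 1L]
  w / sum(w)
}

## --- Metrics ---------------------------------------------------------------

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney U statistic with midranks (ties averaged).
#'
#' @param labels Binary 0/1 truth vector.
#' @param scores Numeric scores for the positive class.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: `sum_i (R_i - R_(i-1)) * P_i` over
#' descending score thresholds, with ties handled as one threshold block.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, or `NA` if no positives are present.
#' @export
auprc <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels)) {
    return(if (n_pos == length(labels)) 1 else NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # collapse tied scores into single threshold blocks
  block <- cumsum(!duplicated(sc))
  tp_b <- tapply(lab == 1, block, sum)
  n_b <- tapply(lab, block, length)
  tp <- cumsum(tp_b)
  fp <- cumsum(n_b) - tp
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for one test fold
#'
#' Balanced accuracy from the argmax confusion matrix, support-weighted F1,
#' and support-weighted one-vs-rest AUROC and AUPRC (for two classes the
#' negative-class curves use `1 - score`). If the test fold contains only
#' one class, the metrics are undefined and returned as `NA` with a
#' warning.
#'
#' @param labels Binary 0/1 truth vector.
#' @param probs n x 2 matrix of class probabilities (or a vector of
#'   positive-class scores).
#' @return Named numeric vector: `balanced_accuracy`, `weighted_f1`,
#'   `weighted_auroc`, `weighted_auprc`.
#' @export
evaluate_predictions <- function(labels, probs) {
  if (is.matrix(probs)) {
    scores <- probs[, 2]
    pred <- max.col(probs, ties.method = "first") - 1L
  } else {
    scores <- probs
    pred <- as.integer(scores > 0.5)
  }
  if (length(unique(labels)) < 2L) {
    warning("test set contains a single class; metrics are undefined")
    return(c(balanced_accuracy = NA_real_, weighted_f1 = NA_real_,
             weighted_auroc = NA_real_, weighted_auprc = NA_real_))
  }
  per_class <- vapply(c(0L, 1L), function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    recall <- tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    c(recall = recall, f1 = f1, support = sum(labels == cls))
  }, numeric(3))
  support <- per_class["support", ]
  wts <- support / sum(support)
  auroc_c <- c(auroc(1 - labels, 1 - scores), auroc(labels, scores))
  auprc_c <- c(auprc(1 - labels, 1 - scores), auprc(labels, scores))
  c(
    balanced_accuracy = mean(per_class["recall", ]),
    weighted_f1 = sum(wts * per_class["f1", ]),
    weighted_auroc = sum(wts * auroc_c),
    weighted_auprc = sum(wts * auprc_c)
  )
}

## --- Cross-validation ------------------------------------------------------

#' Train and evaluate one cross-validation fold
#'
#' Trains on the fold's training indices with class-weighted sampling,
#' selects the checkpoint with minimum validation loss, and only then
#' evaluates once on the test indices.
#'
#' @param bags List of labeled [feature_bag()] objects.
#' @param split One fold from [stratified_kfold()].
#' @param model One of `"mipcl"`, `"abmil"`, `"clam"`.
#' @param config A [mil_config()].
#' @return List with `fit` (the selected `mil_model`), `metrics` (named
#'   vector from [evaluate_predictions()]), `test_probs`, `test_labels`.
#' @export
train_fold <- function(bags, split, model, config = mil_config()) {
  fit <- mil_fit(bags[split$train_idx], model = model, config = config,
                 val_bags = if (length(split$val_idx)) bags[split$val_idx])
  test_bags <- bags[split$test_idx]
  probs <- predict(fit, test_bags, type = "prob")
  labels <- bag_labels(test_bags)
  list(
    fit = fit,
    metrics = evaluate_predictions(labels, probs),
    test_probs = probs,
    test_labels = labels
  )
}

#' Stratified k-fold cross-validation of a MIL model
#'
#' Runs the full protocol: disjoint stratified test folds, 8:1 stratified
#' train/validation split of the remainder, class-weighted sampling,
#' validation-loss model selection, one test evaluation per fold.
#'
#' @param bags List of labeled [feature_bag()] objects.
#' @param model One of `"mipcl"`, `"abmil"`, `"clam"`.
#' @param k Number of folds (default 10).
#' @param config A [mil_config()].
#' @param seed Seed for the fold splits (and, via `config$seed` offsets,
#'   per-fold training randomness).
#' @param keep_fits Keep the fitted models (default FALSE to save memory).
#' @return An object of class `mil_cv`: list with `metrics` (k x 4 data
#'   frame), `mean_metrics`, `folds`, `model`, and optionally `fits`.
#' @export
mil_cv <- function(bags, model = c("mipcl", "abmil", "clam"), k = 10L,
                   config = mil_config(), seed = 1L, keep_fits = FALSE) {
  model <- match.arg(model)
  labels <- bag_labels(bags)
  folds <- stratified_kfold(labels, k = k, seed = seed)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config
    cfg$seed <- as.integer((if (is.null(config$seed)) seed else config$seed) + f)
    res[[f]] <- train_fold(bags, folds[[f]], model, cfg)
  }
  metrics <- as.data.frame(do.call(rbind, lapply(res, `[[`, "metrics")))
  metrics <- cbind(fold = seq_len(k) - 1L, metrics)
  structure(
    list(
      model = model,
      metrics = metrics,
      mean_metrics = colMeans(metrics[, -1L, drop = FALSE]),
      folds = folds,
      fits = if (keep_fits) lapply(res, `[[`, "fit"),
      test_probs = lapply(res, `[[`, "test_probs"),
      test_labels = lapply(res, `[[`, "test_labels")
    ),
    class = "mil_cv"
  )
}

#' @export
print.mil_cv <- function(x, ...) {
  cat(sprintf("<mil_cv> %s, %d folds\n", toupper(x$model), nrow(x$metrics)))
  m <- x$mean_metrics
  cat(sprintf("  balanced accuracy %.3f | weighted F1 %.3f | AUROC %.3f | AUPRC %.3f\n",
              m["balanced_accuracy"], m["weighted_f1"],
              m["weighted_auroc"], m["weighted_auprc"]))
  invisible(x)
}

#' @export
summary.mil_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$metrics, row.names = FALSE, digits = 3)
  invisible(object)
}

## --- Paired model comparison ----------------------------------------------

## Two-sided Wilcoxon signed-rank p-value with classic zero handling:
## zero differences are dropped; if all differences are zero the p-value is
## 1. The exact distribution is used for n <= 25 when |differences| are
## untied, otherwise the normal approximation with continuity correction.
wilcoxon_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) return(1.0)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value
  )
}

## Percentile bootstrap CI of the mean of a per-fold metric vector.
bootstrap_ci <- function(x, n_boot = 1e4, conf = 0.95) {
  if (length(unique(x)) == 1L) {
    return(c(lower = x[1], upper = x[1]))
  }
  means <- vapply(seq_len(n_boot), function(i) {
    mean(sample(x, length(x), replace = TRUE))
  }, numeric(1))
  qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(lower = qs[1], upper = qs[2])
}

#' Compare two models' per-fold metrics
#'
#' Paired two-sided Wilcoxon signed-rank tests over the fold metrics (one
#' test per metric, zero differences dropped, p = 1 when all differences
#' are zero) and percentile bootstrap confidence intervals of each model's
#' mean metric, obtained by resampling folds. With only k folds the CIs
#' are necessarily wide; they quantify fold-level uncertainty, not
#' slide-level uncertainty.
#'
#' @param metrics_a,metrics_b Per-fold metric data frames (as in
#'   `mil_cv()$metrics`) or named-column matrices with equal fold counts;
#'   a bare numeric vector is treated as a single metric.
#' @param n_boot Bootstrap resamples (default 10^4).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List with `p_values` (named per metric), `ci_a`, `ci_b` (2-row
#'   matrices of lower/upper bounds per metric).
#' @export
compare_models <- function(metrics_a, metrics_b, n_boot = 1e4, seed = 1L,
                           conf = 0.95) {
  as_mat <- function(m) {
    if (is.vector(m) && is.numeric(m)) {
      matrix(m, ncol = 1L, dimnames = list(NULL, "metric"))
    } else {
      m <- as.data.frame(m)
      m <- m[, setdiff(colnames(m), "fold"), drop = FALSE]
      as.matrix(m)
    }
  }
  A <- as_mat(metrics_a)
  B <- as_mat(metrics_b)
  if (nrow(A) != nrow(B)) stop("fold counts differ between the two models")
  if (!identical(colnames(A), colnames(B))) {
    stop("metric columns differ between the two models")
  }
  set.seed(seed)
  p <- vapply(colnames(A), function(m) wilcoxon_signed_rank(A[, m], B[, m]),
              numeric(1))
  ci_a <- vapply(colnames(A), function(m) bootstrap_ci(A[, m], n_boot, conf),
                 numeric(2))
  ci_b <- vapply(colnames(B), function(m) bootstrap_ci(B[, m], n_boot, conf),
                 numeric(2))
  list(p_values = p, ci_a = ci_a, ci_b = ci_b)
}
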