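# Cross-validation harness, sampling weights, metrics, statistics.

test_that("stratified folds partition the data with exact class arithmetic", {
  labels <- c(rep(1, 80), rep(0, 20))
  folds <- stratified_kfold(labels, k = 10, seed = 4)
  expect_length(folds, 10L)
  all_test <- unlist(lapply(folds, `[[`, "test_idx"))
  expect_identical(sort(all_test), 1:100)     # disjoint union covers all
  for (f in folds) {
    expect_identical(sum(labels[f$test_idx] == 1), 8L)
    expect_identical(sum(labels[f$test_idx] == 0), 2L)
    expect_identical(sum(labels[f$val_idx] == 1), 8L)
    expect_identical(sum(labels[f$val_idx] == 0), 2L)
    expect_identical(sum(labels[f$train_idx] == 1), 64L)
    expect_identical(sum(labels[f$train_idx] == 0), 16L)
    # no index in two roles
    expect_length(intersect(f$train_idx, f$val_idx), 0L)
    expect_length(intersect(f$train_idx, f$test_idx), 0L)
    expect_length(intersect(f$val_idx, f$test_idx), 0L)
    expect_identical(sort(c(f$train_idx, f$val_idx, f$test_idx)), 1:100)
  }
  expect_identical(stratified_kfold(labels, k = 10, seed = 4), folds)
  expect_error(stratified_kfold(c(rep(1, 95), rep(0, 5)), k = 10),
               "at least k")
})

test_that("sampler weights invert class frequency and balance draws", {
  labels <- c(rep(1, 75), rep(0, 25))
  w <- sampler_weights(labels)
  expect_equal(sum(w), 1)
  expect_equal(w[labels == 0][1] / w[labels == 1][1], 3, tolerance = 1e-12)
  expect_equal(sampler_weights(rep(c(0, 1), 10)), rep(0.05, 20))
  expect_error(sampler_weights(rep(1, 5)), "both classes")
  # Monte-Carlo: sampled class frequency within 3 sigma of one half
  set.seed(20)
  draws <- sample(labels, 1e4, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws == 0) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("fold metrics match hand computations and sane limits", {
  # perfect predictions
  lab <- c(0, 0, 1, 1, 1)
  perfect <- cbind(1 - lab, lab)
  m <- evaluate_predictions(lab, perfect)
  expect_equal(unname(m), rep(1, 4))
  # label-independent scores have chance-level AUROC
  set.seed(21)
  lab2 <- rbinom(4000, 1, 0.5)
  sc2 <- runif(4000)
  expect_equal(auroc(lab2, sc2), 0.5, tolerance = 0.03)
  # fixed 10-prediction confusion case, F1 by hand:
  # truth: 6 pos, 4 neg; predictions flip one of each
  truth <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 1, 1, 0, 1, 0, 0, 0)
  probs <- cbind(1 - pred, pred)
  mm <- evaluate_predictions(truth, probs)
  prec1 <- 5 / 6; rec1 <- 5 / 6; f1_1 <- 2 * prec1 * rec1 / (prec1 + rec1)
  prec0 <- 3 / 4; rec0 <- 3 / 4; f1_0 <- 2 * prec0 * rec0 / (prec0 + rec0)
  expect_equal(unname(mm["weighted_f1"]), 0.6 * f1_1 + 0.4 * f1_0,
               tolerance = 1e-12)
  expect_equal(unname(mm["balanced_accuracy"]), (rec1 + rec0) / 2,
               tolerance = 1e-12)
  # single-class test sets are flagged undefined
  expect_warning(res <- evaluate_predictions(rep(1, 5), cbind(0.2, 0.8)),
                 "single class")
  expect_true(all(is.na(res)))
})

test_that("AUROC and AUPRC agree with independent implementations", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (i in 1:5) {
    lab <- rbinom(40, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- rnorm(40) + lab
    ref <- as.numeric(suppressMessages(pROC::auc(lab, sc)))
    expect_equal(auroc(lab, sc), ref, tolerance = 1e-10)
  }
  # AUPRC against direct enumeration on a tiny ranked case
  lab <- c(1, 0, 1, 0)
  sc <- c(0.9, 0.8, 0.7, 0.1)
  # thresholds descending: precisions 1/1, 1/2, 2/3 at recalls .5, .5, 1
  expect_equal(auprc(lab, sc), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
})

test_that("paired comparison reproduces exact Wilcoxon tails and degenerate CIs", {
  a <- c(0.91, 0.90, 0.93, 0.88, 0.92, 0.95, 0.89, 0.94, 0.90, 0.93)
  b <- a - c(0.021, 0.012, 0.033, 0.015, 0.024, 0.011, 0.026, 0.013, 0.031,
             0.025)
  res <- compare_models(a, b, n_boot = 2000, seed = 1)
  # all ten differences positive: exact two-sided tail 2 / 2^10
  expect_equal(unname(res$p_values), 2 / 1024, tolerance = 1e-12)
  # identical vectors: zero differences dropped, p = 1
  expect_equal(unname(compare_models(a, a, n_boot = 100, seed = 1)$p_values), 1)
  # constant metric vector: degenerate CI
  cst <- rep(0.9, 10)
  rc <- compare_models(cst, a, n_boot = 100, seed = 1)
  expect_equal(unname(rc$ci_a[, 1]), c(0.9, 0.9))
  # determinism
  r1 <- compare_models(a, b, n_boot = 500, seed = 7)
  r2 <- compare_models(a, b, n_boot = 500, seed = 7)
  expect_identical(r1, r2)
})

test_that("the OneCycle schedule warms up, peaks and anneals with cycled momentum", {
  lr_max <- 3e-4
  total <- 100
  lrs <- sapply(1:total, function(s) {
    cytomil:::onecycle_schedule(s, total, lr_max)$lr
  })
  moms <- sapply(1:total, function(s) {
    cytomil:::onecycle_schedule(s, total, lr_max)$momentum
  })
  expect_equal(max(lrs), lr_max, tolerance = 1e-10)
  expect_identical(which.max(lrs), 30L)               # pct_start = 0.3
  expect_lt(lrs[total], lr_max / 1000)                # annealed to ~lr/1e4
  expect_gt(lrs[1], 0)
  # momentum cycles inversely to the learning rate
  expect_identical(which.min(moms), 30L)
  expect_gt(moms[total], moms[30])
})

test_that("training separates classes and improves with class separation", {
  cfg <- mil_config(epochs = 20, seed = 2)
  aurocs <- sapply(c(0, 6), function(sep) {
    spec <- bag_spec(feature_dim = 10, bag_size_range = c(10, 20),
                     separation = sep, seed = 31)
    bags <- sample_dataset(spec, 60)
    folds <- stratified_kfold(vapply(bags, function(b) b$bag_label,
                                     integer(1)), k = 5, seed = 31)
    r <- train_fold(bags, folds[[1]], "abmil", cfg)
    unname(r$metrics["weighted_auroc"])
  })
  expect_lt(aurocs[1], 0.85)   # no signal at zero separation
  expect_gte(aurocs[2], 0.95)  # near-perfect at separation 6
  expect_gt(aurocs[2], aurocs[1])
})

test_that("model selection tracks the minimum validation loss", {
  spec <- bag_spec(feature_dim = 8, bag_size_range = c(5, 10), seed = 33)
  bags <- sample_dataset(spec, 30)
  cfg <- mil_config(embed_dim = 8, attn_dim = 4, groups = 2, epochs = 6,
                    patience = Inf, min_delta = 0, seed = 1)
  fit <- mil_fit(bags[1:24], "abmil", config = cfg, val_bags = bags[25:30])
  expect_identical(nrow(fit$history), 6L)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  # persisted checkpoints restore the identical model
  p <- tempfile(fileext = ".rds")
  save_mil_model(fit, p)
  back <- load_mil_model(p)
  expect_identical(predict(back, bags[1:3]), predict(fit, bags[1:3]))
  unlink(p)
})
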