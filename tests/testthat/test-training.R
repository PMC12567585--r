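test_that("focal loss matches its closed forms and is monotone in confidence", {
  expect_equal(focal_loss(matrix(c(0, 1), 1), 1L, gamma = 2), 0)
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, gamma = 0), log(2))
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, gamma = 2),
               0.25 * log(2))
  # gamma = 0 with unit weights is cross-entropy
  withr::with_seed(51, {
    p <- runif(20, 0.05, 0.95)
    probs <- cbind(1 - p, p)
    y <- rbinom(20, 1, 0.5)
    ce <- mean(-log(ifelse(y == 1, p, 1 - p)))
    expect_equal(focal_loss(probs, y, gamma = 0), ce, tolerance = 1e-12)
  })
  # strictly decreasing in p_y for fixed gamma > 0
  ps <- seq(0.01, 0.99, by = 0.01)
  losses <- sapply(ps, function(p)
    focal_loss(matrix(c(1 - p, p), 1), 1L, gamma = 2))
  expect_true(all(diff(losses) < 0))
  # per-class weights scale the per-sample terms
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, weights = c(1, 3),
                          gamma = 0), 3 * log(2))
})

test_that("inverse-frequency class weights are normalised to mean one", {
  w <- actimodal:::class_weights(c(rep(0L, 30), rep(1L, 10)), "inverse")
  expect_equal(mean(w), 1)
  expect_equal(w[2] / w[1], 3)
  expect_equal(actimodal:::class_weights(c(0L, 1L), "none"), c(1, 1))
})

test_that("subject split follows largest-remainder stratification", {
  ids <- sprintf("P%02d", 1:50)
  labels <- c(rep(1L, 13), rep(0L, 37))
  sp <- subject_split(ids, labels, c(0.55, 0.15, 0.30), seed = 4)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 27L, val = 8L, test = 15L))
  pos <- function(set) sum(labels[match(set, ids)])
  expect_equal(c(pos(sp$train), pos(sp$val), pos(sp$test)), c(7, 2, 4))
  # disjoint and exhaustive
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_ids), sort(ids))
  expect_equal(anyDuplicated(all_ids), 0L)
  # degenerate fractions: everyone trains
  sp1 <- subject_split(ids, labels, c(1, 0, 0), seed = 1)
  expect_equal(sort(sp1$train), sort(ids))
  expect_length(sp1$val, 0)
  # deterministic given the seed
  expect_identical(subject_split(ids, labels, seed = 4), sp)
  expect_false(identical(subject_split(ids, labels, seed = 5)$train, sp$train))
  expect_error(subject_split(c("a", "b", "c"), c(1L, 0L, 0L)),
               "fewer than")
})

test_that("stratified k-fold partitions subjects with balanced classes", {
  ids <- sprintf("P%02d", 1:50)
  labels <- c(rep(1L, 13), rep(0L, 37))
  folds <- stratified_kfold(ids, labels, k = 10, seed = 2)
  expect_equal(sort(names(folds)), sort(ids))
  expect_equal(as.integer(table(folds)), rep(5L, 10))   # folds of size 5
  pos_per_fold <- tapply(labels[match(names(folds), ids)], folds, sum)
  expect_true(all(pos_per_fold %in% 1:2))           # 13 positives, 10 folds
  expect_error(stratified_kfold(ids, labels, k = 20), "< k")
  expect_identical(stratified_kfold(ids, labels, k = 5, seed = 9),
                   stratified_kfold(ids, labels, k = 5, seed = 9))
})

test_that("confusion metrics agree with the formula oracle", {
  m <- compute_metrics(TP = 50, TN = 50, FP = 0, FN = 0)
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                            mcc = 1))
  m2 <- compute_metrics(TP = 25, TN = 25, FP = 25, FN = 25)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mcc, 0)
  withr::with_seed(52, {
    for (i in 1:100) {
      cnt <- rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1))
      got <- suppressWarnings(compute_metrics(TP = cnt[1], TN = cnt[2],
                                              FP = cnt[3], FN = cnt[4]))
      want <- metric_oracle(cnt[1], cnt[2], cnt[3], cnt[4])
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  })
  expect_error(compute_metrics(TP = -1), "negative")
  # no predicted positives: precision, f1 and mcc all degrade to 0, each
  # with its own warning
  w <- capture_warnings(m3 <- compute_metrics(TP = 0, TN = 5, FP = 0, FN = 2))
  expect_length(w, 3)
  expect_match(w, "precision|f1|mcc", all = TRUE)
  expect_equal(c(m3$precision, m3$f1, m3$mcc), c(0, 0, 0))
})

test_that("trapezoidal AUC equals the midrank Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(53, {
    for (i in 1:30) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
      expect_equal(roc_auc(s, y), auc_rank_oracle(s, y), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(54, {
    y <- rbinom(80, 1, 0.4)
    s <- round(rnorm(80), 1)
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("training machinery honours the learning rate and converges on separable data", {
  # zero learning rate leaves every parameter untouched
  samples <- random_samples(n = 6)
  model <- build_model(tiny_model_config(6, "simple_concat"), seed = 12)
  m0 <- train_model(model, samples,
                    cfg = train_config(epochs = 1, learning_rate = 0,
                                       weight_decay = 0, batch_size = 3))
  expect_identical(m0$params, model$params)
  expect_true(all(is.finite(m0$history$train_loss)))
  # linearly separable tabular signal: concat fusion fits it in 20 epochs
  withr::with_seed(55, {
    n <- 16
    ids <- sprintf("T%03d", seq_len(n))
    labs <- stats::setNames(rep(c(0L, 1L), each = n / 2), ids)
    feat <- matrix(rnorm(n * 4, sd = 0.3), n, dimnames = list(ids, NULL))
    feat[, 1] <- feat[, 1] + ifelse(labs == 1L, 3, -3)
    seqs <- lapply(ids, random_sequence)
    toy <- build_samples(seqs, feat, labs, vit_config_tiny())
  })
  m1 <- train_model(build_model(tiny_model_config(4, "simple_concat"),
                                seed = 13),
                    toy, cfg = tiny_train_config(epochs = 20, batch_size = 8))
  pred <- predict_model(m1, toy)
  expect_gte(mean(pred$pred == pred$label), 0.95)
})

test_that("training history tracks validation and retains the best epoch", {
  samples <- random_samples(n = 8)
  model <- build_model(tiny_model_config(6), seed = 14)
  fit <- train_model(model, samples[1:6], samples[7:8],
                     cfg = tiny_train_config(epochs = 3, batch_size = 4))
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_length(fit$class_weights, 2)
})
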