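# Folds, the training loop and cross-validation mechanics.
# Training runs here use a deliberately small surrogate corpus and few
# epochs; they exercise mechanics, not headline accuracy.

test_that("stratified folds partition every class evenly", {
  y <- rep(0:2, c(50, 45, 30))
  fs <- make_folds(y, k = 10, seed = 4)
  # partition: disjoint, exhaustive
  all_idx <- sort(unlist(fs$test_indices))
  expect_identical(all_idx, seq_along(y))
  expect_equal(sum(lengths(fs$test_indices)), length(y))
  # per-class counts per fold within one of each other
  for (cl in 0:2) {
    counts <- vapply(fs$test_indices,
                     function(ix) sum(y[ix] == cl), 1L)
    expect_lte(diff(range(counts)), 1L)
  }
  # determinism
  fs2 <- make_folds(y, k = 10, seed = 4)
  expect_identical(fs$assignment, fs2$assignment)
  fs3 <- make_folds(y, k = 10, seed = 5)
  expect_false(identical(fs$assignment, fs3$assignment))
  expect_error(make_folds(rep(0:1, c(5, 50)), k = 10, seed = 1), "fewer")
})

test_that("2300 segments per class split into folds of 230", {
  y <- rep(0:1, each = 2300)
  fs <- make_folds(y, k = 10, seed = 1)
  for (ix in fs$test_indices) {
    expect_equal(length(ix), 460L)
    expect_equal(sum(y[ix] == 0), 230L)
  }
})

test_that("training is reproducible and tracks the best checkpoint", {
  tab <- tiny_corpus(n_rec = 3, sets = c("A", "E"), seed = 31,
                     separability = 3)
  task <- build_task_dataset(tab, "A-E")
  cfg <- train_config(epochs = 3, seed = 11, batch_size = 32)
  f1 <- mnlnet(task, config = cfg)
  f2 <- mnlnet(task, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$best_val_accuracy, max(f1$history$val_accuracy))
  expect_equal(f1$history$val_accuracy[f1$best_epoch],
               f1$best_val_accuracy)
  # a separable task at this contrast is learned quickly
  expect_gte(f1$best_val_accuracy, 0.9)
})

test_that("the learning rate only decays, by the configured factor at plateaus", {
  # constant labels force the validation accuracy to saturate immediately,
  # so every later epoch is a non-improvement and the schedule must fire
  # every `patience` epochs
  set.seed(2)
  x <- matrix(rnorm(60 * 178), 60)
  y <- rep(0:1, 30)
  cfg <- train_config(epochs = 8, seed = 3, patience = 2, batch_size = 30,
                      val_fraction = 0.2)
  fit <- mnlnet(x, y, config = cfg)
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  drops <- lr[-1] / head(lr, -1)
  expect_true(all(abs(drops[drops < 1] - 0.1) < 1e-12))
  # first epoch always runs at the initial rate
  expect_equal(lr[1], 5e-4)
})

test_that("cross-validation reports k folds plus a consistent mean", {
  tab <- tiny_corpus(n_rec = 3, sets = c("A", "E"), seed = 17,
                     separability = 3)
  cfg <- train_config(epochs = 2, seed = 5, batch_size = 32)
  rep1 <- cross_validate(tab, "A-E", k = 3, config = cfg)
  expect_s3_class(rep1, "eval_report")
  expect_equal(ncol(rep1$folds), 3L)
  expect_equal(nrow(rep1$folds), 5L)
  expect_equal(rep1$mean, rowMeans(rep1$folds), tolerance = 1e-9)
  expect_true(all(rep1$folds >= 0 & rep1$folds <= 1))
  # identical seed and config reproduce the report exactly
  rep2 <- cross_validate(tab, "A-E", k = 3, config = cfg)
  expect_identical(rep1$folds, rep2$folds)
})

test_that("validation slices are stratified and never touch the test fold", {
  y <- rep(0:1, each = 40)
  set.seed(1)
  val <- mnlnet:::stratified_holdout(y, 0.1)
  expect_equal(sum(y[val] == 0), 4L)
  expect_equal(sum(y[val] == 1), 4L)
  expect_error(mnlnet:::stratified_holdout(rep(0:1, c(1, 30)), 0.4),
               "consume")
  # fold bookkeeping: each test fold is disjoint from its training rows
  fs <- make_folds(y, k = 4, seed = 2)
  for (f in 1:4) {
    test_idx <- fs$test_indices[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    expect_length(intersect(test_idx, train_idx), 0L)
  }
})
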