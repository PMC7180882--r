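test_that("one-hot encoding uses the fixed AF/Normal/Noisy/Other order", {
  expect_equal(as.numeric(one_hot("AF")), c(1, 0, 0, 0))
  expect_equal(as.numeric(one_hot("Normal")), c(0, 1, 0, 0))
  expect_equal(as.numeric(one_hot("Noisy")), c(0, 0, 1, 0))
  expect_equal(as.numeric(one_hot("Other")), c(0, 0, 0, 1))
  m <- one_hot(c("Other", "AF", "Other"))
  expect_equal(rowSums(m), rep(1, 3))
  expect_error(one_hot("Sinus"), "unknown label")
})

test_that("cross-entropy matches its closed forms", {
  # perfect prediction
  expect_equal(cross_entropy(one_hot("AF"), one_hot("AF")), 0,
               tolerance = 1e-10)
  # uniform prediction: -log(1/4)
  expect_equal(cross_entropy(one_hot("Noisy"), matrix(0.25, 1, 4)), log(4))
  # batch mean of the two
  truth <- one_hot(c("AF", "Noisy"))
  pred <- rbind(c(1, 0, 0, 0), rep(0.25, 4))
  expect_equal(cross_entropy(truth, pred), log(4) / 2)
  expect_error(cross_entropy(one_hot("AF"), matrix(0.25, 2, 4)),
               "same shape")
})

test_that("stratified folds are balanced exactly on divisible classes", {
  labels <- rep(af_classes(), each = 25)
  fs <- stratified_kfold(labels, k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(unname(table(labels[fs$assignments == f])),
                 rep(5L, 4), ignore_attr = TRUE)
  }
})

test_that("stratification holds within one segment on imbalanced classes", {
  # the class balance of the pre-processed Challenge segments
  withr::with_seed(5, {
    labels <- sample(rep(af_classes(), c(903, 5959, 299, 2990)))
  })
  k <- 5
  fs <- stratified_kfold(labels, k, seed = 9)
  sizes <- table(fs$assignments)
  expect_lte(max(sizes) - min(sizes), 1)
  for (cl in af_classes()) {
    per_fold <- table(factor(fs$assignments[labels == cl], levels = 1:k))
    expected <- sum(labels == cl) / k
    expect_true(all(abs(per_fold - expected) <= 1), info = cl)
  }
  # determinism
  fs2 <- stratified_kfold(labels, k, seed = 9)
  expect_identical(fs$assignments, fs2$assignments)
  # a class smaller than k is rejected
  expect_error(stratified_kfold(c("AF", rep("Normal", 10)), k = 3),
               "fewer than k")
})

test_that("a small network memorizes a separable toy set", {
  ds <- toy_segments(n_per_class = 15, seed = 4)
  m <- build_network(tiny_spec(), seed = 4)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 20, epochs = 30,
                      seed = 4, target_train_acc = 1)
  m <- fit(m, ds, cfg)
  expect_true(all(is.finite(m$history$loss)))
  expect_gte(m$history$accuracy[nrow(m$history)], 0.95)
  # loss decreased over training
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
})

test_that("training is deterministic given the seed", {
  ds <- toy_segments(n_per_class = 5, seed = 8)
  run <- function() {
    m <- build_network(tiny_spec(dropout = 0.3), seed = 21)
    m <- fit(m, ds, train_config(learning_rate = 1e-3, batch_size = 10,
                                 epochs = 3, seed = 21))
    m$history$loss
  }
  expect_identical(run(), run())
})

test_that("a vanishing learning rate leaves parameters unchanged", {
  ds <- toy_segments(n_per_class = 3, seed = 2)
  m <- build_network(tiny_spec(), seed = 2)
  before <- afdetect1d:::net_get_params(m$handle)
  m <- fit(m, ds, train_config(learning_rate = 1e-12, batch_size = 12,
                               epochs = 1, seed = 2))
  after <- afdetect1d:::net_get_params(m$handle)
  expect_lt(max(abs(after - before)), 1e-9)
})

test_that("inference is deterministic after training (dropout off)", {
  ds <- toy_segments(n_per_class = 4, seed = 6)
  m <- build_network(tiny_spec(dropout = 0.5), seed = 6)
  m <- fit(m, ds, train_config(learning_rate = 1e-3, batch_size = 16,
                               epochs = 2, seed = 6))
  p1 <- predict(m, ds)
  p2 <- predict(m, ds)
  expect_identical(p1$probs, p2$probs)
})

test_that("validation monitoring and early stopping are recorded", {
  ds <- toy_segments(n_per_class = 6, seed = 9)
  val <- toy_segments(n_per_class = 3, seed = 10)
  m <- build_network(tiny_spec(), seed = 9)
  m <- fit(m, ds, train_config(learning_rate = 1e-3, batch_size = 12,
                               epochs = 4, seed = 9, patience = 2),
           validation = val)
  expect_true(all(c("val_loss", "val_accuracy") %in% names(m$history)))
  expect_lte(nrow(m$history), 4)
})
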