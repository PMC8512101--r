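test_that("metrics reproduce their defining ratios from counts", {
  r <- eval_metrics(50, 30, 10, 10)
  expect_equal(r$acc, 0.80)
  expect_equal(r$sn, 0.8333, tolerance = 1e-4)
  expect_equal(r$sp, 0.75)
  expect_equal(r$pr, 0.8333, tolerance = 1e-4)
  perfect <- eval_metrics(40, 60, 0, 0)
  expect_equal(c(perfect$acc, perfect$sn, perfect$sp, perfect$pr),
               c(1, 1, 1, 1))
  expect_equal(eval_metrics(0, 0, 25, 25)$acc, 0)
  # property: metrics recompute from any random count quadruple
  set.seed(30)
  for (i in 1:50) {
    q <- rpois(4, 20)
    m <- eval_metrics(q[1], q[2], q[3], q[4])
    expect_equal(sum(m$counts), sum(q))
    expect_equal(m$acc, (q[1] + q[2]) / sum(q))
    if (q[1] + q[4] > 0) expect_equal(m$sn, q[1] / (q[1] + q[4]))
    if (q[2] + q[3] > 0) expect_equal(m$sp, q[2] / (q[2] + q[3]))
    if (q[1] + q[3] > 0) expect_equal(m$pr, q[1] / (q[1] + q[3]))
  }
  expect_true(is.na(eval_metrics(0, 5, 0, 0)$sn))   # zero denominator
  expect_error(eval_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("stratified split allocates proportionally and deterministically", {
  x <- lapply(1:100, function(i) matrix(rnorm(4), 1))
  ds <- labeled_dataset(x, rep(c(0L, 1L), c(60, 40)))
  sp <- stratified_split(ds, split_spec(0.7, 0.1, 0.2, seed = 5))
  expect_equal(length(sp$train$x), 70)
  expect_equal(length(sp$val$x), 10)
  expect_equal(length(sp$test$x), 20)
  expect_equal(as.integer(table(sp$train$y)), c(42, 28))
  expect_equal(as.integer(table(sp$val$y)), c(6, 4))
  expect_equal(as.integer(table(sp$test$y)), c(12, 8))
  # partition: disjoint and covering
  all_idx <- sort(unname(unlist(sp$indices)))
  expect_equal(all_idx, 1:100)
  # determinism
  sp2 <- stratified_split(ds, split_spec(0.7, 0.1, 0.2, seed = 5))
  expect_identical(sp$indices, sp2$indices)
  sp3 <- stratified_split(ds, split_spec(0.7, 0.1, 0.2, seed = 6))
  expect_false(identical(sp$indices, sp3$indices))
  # a class too small to reach every subset
  tiny <- labeled_dataset(x[1:20], rep(c(0L, 1L), c(18, 2)))
  expect_error(stratified_split(tiny, split_spec(0.7, 0.1, 0.2)),
               "too few")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
  expect_error(split_spec(0.0, 0.5, 0.5), "strictly")
})

test_that("LSTM gradients agree with finite differences", {
  ns <- asNamespace("semgfatigue")
  set.seed(31)
  X <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  y <- c(0L, 1L, 1L, 0L)
  params <- ns$lstm_init(2L, 5L, 4L)
  params <- lapply(params, function(p) p + rnorm(length(p), sd = 0.05))
  fw <- ns$lstm_forward(params, X, dropout = 0, training = TRUE)
  gr <- ns$lstm_backward(params, fw, y)
  for (nm in names(params)) {
    for (idx in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      eps <- 1e-6
      up <- params; up[[nm]][idx] <- up[[nm]][idx] + eps
      dn <- params; dn[[nm]][idx] <- dn[[nm]][idx] - eps
      num <- (ns$lstm_loss(ns$lstm_forward(up, X)$P, y) -
                ns$lstm_loss(ns$lstm_forward(dn, X)$P, y)) / (2 * eps)
      expect_equal(gr[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("CNN gradients agree with finite differences", {
  ns <- asNamespace("semgfatigue")
  set.seed(32)
  X <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  y <- c(1L, 0L, 1L, 0L)
  params <- ns$cnn_init(3L, 5L, cnn_config(filters1 = 3L, filters2 = 4L,
                                           fc_units = 5L))
  # jitter every parameter so no ReLU input sits exactly on its kink
  params <- lapply(params, function(p) p + rnorm(length(p), sd = 0.05))
  fw <- ns$cnn_forward(params, X, training = TRUE)
  gr <- ns$cnn_backward(params, fw, y)
  for (nm in names(params)) {
    for (idx in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      eps <- 1e-6
      up <- params; up[[nm]][idx] <- up[[nm]][idx] + eps
      dn <- params; dn[[nm]][idx] <- dn[[nm]][idx] - eps
      num <- (ns$lstm_loss(ns$cnn_forward(up, X)$P, y) -
                ns$lstm_loss(ns$cnn_forward(dn, X)$P, y)) / (2 * eps)
      expect_equal(gr[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("LSTM training is seeded-deterministic and learns separable data", {
  ds <- generate_feature_dataset(60, 3, seed = 33)
  sp <- stratified_split(ds, split_spec(seed = 33))
  cfg <- lstm_config(epochs = 8L, seed = 33)
  m1 <- train_lstm(sp$train, sp$val, cfg)
  m2 <- train_lstm(sp$train, sp$val, cfg)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$params, m2$params)
  m <- train_lstm(sp$train, sp$val, lstm_config(epochs = 30L, seed = 33))
  expect_gte(evaluate_model(m, sp$test)$acc, 0.95)
  # single-class training set refused
  ones <- labeled_dataset(ds$x[ds$y == 1L], ds$y[ds$y == 1L])
  expect_error(train_lstm(ones, sp$val, cfg), "both classes")
})

test_that("SGDM optimizer variant trains the LSTM too", {
  ds <- generate_feature_dataset(60, 3, seed = 34)
  sp <- stratified_split(ds, split_spec(seed = 34))
  m <- train_lstm(sp$train, sp$val,
                  lstm_config(epochs = 40L, optimizer = "sgdm",
                              learning_rate = 0.05, seed = 34))
  expect_gte(evaluate_model(m, sp$test)$acc, 0.9)
})

test_that("CNN and SVM baselines learn separable data deterministically", {
  ds <- generate_feature_dataset(80, 3, seed = 35)
  sp <- stratified_split(ds, split_spec(seed = 35))
  c1 <- train_cnn(sp$train, sp$val, cnn_config(epochs = 25L, seed = 35))
  c2 <- train_cnn(sp$train, sp$val, cnn_config(epochs = 25L, seed = 35))
  expect_identical(c1$params, c2$params)
  expect_gte(evaluate_model(c1, sp$test)$acc, 0.90)
  s1 <- train_svm(sp$train)
  s2 <- train_svm(sp$train)
  expect_gte(evaluate_model(s1, sp$test)$acc, 0.90)
  expect_identical(predict_fatigue(s1, sp$test), predict_fatigue(s2, sp$test))
  expect_error(train_svm(labeled_dataset(ds$x[ds$y == 0L],
                                         ds$y[ds$y == 0L])),
               "both classes")
})

test_that("length-1 sequences reduce to per-window classification", {
  ds <- generate_feature_dataset(60, 3, seed = 36, seq_len = 1)
  expect_equal(nrow(ds$x[[1]]), 1)
  sp <- stratified_split(ds, split_spec(seed = 36))
  m <- train_lstm(sp$train, sp$val, lstm_config(units = 20L, fc_units = 8L,
                                                epochs = 30L, seed = 36))
  expect_gte(evaluate_model(m, sp$test)$acc, 0.9)
})
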