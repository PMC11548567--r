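test_that("allocated weights agree with the arithmetic parameter count", {
  m <- build_cnn(default_arch())
  expect_equal(m$param_count, total_params(default_arch()))

  # property: agreement holds across random architectures
  set.seed(41)
  for (i in 1:10) {
    n_blocks <- sample(1:3, 1)
    layers <- list()
    for (b in seq_len(n_blocks)) {
      layers <- c(layers, list(conv1d(sample(2:8, 1), sample(c(3, 5, 7), 1)),
                               maxpool1d(sample(2:3, 1))))
    }
    layers <- c(layers, list(flatten(), dense(sample(c(8, 16, 32), 1)),
                             dense(4, activation = "softmax")))
    arch <- arch_spec(sample(c(128, 256), 1), layers)
    expect_equal(build_cnn(arch)$param_count, total_params(arch))
  }
})

test_that("forward passes emit normalised probability rows of the right shape", {
  arch <- tiny_arch()
  m <- build_cnn(arch)
  X1 <- matrix(rnorm(64), 1)
  p1 <- predict(m, X1)
  expect_equal(dim(p1), c(1L, 4L))
  expect_equal(sum(p1), 1, tolerance = 1e-6)

  Xn <- matrix(rnorm(7 * 64), 7)
  pn <- predict(m, Xn)
  expect_equal(dim(pn), c(7L, 4L))
  expect_equal(rowSums(pn), rep(1, 7), tolerance = 1e-6)
  expect_true(all(pn >= 0))

  cls <- predict(m, Xn, type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), class_levels())

  expect_error(predict(m, matrix(rnorm(10), 1)), "expects")
})

test_that("focal loss generalises cross-entropy and matches hand arithmetic", {
  p <- matrix(c(0.5, 0.5), 1)
  t0 <- matrix(c(1, 0), 1)
  expect_equal(focal_loss(p, t0, gamma = 2), 0.25 * (-log(0.5)))
  expect_equal(focal_loss(p, t0, gamma = 0), -log(0.5))

  set.seed(42)
  P <- matrix(runif(20), 5); P <- P / rowSums(P)
  Tm <- diag(4)[sample(1:4, 5, TRUE), ]
  ce <- mean(-log(rowSums(P * Tm)))
  expect_equal(focal_loss(P, Tm, gamma = 0), ce)

  perfect <- diag(4)[c(1, 2), ]
  expect_equal(focal_loss(perfect, diag(4)[c(1, 2), ], gamma = 2), 0)
  expect_warning(focal_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1), gamma = 0),
                 "clipping")
  expect_error(focal_loss(matrix(c(0.2, 0.2), 1), matrix(c(1, 0), 1)), "sum to 1")
})

test_that("training is deterministic under a fixed seed and learns separable data", {
  dm <- random_dm(n_per_class = 10, len = 64, seed = 43, sdev = 0.3)
  parts <- split_train_test(dm, preprocess_config(model_input_samples = 64,
                                                  cycle_truncation_s = 1, target_rate = 64,
                                                  seed = 43))
  cfg <- train_config(epochs = 15, batch_size = 8, learning_rate = 0.005, seed = 7)
  m1 <- train_cnn(build_cnn(tiny_arch(), cfg), parts$train, parts$test, cfg)
  m2 <- train_cnn(build_cnn(tiny_arch(), cfg), parts$train, parts$test, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_gte(max(m1$history$val_acc), 0.9)

  cfg2 <- train_config(epochs = 15, batch_size = 8, learning_rate = 0.005, seed = 8)
  m3 <- train_cnn(build_cnn(tiny_arch(), cfg2), parts$train, parts$test, cfg2)
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("zero-epoch training returns the untrained model with empty history", {
  dm <- random_dm(n_per_class = 3, len = 64, seed = 44)
  cfg <- train_config(epochs = 0)
  m <- build_cnn(tiny_arch(), cfg)
  fitted <- train_cnn(m, dm, cfg = cfg)
  expect_false(fitted$trained)
  expect_equal(nrow(fitted$history), 0)
  expect_identical(fitted$params, m$params)
})

test_that("focal loss can drive training end to end", {
  dm <- random_dm(n_per_class = 8, len = 64, seed = 45, sdev = 0.3)
  cfg <- train_config(epochs = 10, batch_size = 8, learning_rate = 0.005,
                      loss = "focal", focal_gamma = 2, seed = 1)
  m <- train_cnn(build_cnn(tiny_arch(), cfg), dm, cfg = cfg)
  expect_gte(m$history$train_acc[10], 0.7)
  expect_true(all(is.finite(m$history$train_loss)))
})

test_that("model tidiers expose the training history long-form", {
  dm <- random_dm(n_per_class = 4, len = 64, seed = 46)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 1)
  m <- train_cnn(build_cnn(tiny_arch(), cfg), dm, dm, cfg)
  td <- tidy(m)
  expect_setequal(unique(td$split), c("train", "val"))
  expect_setequal(unique(td$metric), c("loss", "acc"))
  expect_equal(nrow(td), 3 * 4)
  g <- glance(m)
  expect_true(g$trained)
  expect_equal(g$epochs, 3L)
})
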