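zero_lstm_params <- function(input_dim, units) {
  p <- random_lstm_params(input_dim, units)
  p$U <- lapply(p$U, function(m) m * 0)
  p$W <- lapply(p$W, function(m) m * 0)
  p$b <- lapply(p$b, function(v) v * 0)
  p
}

test_that("lstm_step reproduces the analytic zero-parameter cases", {
  p <- zero_lstm_params(2L, 3L)
  st0 <- lstm_zero_state(3L)
  out <- lstm_step(c(1, -1), st0, p)
  expect_equal(out$h, rep(0, 3))
  expect_equal(out$c, rep(0, 3))

  # zero params, nonzero previous cell: gates 0.5, candidate 0
  cprev <- c(0.4, -1, 2)
  out2 <- lstm_step(c(1, -1), list(h = rep(0, 3), c = cprev), p)
  expect_equal(out2$c, 0.5 * cprev)
  expect_equal(out2$h, 0.5 * tanh(0.5 * cprev))
})

test_that("lstm_step matches the scalar-loop oracle on random instances", {
  set.seed(202)
  for (rep in 1:40) {
    p <- random_lstm_params(2L, 3L)
    x <- rnorm(2)
    st <- list(h = rnorm(3, sd = 0.5), c = rnorm(3))
    got <- lstm_step(x, st, p)
    want <- oracle_lstm_step(x, st$h, st$c, p)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
  }
})

test_that("cell magnitudes respect the gate bounds", {
  set.seed(17)
  for (rep in 1:20) {
    p <- random_lstm_params(3L, 4L)
    st <- list(h = rnorm(4, sd = 0.5), c = rnorm(4))
    out <- lstm_step(rnorm(3), st, p)
    expect_true(all(abs(out$c) <= abs(st$c) + 1))
    expect_true(all(abs(out$h) <= 1))
  }
})

test_that("compiled sequence kernel agrees with repeated lstm_step calls", {
  set.seed(31)
  p <- random_lstm_params(1L, 5L)
  X <- matrix(rnorm(4 * 6), 4, 6)
  fwd <- ecgad:::.lstm_layer_forward(ecgad:::.seq_cube(X), p)
  st <- lstm_zero_state(5L, n = 4L)
  for (t in 1:6) st <- lstm_step(X[, t, drop = FALSE], st, p)
  expect_equal(fwd$H[, , 6], st$h, tolerance = 1e-14)
  expect_equal(fwd$C[, , 6], st$c, tolerance = 1e-14)
})

test_that("lstm_forward handles base cases and rejects empty sequences", {
  set.seed(23)
  l1 <- random_lstm_params(1L, 4L)
  l2 <- random_lstm_params(4L, 4L)
  x1 <- 0.7
  h1 <- lstm_step(x1, lstm_zero_state(4L), l1)
  manual <- lstm_step(h1$h, lstm_zero_state(4L), l2)$h
  expect_equal(lstm_forward(x1, l1, l2), manual, tolerance = 1e-12)

  z1 <- zero_lstm_params(1L, 4L)
  z2 <- zero_lstm_params(4L, 4L)
  expect_equal(lstm_forward(runif(10), z1, z2), rep(0, 4))
  expect_error(lstm_forward(matrix(0, 2, 0), l1, l2), "empty sequence")
})

test_that("classify_sequence is the head applied to the pooled summary", {
  set.seed(29)
  model <- structure(
    list(
      layer1 = random_lstm_params(1L, 4L),
      layer2 = random_lstm_params(4L, 4L),
      head = dense_layer(matrix(rnorm(4), 4, 1), rnorm(1), "sigmoid"),
      dropout_rate = 0.25, pooling = "mean"
    ),
    class = "lstm_model"
  )
  X <- matrix(runif(3 * 8), 3, 8)
  p <- classify_sequence(X, model)
  expect_true(all(p > 0 & p < 1))
  hP <- ecgad:::.lstm_summary(X, model$layer1, model$layer2, "mean")
  expect_equal(p, as.numeric(dense_forward(hP, model$head)))

  zero <- model
  zero$layer1 <- zero_lstm_params(1L, 4L)
  zero$layer2 <- zero_lstm_params(4L, 4L)
  zero$head <- dense_layer(matrix(0, 4, 1), 0, "sigmoid")
  expect_equal(classify_sequence(X, zero), rep(0.5, 3))
})

test_that("bce_loss matches closed forms and the scalar oracle", {
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  set.seed(44)
  for (rep in 1:20) {
    y <- rbinom(12, 1, 0.5)
    p <- runif(12)
    expect_equal(bce_loss(y, p), oracle_bce(y, p), tolerance = 1e-12)
  }
  expect_error(bce_loss(c(1, 0), 0.5), "length")
  expect_error(bce_loss(c(2, 0), c(0.5, 0.5)), "0/1")
})

test_that("LSTM training learns a small separable problem deterministically", {
  sp <- prepared_split(40, 20, seed = 13, series_length = 30L)
  train <- sp$train
  cfg <- train_config(epochs = 8L, batch_size = 16L, seed = 3L)
  fit <- train_lstm(train, cfg, units = 8L)
  expect_equal(nrow(fit$history), 8L)
  expect_lt(fit$history$loss[8], fit$history$loss[1])
  expect_identical(train_lstm(train, cfg, units = 8L)$history, fit$history)

  only_norm <- subset_normals(train)
  expect_error(train_lstm(only_norm, cfg), "both")
  expect_error(train_lstm(train, cfg, dropout_rate = 1), "dropout_rate")
})
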