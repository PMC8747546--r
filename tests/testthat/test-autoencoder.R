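test_that("dense_forward matches the scalar-loop oracle and validates shapes", {
  set.seed(101)
  for (rep in 1:30) {
    in_dim <- sample(1:6, 1)
    out_dim <- sample(1:5, 1)
    act <- sample(c("relu", "sigmoid", "linear"), 1)
    layer <- dense_layer(
      matrix(rnorm(in_dim * out_dim), in_dim, out_dim), rnorm(out_dim), act
    )
    x <- rnorm(in_dim)
    expect_equal(dense_forward(x, layer), oracle_dense(x, layer$W, layer$b, act),
      tolerance = 1e-12
    )
  }
  zl <- const_dense(3, 2, "relu")
  expect_equal(dense_forward(c(1, 2, 3), zl), c(0, 0))
  expect_equal(dense_forward(c(1, 2, 3), const_dense(3, 2, "sigmoid")), c(0.5, 0.5))
  expect_error(dense_forward(c(1, 2), zl), "expects 3")
  expect_error(dense_layer(matrix(0, 2, 2), 1, "relu"), "bias length")
})

test_that("dense_forward on a batch equals row-by-row application", {
  set.seed(7)
  layer <- dense_layer(matrix(rnorm(12), 4, 3), rnorm(3), "sigmoid")
  X <- matrix(rnorm(20), 5, 4)
  batch <- dense_forward(X, layer)
  for (i in 1:5) expect_equal(batch[i, ], dense_forward(X[i, ], layer))
})

test_that("encode composes the three dense layers and stays non-negative", {
  set.seed(3)
  enc <- withr::with_seed(3, encoder_params(input_dim = 12L))
  x <- runif(12)
  manual <- dense_forward(
    dense_forward(dense_forward(x, enc$layers[[1]]), enc$layers[[2]]),
    enc$layers[[3]]
  )
  expect_equal(encode(x, enc), manual)
  expect_length(manual, 8L)
  expect_true(all(encode(matrix(runif(36), 3), enc) >= 0))
})

test_that("attention score, gate and context behave per their algebra", {
  attn <- withr::with_seed(5, attention_params())
  z <- runif(8)
  expect_equal(
    attention_score(z, attn),
    as.numeric(z %*% attn$score_layer$W + attn$score_layer$b)
  )
  id <- attention_params()
  id$score_layer <- dense_layer(diag(8), rep(0, 8), "linear")
  expect_equal(attention_score(z, id), z)

  expect_equal(attention_gate(rep(0, 8)), rep(0.5, 8))
  expect_equal(attention_gate(log(3)), 0.75)
  expect_equal(attention_gate(50), 1, tolerance = 1e-12)
  sm <- attention_gate(rnorm(8), normalize = "softmax")
  expect_equal(sum(sm), 1)

  g <- attention_gate(rnorm(8))
  expect_equal(context_vector(g, z), g * z)
  expect_equal(context_vector(rep(1, 8) - 1e-15, z), z, tolerance = 1e-12)
  expect_equal(context_vector(rep(0, 8), z), rep(0, 8))
  expect_error(context_vector(g[1:4], z), "identical shape")
})

test_that("attention gates always shrink the latent vector", {
  set.seed(12)
  attn <- attention_params()
  for (rep in 1:20) {
    z <- encode(runif(12), withr::with_seed(rep, encoder_params(input_dim = 12L)))
    ctx <- context_vector(attention_gate(attention_score(z, attn)), z)
    expect_true(all(abs(ctx) <= abs(z) + 1e-15))
  }
})

test_that("decode maps through the stack into (0, 1)", {
  dec <- withr::with_seed(9, decoder_params(input_dim = 12L))
  c8 <- runif(8)
  manual <- dense_forward(
    dense_forward(dense_forward(c8, dec$layers[[1]]), dec$layers[[2]]),
    dec$layers[[3]]
  )
  expect_equal(decode(c8, dec), manual)
  expect_true(all(manual > 0 & manual < 1))
  zeros <- zero_ae_params()
  expect_equal(decode(c8, zeros$dec), rep(0.5, 12L))
})

test_that("mae_loss matches the scalar oracle", {
  x <- runif(10)
  expect_equal(mae_loss(x, x), 0)
  expect_equal(mae_loss(c(0, 1), c(1, 0)), 1)
  set.seed(8)
  for (rep in 1:20) {
    a <- rnorm(14)
    b <- rnorm(14)
    expect_equal(mae_loss(a, b), oracle_mae(a, b), tolerance = 1e-12)
  }
  expect_error(mae_loss(1:3, 1:4), "length")
  expect_equal(per_record_mae(rbind(a, a), rbind(b, a)), c(oracle_mae(a, b), 0))
})

test_that("cat_ae_forward equals its four stages composed by hand", {
  enc <- withr::with_seed(21, encoder_params(input_dim = 12L))
  attn <- withr::with_seed(22, attention_params())
  dec <- withr::with_seed(23, decoder_params(input_dim = 12L))
  x <- runif(12)
  out <- cat_ae_forward(x, enc, attn, dec)
  z <- encode(x, enc)
  g <- attention_gate(attention_score(z, attn))
  expect_equal(out$z, z)
  expect_equal(out$gates, g)
  expect_equal(out$context, g * z)
  expect_equal(out$xhat, decode(g * z, dec))

  zeros <- zero_ae_params()
  expect_equal(
    cat_ae_forward(x, zeros$enc, zeros$attn, zeros$dec)$xhat,
    rep(0.5, 12L)
  )
})

test_that("saturated gates reduce the attention model to the plain one", {
  enc <- withr::with_seed(31, encoder_params(input_dim = 12L))
  dec <- withr::with_seed(32, decoder_params(input_dim = 12L))
  sat <- attention_params()
  sat$score_layer <- dense_layer(matrix(0, 8, 8), rep(60, 8), "linear")
  x <- runif(12)
  expect_equal(
    cat_ae_forward(x, enc, sat, dec)$xhat,
    cat_ae_forward(x, enc, NULL, dec)$xhat,
    tolerance = 1e-10
  )
})

test_that("training drives the loss down and honors the normal-only contract", {
  base <- generate_beats(60, 0, noise_sd = 0.02, series_length = 24L, seed = 6)
  np <- fit_normalization(base)
  normals <- normalize_dataset(base, np)
  cfg <- train_config(epochs = 25L, batch_size = 16L, seed = 1L)
  fit <- train_autoencoder(normals, "cat_ae", cfg)
  expect_equal(nrow(fit$history), 25L)
  expect_lt(fit$history$loss[25], fit$history$loss[1])
  refit <- train_autoencoder(normals, "cat_ae", cfg)
  expect_identical(fit$history, refit$history)

  mixed <- generate_beats(10, 5, series_length = 24L, seed = 2)
  expect_error(train_autoencoder(mixed, "cat_ae", cfg), "normal beats only")
  empty <- normals[integer(0)]
  expect_error(train_autoencoder(empty, "ae", cfg), "empty")
})

test_that("an autoencoder memorizes identical beats to high precision", {
  proto <- apply_normalization(
    normal_prototype(20L), norm_params(-5, 2)
  )
  ds <- beat_dataset(
    matrix(proto, nrow = 24, ncol = 20, byrow = TRUE),
    rep(1L, 24), rep("normal", 24)
  )
  fit <- train_autoencoder(
    ds, "cat_ae",
    train_config(epochs = 220L, batch_size = 24L, seed = 4L)
  )
  expect_lt(fit$history$loss[220], 0.01)
})
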