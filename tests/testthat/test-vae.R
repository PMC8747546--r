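test_that("vae_encode computes both heads off the shared hidden layer", {
  enc <- withr::with_seed(41, vae_encoder_params(input_dim = 16L))
  x <- runif(16)
  h <- dense_forward(x, enc$hidden)
  post <- vae_encode(x, enc)
  expect_equal(post$mu, dense_forward(h, enc$mu_head))
  expect_equal(post$logvar, dense_forward(h, enc$logvar_head))
  expect_length(post$mu, 2L)

  zero <- vae_encoder_params(input_dim = 16L)
  zero$hidden <- const_dense(16, 32, "relu")
  zero$mu_head <- const_dense(32, 2, "linear")
  zero$logvar_head <- const_dense(32, 2, "linear")
  expect_equal(vae_encode(x, zero)$mu, c(0, 0))
  expect_equal(vae_encode(x, zero)$logvar, c(0, 0))
})

test_that("reparameterize is the affine map mu + exp(logvar/2) * eps", {
  mu <- c(0.3, -1)
  lv <- c(0.5, -0.2)
  expect_equal(reparameterize(mu, lv, c(0, 0))$z, mu)
  expect_equal(reparameterize(mu, c(0, 0), c(1, 1))$z, mu + 1)

  e1 <- rnorm(2)
  e2 <- rnorm(2)
  z <- function(e) reparameterize(mu, lv, e)$z
  expect_equal(z(e1) + z(e2) - z(c(0, 0)), z(e1 + e2), tolerance = 1e-12)
})

test_that("reparameterized samples have the advertised moments", {
  mu <- c(1.5, -0.5)
  lv <- c(0.4, -1)
  draws <- withr::with_seed(77, {
    eps <- matrix(rnorm(2e5), ncol = 2)
    t(apply(eps, 1, function(e) reparameterize(mu, lv, e)$z))
  })
  n <- nrow(draws)
  for (d in 1:2) {
    se_mean <- sqrt(exp(lv[d]) / n)
    expect_lt(abs(mean(draws[, d]) - mu[d]), 3 * se_mean)
    se_var <- exp(lv[d]) * sqrt(2 / (n - 1))
    expect_lt(abs(var(draws[, d]) - exp(lv[d])), 3 * se_var)
  }
})

test_that("kl_gaussian matches closed forms and the integration oracle", {
  expect_equal(kl_gaussian(c(0, 0), c(0, 0)), 0)
  expect_equal(kl_gaussian(c(1, 0), c(0, 0)), 0.5)
  set.seed(55)
  for (rep in 1:20) {
    mu <- rnorm(2)
    lv <- rnorm(2, sd = 0.8)
    expect_equal(kl_gaussian(mu, lv), oracle_kl(mu, lv), tolerance = 1e-10)
    expect_gte(kl_gaussian(mu, lv), 0)
  }
  # zero exactly (to numerical precision) only at the prior
  expect_lt(kl_gaussian(c(0, 0), c(0, 0)), 1e-12)
  expect_gt(kl_gaussian(c(1e-3, 0), c(0, 0)), 0)
  M <- matrix(rnorm(6), 3, 2)
  L <- matrix(rnorm(6, sd = 0.3), 3, 2)
  expect_equal(
    kl_gaussian(M, L),
    sapply(1:3, function(i) kl_gaussian(M[i, ], L[i, ]))
  )
})

test_that("vae_loss decomposes into reconstruction plus KL", {
  x <- runif(14)
  loss0 <- vae_loss(x, x, c(0, 0), c(0, 0))
  expect_equal(loss0$total, 0)
  set.seed(66)
  xh <- runif(14)
  mu <- rnorm(2)
  lv <- rnorm(2, sd = 0.5)
  l <- vae_loss(x, xh, mu, lv)
  expect_equal(l$recon, sum((xh - x)^2))
  expect_equal(l$kl, oracle_kl(mu, lv), tolerance = 1e-10)
  expect_equal(l$total, l$recon + l$kl)
  lb <- vae_loss(x, xh, mu, lv, recon_loss = "bernoulli")
  expect_equal(lb$recon, -sum(x * log(xh) + (1 - x) * log(1 - xh)),
    tolerance = 1e-6
  )
  expect_gte(lb$kl, 0)
})

test_that("VAE training reduces the loss, keeps KL non-negative, is seeded", {
  base <- generate_beats(60, 0, noise_sd = 0.02, series_length = 24L, seed = 3)
  normals <- normalize_dataset(base, fit_normalization(base))
  cfg <- train_config(epochs = 40L, batch_size = 16L, seed = 2L)
  fit <- train_vae(normals, cfg)
  expect_lt(fit$history$loss[40], fit$history$loss[1])
  expect_true(all(fit$history$kl_min >= 0))
  expect_identical(train_vae(normals, cfg)$history, fit$history)
  expect_error(train_vae(generate_beats(4, 4, seed = 1), cfg), "normal beats only")
})

test_that("a trained VAE reconstructs better than an untrained autoencoder", {
  base <- generate_beats(50, 0,
    noise_sd = 0, amplitude_jitter = 0.05,
    series_length = 24L, seed = 8
  )
  normals <- normalize_dataset(base, fit_normalization(base))
  fit <- train_vae(normals, train_config(epochs = 60L, batch_size = 16L, seed = 1L))
  vae_err <- mean(per_record_errors(fit, normals)$errors)
  raw <- list(
    enc = withr::with_seed(9, encoder_params(input_dim = 24L)),
    dec = withr::with_seed(10, decoder_params(input_dim = 24L))
  )
  untrained <- function(x) cat_ae_forward(x, raw$enc, NULL, raw$dec)$xhat
  ae_err <- mean(per_record_errors(untrained, normals)$errors)
  expect_lt(vae_err, ae_err)
})
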