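#' @title Variational autoencoder
#' @description A small VAE for 140-sample beats: one 32-unit ReLU hidden
#'   layer on each side, a 2-d Gaussian latent whose mean and log-variance
#'   are linear heads off the shared hidden activation, reparameterized
#'   sampling, and a loss that sums a reconstruction term and the analytic
#'   KL divergence from the latent posterior to the standard-normal prior.
#' @name vae
NULL

#' VAE parameter constructors
#'
#' Freshly initialized (Glorot-uniform) VAE parameter stacks; consume the
#' current RNG stream.
#'
#' @param input_dim beat length (default 140).
#' @param hidden_dim hidden width on each side (default 32).
#' @param latent_dim Gaussian latent dimension (default 2).
#' @return `vae_encoder_params()`: list with a ReLU `hidden` layer and
#'   linear `mu_head` / `logvar_head`.
#' @export
vae_encoder_params <- function(input_dim = 140L, hidden_dim = 32L,
                               latent_dim = 2L) {
  structure(
    list(
      hidden = .init_dense(input_dim, hidden_dim, "relu"),
      mu_head = .init_dense(hidden_dim, latent_dim, "linear"),
      logvar_head = .init_dense(hidden_dim, latent_dim, "linear")
    ),
    class = "vae_encoder_params"
  )
}

#' @rdname vae_encoder_params
#' @return `vae_decoder_params()`: a ReLU `hidden` layer and a sigmoid
#'   `out` layer back to `input_dim`.
#' @export
vae_decoder_params <- function(latent_dim = 2L, hidden_dim = 32L,
                               input_dim = 140L) {
  structure(
    list(
      hidden = .init_dense(latent_dim, hidden_dim, "relu"),
      out = .init_dense(hidden_dim, input_dim, "sigmoid")
    ),
    class = "vae_decoder_params"
  )
}

#' Encode beats to posterior mean and log-variance
#'
#' @param x normalized beat vector or `n x input_dim` matrix.
#' @param enc a [vae_encoder_params()] stack.
#' @return List with `mu` and `logvar`, each a length-2 vector (or `n x 2`
#'   matrix): the diagonal-Gaussian posterior parameters.
#' @export
vae_encode <- function(x, enc) {
  stopifnot(inherits(enc, "vae_encoder_params"))
  h <- dense_forward(x, enc$hidden)
  list(
    mu = dense_forward(h, enc$mu_head),
    logvar = dense_forward(h, enc$logvar_head)
  )
}

#' Reparameterized Gaussian sample
#'
#' `z = mu + exp(logvar / 2) * epsilon` with `epsilon ~ N(0, I)`, making the
#' sampling step differentiable in `mu` and `logvar`. Supply `epsilon` for a
#' deterministic result; otherwise it is drawn from the current RNG stream.
#'
#' @param mu,logvar posterior parameters (equal shapes).
#' @param epsilon optional standard-normal draw of the same shape.
#' @return List with `z` and the `epsilon` actually used.
#' @export
reparameterize <- function(mu, logvar, epsilon = NULL) {
  if (length(mu) != length(logvar)) stop("`mu` and `logvar` shape mismatch")
  if (is.null(epsilon)) {
    epsilon <- mu * 0 + rnorm(length(mu))
  } else if (length(epsilon) != length(mu)) {
    stop("`epsilon` must match the shape of `mu`")
  }
  list(z = mu + exp(logvar / 2) * epsilon, epsilon = epsilon)
}

#' Analytic KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian `N(mu, diag(exp(logvar)))`,
#' `KL = sum_d 0.5 * (mu_d^2 + exp(logvar_d) - 1 - logvar_d)`, which is zero
#' exactly when the posterior equals the prior.
#'
#' @param mu,logvar posterior parameters; vectors, or matrices with one
#'   record per row.
#' @return Non-negative scalar (or one value per row).
#' @export
kl_gaussian <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stop("`mu` and `logvar` shape mismatch")
  term <- 0.5 * (mu^2 + exp(logvar) - 1 - logvar)
  if (is.matrix(term)) rowSums(term) else sum(term)
}

#' VAE loss: reconstruction plus KL
#'
#' The reconstruction term is, per record, the sum over the beat's samples
#' of the squared error (the negative log-likelihood of a unit-variance
#' Gaussian observation model, up to an additive constant), or the Bernoulli
#' cross-entropy when `recon_loss = "bernoulli"`. For matrix inputs the
#' components are averaged over records.
#'
#' @param x,xhat input and reconstruction (equal shapes).
#' @param mu,logvar posterior parameters for the same records.
#' @param recon_loss `"gaussian"` (default) or `"bernoulli"`.
#' @return A `vae_loss` object: list with `recon`, `kl`, `total`
#'   (`total = recon + kl`).
#' @export
vae_loss <- function(x, xhat, mu, logvar,
                     recon_loss = c("gaussian", "bernoulli")) {
  recon_loss <- match.arg(recon_loss)
  if (length(x) != length(xhat)) stop("`x` and `xhat` shape mismatch")
  if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1L)
    xhat <- matrix(xhat, nrow = 1L)
    mu <- matrix(mu, nrow = 1L)
    logvar <- matrix(logvar, nrow = 1L)
  }
  recon_per <- if (recon_loss == "gaussian") {
    rowSums((xhat - x)^2)
  } else {
    ph <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
    -rowSums(x * log(ph) + (1 - x) * log(1 - ph))
  }
  kl_per <- kl_gaussian(mu, logvar)
  recon <- mean(recon_per)
  kl <- mean(kl_per)
  structure(
    list(recon = recon, kl = kl, total = recon + kl),
    class = "vae_loss"
  )
}

# ---- training ---------------------------------------------------------------

.vae_trainable <- function(model) {
  list(
    enc_hidden = model$encoder$hidden[c("W", "b")],
    mu_head = model$encoder$mu_head[c("W", "b")],
    logvar_head = model$encoder$logvar_head[c("W", "b")],
    dec_hidden = model$decoder$hidden[c("W", "b")],
    dec_out = model$decoder$out[c("W", "b")]
  )
}

.vae_set_trainable <- function(model, tr) {
  model$encoder$hidden$W <- tr$enc_hidden$W
  model$encoder$hidden$b <- tr$enc_hidden$b
  model$encoder$mu_head$W <- tr$mu_head$W
  model$encoder$mu_head$b <- tr$mu_head$b
  model$encoder$logvar_head$W <- tr$logvar_head$W
  model$encoder$logvar_head$b <- tr$logvar_head$b
  model$decoder$hidden$W <- tr$dec_hidden$W
  model$decoder$hidden$b <- tr$dec_hidden$b
  model$decoder$out$W <- tr$dec_out$W
  model$decoder$out$b <- tr$dec_out$b
  model
}

# One minibatch: forward with a fresh epsilon per record, loss, gradients.
.vae_batch_grad <- function(X, model, recon_loss) {
  n <- nrow(X)
  enc <- model$encoder
  dec <- model$decoder

  Hpre <- sweep(X %*% enc$hidden$W, 2L, enc$hidden$b, `+`)
  H <- pmax(Hpre, 0)
  Mu <- sweep(H %*% enc$mu_head$W, 2L, enc$mu_head$b, `+`)
  Lv <- sweep(H %*% enc$logvar_head$W, 2L, enc$logvar_head$b, `+`)
  Eps <- matrix(rnorm(length(Mu)), nrow = n)
  Sd <- exp(Lv / 2)
  Zl <- Mu + Sd * Eps

  Dpre <- sweep(Zl %*% dec$hidden$W, 2L, dec$hidden$b, `+`)
  D <- pmax(Dpre, 0)
  Opre <- sweep(D %*% dec$out$W, 2L, dec$out$b, `+`)
  Y <- plogis(Opre)

  loss <- vae_loss(X, Y, Mu, Lv, recon_loss = recon_loss)

  # backward (all gradients of the batch-mean total loss)
  dOpre <- if (recon_loss == "gaussian") {
    2 * (Y - X) * Y * (1 - Y) / n
  } else {
    (Y - X) / n # sigmoid + cross-entropy shortcut
  }
  g_out <- list(W = crossprod(D, dOpre), b = colSums(dOpre))
  dD <- (dOpre %*% t(dec$out$W)) * (D > 0)
  g_dh <- list(W = crossprod(Zl, dD), b = colSums(dD))
  dZ <- dD %*% t(dec$hidden$W)

  dMu <- dZ + Mu / n
  dLv <- dZ * Eps * Sd / 2 + 0.5 * (exp(Lv) - 1) / n

  g_mu <- list(W = crossprod(H, dMu), b = colSums(dMu))
  g_lv <- list(W = crossprod(H, dLv), b = colSums(dLv))
  dH <- (dMu %*% t(enc$mu_head$W) + dLv %*% t(enc$logvar_head$W)) * (H > 0)
  g_eh <- list(W = crossprod(X, dH), b = colSums(dH))

  list(
    loss = loss,
    grads = list(
      enc_hidden = g_eh, mu_head = g_mu, logvar_head = g_lv,
      dec_hidden = g_dh, dec_out = g_out
    )
  )
}

#' Train a variational autoencoder on normal beats
#'
#' Adam on the batch-mean of [vae_loss()], with one fresh standard-normal
#' `epsilon` draw per record per step. Like [train_autoencoder()], the
#' training set must be normal-only and normalized.
#'
#' @inheritParams train_autoencoder
#' @param config a [train_config()]; defaults to 100 epochs for the VAE.
#' @param recon_loss reconstruction likelihood, see [vae_loss()].
#' @return An object of class `vae_model` with parameter stacks and
#'   `history`: per-epoch `loss` (total), `recon`, `kl`, and `kl_min`, the
#'   smallest batch-mean KL seen in the epoch.
#' @export
train_vae <- function(normals, config = train_config(epochs = 100L),
                      recon_loss = c("gaussian", "bernoulli")) {
  recon_loss <- match.arg(recon_loss)
  .check_normal_only(normals, "a variational autoencoder")
  stopifnot(inherits(config, "train_config"))
  X_all <- normals$values
  n <- nrow(X_all)

  withr::with_seed(config$seed, {
    model <- list(
      encoder = vae_encoder_params(input_dim = ncol(X_all)),
      decoder = vae_decoder_params(input_dim = ncol(X_all)),
      recon_loss = recon_loss,
      config = config
    )
    tr <- .vae_trainable(model)
    opt <- .adam_init(tr)
    hist <- data.frame(
      epoch = seq_len(config$epochs),
      loss = NA_real_, recon = NA_real_, kl = NA_real_, kl_min = NA_real_
    )
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      tot <- rec <- kl <- c()
      for (idx in .batch_indices(n, config$batch_size)) {
        model <- .vae_set_trainable(model, tr)
        step <- .vae_batch_grad(X_all[perm[idx], , drop = FALSE], model, recon_loss)
        res <- .adam_step(tr, step$grads, opt, lr = config$learning_rate)
        tr <- res$params
        opt <- res$state
        tot <- c(tot, step$loss$total)
        rec <- c(rec, step$loss$recon)
        kl <- c(kl, step$loss$kl)
      }
      hist[ep, c("loss", "recon", "kl", "kl_min")] <-
        c(mean(tot), mean(rec), mean(kl), min(kl))
    }
    model <- .vae_set_trainable(model, tr)
    model$history <- hist
    class(model) <- "vae_model"
    model
  })
}

#' @export
print.vae_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<vae_model> epochs=%d  total=%.4f (recon %.4f + kl %.4f)\n",
    nrow(x$history), last$loss, last$recon, last$kl
  ))
  invisible(x)
}

#' @export
#' @describeIn model_reconstruct deterministic VAE reconstruction decoded at
#'   the posterior mean (`z = mu`), so anomaly scores are reproducible.
model_reconstruct.vae_model <- function(model, x) {
  post <- vae_encode(x, model$encoder)
  h <- dense_forward(post$mu, model$decoder$hidden)
  dense_forward(h, model$decoder$out)
}
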