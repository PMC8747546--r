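#' @title Dense autoencoder with a concatenation-attention bottleneck
#' @description The reconstruction model at the core of the package: a
#'   140-32-16-8 ReLU encoder, an optional attention module that scores the
#'   8-d latent vector with a single linear layer, squashes the scores
#'   through a sigmoid and gates the latent elementwise, and an 8-16-32-140
#'   decoder whose final sigmoid keeps reconstructions in (0, 1). Trained by
#'   minimizing the mean absolute error between input and reconstruction.
#' @name autoencoder
NULL

#' Encoder / attention / decoder parameter constructors
#'
#' Freshly initialized (Glorot-uniform, zero bias) parameter stacks for the
#' dense autoencoder. These consume the current RNG stream; seed via
#' [withr::with_seed()] or let [train_autoencoder()] handle seeding.
#'
#' @param input_dim beat length (default 140).
#' @param hidden encoder widths, outermost first (default `c(32, 16, 8)`).
#' @return `encoder_params()`: list of three ReLU [dense_layer()]s.
#' @export
encoder_params <- function(input_dim = 140L, hidden = c(32L, 16L, 8L)) {
  dims <- c(input_dim, hidden)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    .init_dense(dims[[i]], dims[[i + 1L]], "relu")
  })
  structure(list(layers = layers), class = "encoder_params")
}

#' @rdname encoder_params
#' @param latent_dim bottleneck width (default 8).
#' @return `attention_params()`: a single linear `latent_dim x latent_dim`
#'   score layer.
#' @export
attention_params <- function(latent_dim = 8L) {
  structure(
    list(score_layer = .init_dense(latent_dim, latent_dim, "linear")),
    class = "attention_params"
  )
}

#' @rdname encoder_params
#' @return `decoder_params()`: two ReLU layers and a final sigmoid layer
#'   back to `input_dim`.
#' @export
decoder_params <- function(latent_dim = 8L, hidden = c(16L, 32L),
                           input_dim = 140L) {
  dims <- c(latent_dim, hidden, input_dim)
  acts <- c(rep("relu", length(dims) - 2L), "sigmoid")
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    .init_dense(dims[[i]], dims[[i + 1L]], acts[[i]])
  })
  structure(list(layers = layers), class = "decoder_params")
}

#' Encode beats to the latent space
#'
#' @param x numeric vector (one normalized beat) or `n x input_dim` matrix.
#' @param enc an [encoder_params()] stack.
#' @return Latent activations (length-8 vector or `n x 8` matrix), all
#'   non-negative (ReLU output).
#' @export
encode <- function(x, enc) {
  stopifnot(inherits(enc, "encoder_params"))
  for (layer in enc$layers) x <- dense_forward(x, layer)
  x
}

#' Attention score, gate and context operations
#'
#' The attention module computes a raw score `e = W z + b` from the latent
#' vector with one linear layer ([attention_score()]), converts it to gates
#' in (0, 1) ([attention_gate()]), and multiplies the gates elementwise into
#' the latent vector ([context_vector()]). With `normalize = "softmax"` the
#' scores are instead renormalized into a probability vector over the
#' latent dimensions before gating.
#'
#' @param z latent vector (length 8) or `n x 8` matrix.
#' @param attn an [attention_params()] object.
#' @return [attention_score()]: raw scores, same shape as `z`.
#' @export
attention_score <- function(z, attn) {
  stopifnot(inherits(attn, "attention_params"))
  dense_forward(z, attn$score_layer)
}

#' @rdname attention_score
#' @param e raw attention scores.
#' @param normalize `"none"` (elementwise sigmoid, the default) or
#'   `"softmax"` (row-normalized probability weights).
#' @return [attention_gate()]: gates in (0, 1), same shape as `e`.
#' @export
attention_gate <- function(e, normalize = c("none", "softmax")) {
  normalize <- match.arg(normalize)
  if (normalize == "none") {
    plogis(e)
  } else if (is.matrix(e)) {
    ex <- exp(e - apply(e, 1L, max))
    ex / rowSums(ex)
  } else {
    ex <- exp(e - max(e))
    ex / sum(ex)
  }
}

#' @rdname attention_score
#' @param gates attention gates from [attention_gate()].
#' @return [context_vector()]: the gated latent `C = gates * z`, elementwise.
#' @export
context_vector <- function(gates, z) {
  if (!identical(dim(gates), dim(z)) || length(gates) != length(z)) {
    stop("`gates` and `z` must have identical shape")
  }
  gates * z
}

#' Decode a context (or latent) vector back to a beat
#'
#' @param ctx context or latent vector (length 8) or `n x 8` matrix.
#' @param dec a [decoder_params()] stack.
#' @return Reconstruction in (0, 1), length `input_dim` (or matrix).
#' @export
decode <- function(ctx, dec) {
  stopifnot(inherits(dec, "decoder_params"))
  for (layer in dec$layers) ctx <- dense_forward(ctx, layer)
  ctx
}

#' Mean absolute error
#'
#' Per-record loss is the mean of `|xhat - x|` over the beat's samples; for
#' a batch (matrix input) the scalar returned is the mean over records,
#' which keeps the detection threshold scale-free in the series length.
#'
#' @param x,xhat numeric vectors or equal-shaped matrices.
#' @return Non-negative scalar.
#' @seealso [per_record_mae()] for the unreduced per-record errors.
#' @export
mae_loss <- function(x, xhat) {
  if (length(x) != length(xhat)) stop("`x` and `xhat` differ in length")
  mean(abs(xhat - x))
}

#' @rdname mae_loss
#' @export
per_record_mae <- function(x, xhat) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(xhat)) xhat <- matrix(xhat, nrow = 1L)
  if (!identical(dim(x), dim(xhat))) stop("shape mismatch")
  unname(rowMeans(abs(xhat - x)))
}

#' Full forward pass of the attention autoencoder
#'
#' @param x normalized beat(s): vector or `n x input_dim` matrix.
#' @param enc,attn,dec parameter stacks; pass `attn = NULL` for the plain
#'   (no-attention) autoencoder, in which case the latent feeds the decoder
#'   directly and `gates`/`context` echo that.
#' @param normalize gate normalization, see [attention_gate()].
#' @return List with `xhat` (reconstruction), `z` (latent), `gates`,
#'   `context`.
#' @export
cat_ae_forward <- function(x, enc, attn, dec,
                           normalize = c("none", "softmax")) {
  normalize <- match.arg(normalize)
  z <- encode(x, enc)
  if (is.null(attn)) {
    gates <- z * 0 + 1
    ctx <- z
  } else {
    gates <- attention_gate(attention_score(z, attn), normalize)
    ctx <- context_vector(gates, z)
  }
  list(xhat = decode(ctx, dec), z = z, gates = gates, context = ctx)
}

# ---- training ---------------------------------------------------------------

# Forward pass with caches + hand-derived backprop for one minibatch.
# X: n x 140 (rows in [0,1]). Returns loss and gradients shaped like params.
.ae_batch_grad <- function(X, params, arch, normalize) {
  n <- nrow(X)
  enc <- params$encoder$layers
  dec <- params$decoder$layers

  pre_e <- vector("list", 3L)
  act_e <- vector("list", 3L)
  h <- X
  for (i in 1:3) {
    pre_e[[i]] <- sweep(h %*% enc[[i]]$W, 2L, enc[[i]]$b, `+`)
    act_e[[i]] <- pmax(pre_e[[i]], 0)
    h <- act_e[[i]]
  }
  Z <- act_e[[3L]]

  if (arch == "cat_ae") {
    sc <- params$attention$score_layer
    E <- sweep(Z %*% sc$W, 2L, sc$b, `+`)
    G <- attention_gate(E, normalize)
    C <- G * Z
  } else {
    C <- Z
  }

  pre_d <- vector("list", 3L)
  act_d <- vector("list", 3L)
  h <- C
  for (i in 1:3) {
    pre_d[[i]] <- sweep(h %*% dec[[i]]$W, 2L, dec[[i]]$b, `+`)
    act_d[[i]] <- if (i < 3L) pmax(pre_d[[i]], 0) else plogis(pre_d[[i]])
    h <- act_d[[i]]
  }
  Y <- act_d[[3L]]
  loss <- mean(abs(Y - X))

  # backward
  dY <- sign(Y - X) / length(Y)
  g_dec <- vector("list", 3L)
  d_up <- dY
  for (i in 3:1) {
    dpre <- if (i == 3L) d_up * Y * (1 - Y) else d_up * (act_d[[i]] > 0)
    inp <- if (i == 1L) C else act_d[[i - 1L]]
    g_dec[[i]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
    d_up <- dpre %*% t(dec[[i]]$W)
  }
  dC <- d_up

  g_attn <- NULL
  if (arch == "cat_ae") {
    dG <- dC * Z
    dZ <- dC * G
    dE <- if (normalize == "none") {
      dG * G * (1 - G)
    } else {
      G * (dG - rowSums(dG * G))
    }
    g_attn <- list(score_layer = list(W = crossprod(Z, dE), b = colSums(dE)))
    dZ <- dZ + dE %*% t(sc$W)
  } else {
    dZ <- dC
  }

  g_enc <- vector("list", 3L)
  d_up <- dZ
  for (i in 3:1) {
    dpre <- d_up * (act_e[[i]] > 0)
    inp <- if (i == 1L) X else act_e[[i - 1L]]
    g_enc[[i]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
    d_up <- dpre %*% t(enc[[i]]$W)
  }

  grads <- list(
    encoder = list(layers = g_enc),
    decoder = list(layers = g_dec)
  )
  if (!is.null(g_attn)) grads$attention <- g_attn
  list(loss = loss, grads = grads)
}

# Strip dense layers down to the numeric leaves the optimizer updates.
.ae_trainable <- function(model) {
  out <- list(
    encoder = list(layers = lapply(model$encoder$layers, function(l) l[c("W", "b")])),
    decoder = list(layers = lapply(model$decoder$layers, function(l) l[c("W", "b")]))
  )
  if (!is.null(model$attention)) {
    out$attention <- list(score_layer = model$attention$score_layer[c("W", "b")])
  }
  out
}

.ae_set_trainable <- function(model, tr) {
  for (i in seq_along(model$encoder$layers)) {
    model$encoder$layers[[i]]$W <- tr$encoder$layers[[i]]$W
    model$encoder$layers[[i]]$b <- tr$encoder$layers[[i]]$b
  }
  for (i in seq_along(model$decoder$layers)) {
    model$decoder$layers[[i]]$W <- tr$decoder$layers[[i]]$W
    model$decoder$layers[[i]]$b <- tr$decoder$layers[[i]]$b
  }
  if (!is.null(model$attention)) {
    model$attention$score_layer$W <- tr$attention$score_layer$W
    model$attention$score_layer$b <- tr$attention$score_layer$b
  }
  model
}

#' Train a (plain or attention) autoencoder on normal beats
#'
#' Minimizes batch MAE with Adam. The dataset must contain only records
#' whose binary label is `"normal"` — the detection procedure depends on the
#' model never having seen an anomaly — and values are expected to be
#' min-max normalized to \[0, 1\].
#'
#' @param normals a binarized, normalized [beat_dataset()] of normal beats.
#' @param arch `"cat_ae"` (attention bottleneck, the default) or `"ae"`
#'   (plain autoencoder).
#' @param config a [train_config()].
#' @param attention_normalize gate normalization, see [attention_gate()].
#' @return An object of class `ae_model`: parameter stacks, the
#'   architecture tag, and `history`, a data frame with one row per epoch
#'   (`epoch`, `loss` = mean minibatch MAE).
#' @export
train_autoencoder <- function(normals, arch = c("cat_ae", "ae"),
                              config = train_config(),
                              attention_normalize = c("none", "softmax")) {
  arch <- match.arg(arch)
  attention_normalize <- match.arg(attention_normalize)
  .check_normal_only(normals, "an autoencoder")
  stopifnot(inherits(config, "train_config"))
  X_all <- normals$values
  n <- nrow(X_all)
  input_dim <- ncol(X_all)

  withr::with_seed(config$seed, {
    model <- list(
      arch = arch,
      encoder = encoder_params(input_dim = input_dim),
      attention = if (arch == "cat_ae") attention_params(),
      decoder = decoder_params(input_dim = input_dim),
      attention_normalize = attention_normalize,
      config = config
    )
    tr <- .ae_trainable(model)
    opt <- .adam_init(tr)
    hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (idx in .batch_indices(n, config$batch_size)) {
        model <- .ae_set_trainable(model, tr)
        step <- .ae_batch_grad(
          X_all[perm[idx], , drop = FALSE],
          model, arch, attention_normalize
        )
        res <- .adam_step(tr, step$grads, opt, lr = config$learning_rate)
        tr <- res$params
        opt <- res$state
        losses <- c(losses, step$loss)
      }
      hist[[ep]] <- mean(losses)
    }
    model <- .ae_set_trainable(model, tr)
    model$history <- data.frame(epoch = seq_len(config$epochs), loss = hist)
    class(model) <- "ae_model"
    model
  })
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf(
    "<ae_model> arch=%s  epochs=%d  final loss=%.5f\n",
    x$arch, nrow(x$history), x$history$loss[nrow(x$history)]
  ))
  invisible(x)
}

#' Reconstruct beats with a trained model
#'
#' Generic used by the detection layer: maps normalized beats to their
#' model reconstruction. Methods exist for [train_autoencoder()] and
#' [train_vae()] fits (the VAE decodes deterministically at `z = mu`), and
#' for plain functions (useful as reference models in tests).
#'
#' @param model a trained model object.
#' @param x normalized beat vector or `n x input_dim` matrix.
#' @return Reconstruction of the same shape.
#' @export
model_reconstruct <- function(model, x) UseMethod("model_reconstruct")

#' @export
model_reconstruct.ae_model <- function(model, x) {
  # exact indexing: a reloaded plain-AE checkpoint has no "attention" field
  # and partial matching must not pick up "attention_normalize"
  cat_ae_forward(x, model$encoder, model[["attention"]], model$decoder,
    normalize = model$attention_normalize
  )$xhat
}

#' @export
model_reconstruct.function <- function(model, x) model(x)
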