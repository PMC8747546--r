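#' Construct a dense (fully connected) layer
#'
#' Weights are stored as an `in_dim x out_dim` matrix so that a batch of
#' inputs (records in rows) is propagated as `X %*% W + b`.
#'
#' @param W numeric weight matrix, `in_dim x out_dim`.
#' @param b numeric bias vector of length `out_dim`.
#' @param activation one of `"relu"`, `"sigmoid"`, `"linear"`.
#' @return An object of class `dense_layer`.
#' @export
dense_layer <- function(W, b, activation = c("relu", "sigmoid", "linear")) {
  activation <- match.arg(activation)
  if (!is.matrix(W) || !is.numeric(W)) stop("`W` must be a numeric matrix")
  if (length(b) != ncol(W)) {
    stop("bias length must equal the layer's output dimension")
  }
  structure(
    list(W = unname(W), b = as.numeric(b), activation = activation),
    class = "dense_layer"
  )
}

.activate <- function(x, activation) {
  switch(activation,
    relu = pmax(x, 0),
    sigmoid = plogis(x),
    linear = x
  )
}

#' Forward pass through a dense layer
#'
#' @param x numeric vector of length `in_dim`, or an `n x in_dim` matrix of
#'   records in rows.
#' @param layer a [dense_layer()].
#' @return `activation(x W + b)`; a vector for vector input, an
#'   `n x out_dim` matrix for matrix input.
#' @export
dense_forward <- function(x, layer) {
  stopifnot(inherits(layer, "dense_layer"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(layer$W)) {
    stop(sprintf(
      "input has %d features but layer expects %d", ncol(x), nrow(layer$W)
    ))
  }
  out <- .activate(sweep(x %*% layer$W, 2L, layer$b, `+`), layer$activation)
  if (vec) out[1L, ] else out
}

# Glorot (uniform) initialization; consumes the current RNG stream.
.init_dense <- function(in_dim, out_dim, activation) {
  lim <- sqrt(6 / (in_dim + out_dim))
  dense_layer(
    matrix(runif(in_dim * out_dim, -lim, lim), in_dim, out_dim),
    rep(0, out_dim),
    activation
  )
}

# ---- parameter-tree utilities ----------------------------------------------
# Model parameters are nested lists whose leaves are numeric matrices or
# vectors; gradients share the same shape.

.map_params <- function(x, f) {
  if (is.list(x)) lapply(x, .map_params, f = f) else f(x)
}

.map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- .map2_params(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

.zeros_like <- function(x) .map_params(x, function(v) v * 0)

# ---- Adam optimizer ---------------------------------------------------------

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- .map2_params(state$m, state$v, function(m, v) {
    lr * (m / corr1) / (sqrt(v / corr2) + eps)
  })
  params <- .map2_params(params, upd, `-`)
  list(params = params, state = state)
}

#' Training configuration
#'
#' Shared hyperparameter container for all model trainers. Defaults follow
#' the study settings for the attention autoencoder (15 epochs, batch 512);
#' [train_vae()] and [train_lstm()] override `epochs` with their own
#' defaults (100 and 20).
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size minibatch size (>= 1); capped at the dataset size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization, batch order and any
#'   sampling during training.
#' @param optimizer currently only `"adam"` (beta1 = 0.9, beta2 = 0.999).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 15L, batch_size = 512L,
                         learning_rate = 1e-3, seed = 42L,
                         optimizer = "adam") {
  optimizer <- match.arg(optimizer, "adam")
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, seed = as.integer(seed),
      optimizer = optimizer
    ),
    class = "train_config"
  )
}

# Guard for the normal-only training contract of reconstruction models.
.check_normal_only <- function(dataset, what) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (n_beats(dataset) == 0L) stop(what, ": training dataset is empty")
  if (is.null(dataset$binary_label)) {
    stop(what, ": dataset must be binarized (see binarize_labels())")
  }
  if (any(dataset$binary_label != "normal")) {
    stop(what, " is trained on normal beats only; anomalous records present")
  }
  invisible(dataset)
}

# Minibatch index list for one epoch (order already permuted by caller).
.batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / min(batch_size, n)))
}
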