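#' @title LSTM binary classifier
#' @description Direct supervised alternative to the reconstruction
#'   detectors: the 140-sample beat is consumed one sample per time step by
#'   two stacked LSTM layers (100 units each), a dropout layer (rate 0.25,
#'   training only) regularizes the final hidden state, and a single sigmoid
#'   neuron emits the probability that the beat is normal. Trained with
#'   binary cross-entropy and Adam. The cell follows the canonical LSTM
#'   update: sigmoid forget/input/output gates, tanh candidate, and
#'   `h_t = o_t * tanh(c_t)`.
#' @name lstm
NULL

#' LSTM layer parameters
#'
#' One gate block per role (`f`orget, `i`nput, `o`utput, `g` candidate):
#' input weights `U` (`in_dim x units`), recurrent weights `W`
#' (`units x units`) and bias `b`. Input weights are Glorot-uniform;
#' recurrent weights are random orthogonal so signal neither explodes nor
#' decays over long unrolls; biases are zero except the forget gate, which
#' starts at 1 so early training does not flush the cell memory. These are
#' the standard initializations for LSTM cells.
#'
#' @param input_dim features per time step.
#' @param units hidden size (default 100).
#' @return An object of class `lstm_layer_params` with fields `U`, `W`, `b`,
#'   each a list over `f`, `i`, `o`, `g`.
#' @export
lstm_layer_params <- function(input_dim, units = 100L) {
  ortho <- function(n) {
    qr.Q(qr(matrix(rnorm(n * n), n, n)))
  }
  gate <- function(bias0) {
    list(
      U = matrix(
        runif(input_dim * units, -1, 1) * sqrt(6 / (input_dim + units)),
        input_dim, units
      ),
      W = ortho(units),
      b = rep(bias0, units)
    )
  }
  gs <- list(f = gate(1), i = gate(0), o = gate(0), g = gate(0))
  structure(
    list(
      U = lapply(gs, `[[`, "U"),
      W = lapply(gs, `[[`, "W"),
      b = lapply(gs, `[[`, "b"),
      units = as.integer(units),
      input_dim = as.integer(input_dim)
    ),
    class = "lstm_layer_params"
  )
}

#' Initial (zero) LSTM state
#' @param units hidden size.
#' @param n batch size; 0 requests vector (single-record) states.
#' @return List with hidden state `h` and cell memory `c`.
#' @export
lstm_zero_state <- function(units, n = 0L) {
  if (n > 0L) {
    list(h = matrix(0, n, units), c = matrix(0, n, units))
  } else {
    list(h = rep(0, units), c = rep(0, units))
  }
}

# Core cell update on batch matrices; returns gates for the BPTT cache.
.lstm_cell <- function(x_t, h_prev, c_prev, params) {
  pre <- function(k) {
    sweep(x_t %*% params$U[[k]] + h_prev %*% params$W[[k]], 2L, params$b[[k]], `+`)
  }
  f <- plogis(pre("f"))
  i <- plogis(pre("i"))
  o <- plogis(pre("o"))
  g <- tanh(pre("g"))
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, f = f, i = i, o = o, g = g)
}

#' Single LSTM time step
#'
#' Canonical update: `f, i, o = sigmoid(x U + h W + b)` per gate,
#' `g = tanh(x U_g + h W_g + b_g)`, `c_t = f * c + i * g`,
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t input at this step: vector of length `input_dim`, or an
#'   `n x input_dim` matrix.
#' @param state list with `h` and `c` (see [lstm_zero_state()]).
#' @param params an [lstm_layer_params()] object.
#' @return Updated state: list with `h` and `c`.
#' @export
lstm_step <- function(x_t, state, params) {
  stopifnot(inherits(params, "lstm_layer_params"))
  vec <- !is.matrix(x_t)
  if (vec) {
    x_t <- matrix(x_t, nrow = 1L)
    state <- list(h = matrix(state$h, 1L), c = matrix(state$c, 1L))
  }
  if (ncol(x_t) != params$input_dim) stop("input feature dimension mismatch")
  if (ncol(state$h) != params$units) stop("state dimension mismatch")
  out <- .lstm_cell(x_t, state$h, state$c, params)
  if (vec) list(h = out$h[1L, ], c = out$c[1L, ]) else out[c("h", "c")]
}

# Forward over a whole sequence via the compiled kernel.
# X: n x in_dim x T cube. Returns H plus the gate/cell caches for BPTT.
.lstm_layer_forward <- function(X, params) {
  out <- lstm_layer_forward_cpp(
    X,
    params$U$f, params$U$i, params$U$o, params$U$g,
    params$W$f, params$W$i, params$W$o, params$W$g,
    params$b$f, params$b$i, params$b$o, params$b$g
  )
  out$X <- X
  out
}

# BPTT through one layer. dH: n x units x T cube of gradients on the
# layer's hidden outputs (zeros where unused).
.lstm_layer_backward <- function(dH, fwd, params) {
  out <- lstm_layer_backward_cpp(
    dH, fwd$X, fwd$H, fwd$F, fwd$I, fwd$O, fwd$G, fwd$C,
    params$U$f, params$U$i, params$U$o, params$U$g,
    params$W$f, params$W$i, params$W$o, params$W$g
  )
  list(
    grads = list(
      U = out$gU,
      W = out$gW,
      b = lapply(out$gb, as.numeric)
    ),
    dX = out$dX
  )
}

# n x T beat matrix -> n x 1 x T input cube for the first layer.
.seq_cube <- function(x) array(x, dim = c(nrow(x), 1L, ncol(x)))

# Data-dependent rescaling of a layer's input weights (LSUV-style): the
# fan-in rules behind standard initializers assume unit-scale inputs, but
# beat samples live in [0, 1] and hidden features have far smaller spread,
# which would leave the gates essentially input-blind. Each gate's U is
# scaled so the input-driven pre-activation has unit standard deviation
# over a calibration batch.
.lsuv_scale_inputs <- function(params, X_cube, target = 1) {
  flat <- matrix(aperm(X_cube, c(1L, 3L, 2L)), ncol = dim(X_cube)[[2L]])
  for (k in names(params$U)) {
    s <- sd(as.vector(flat %*% params$U[[k]]))
    if (s > 0) params$U[[k]] <- params$U[[k]] * (target / s)
  }
  params
}

#' Run the stacked LSTM over a beat sequence
#'
#' The first layer consumes the univariate sequence one sample per step;
#' the second layer consumes the first layer's hidden-state sequence. The
#' final hidden state of the second layer summarizes the beat.
#'
#' @param x numeric vector (one beat) or `n x T` matrix of beats in rows.
#' @param layer1,layer2 [lstm_layer_params()] objects (layer1 with
#'   `input_dim = 1`, layer2 with `input_dim = layer1$units`).
#' @return Final hidden state of layer 2: vector of length `units`, or an
#'   `n x units` matrix.
#' @export
lstm_forward <- function(x, layer1, layer2) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) == 0L) stop("empty sequence")
  hT <- .lstm_summary(x, layer1, layer2, pooling = "final")
  if (vec && is.matrix(hT)) hT[1L, ] else hT
}

#' Classify beats with a trained LSTM model
#'
#' Dropout is inactive at inference: the probability is a deterministic
#' function of the input.
#'
#' @param x normalized beat vector or `n x T` matrix.
#' @param model an `lstm_model` from [train_lstm()].
#' @return Probability (in (0, 1)) that each beat is normal.
#' @export
classify_sequence <- function(x, model) {
  stopifnot(inherits(model, "lstm_model"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  h <- .lstm_summary(x, model$layer1, model$layer2, model$pooling)
  p <- dense_forward(h, model$head)
  as.numeric(p)
}

# Sequence summary fed to the classifier head: the time-mean of the second
# layer's hidden states ("mean", the default) or its final hidden state.
.lstm_summary <- function(x, layer1, layer2, pooling = "mean") {
  l1 <- .lstm_layer_forward(.seq_cube(x), layer1)
  l2 <- .lstm_layer_forward(l1$H, layer2)
  T_len <- dim(l2$H)[[3L]]
  if (pooling == "mean") {
    rowMeans(l2$H, dims = 2L)
  } else {
    l2$H[, , T_len]
  }
}

#' Binary cross-entropy loss
#'
#' `-[y log p + (1 - y) log(1 - p)]`, averaged over records. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` so boundary predictions stay finite.
#'
#' @param y true labels in `{0, 1}`.
#' @param p predicted probabilities.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` differ in length")
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# ---- training ---------------------------------------------------------------

.lstm_trainable <- function(model) {
  list(
    l1 = model$layer1[c("U", "W", "b")],
    l2 = model$layer2[c("U", "W", "b")],
    head = model$head[c("W", "b")]
  )
}

.lstm_set_trainable <- function(model, tr) {
  model$layer1[c("U", "W", "b")] <- tr$l1
  model$layer2[c("U", "W", "b")] <- tr$l2
  model$head$W <- tr$head$W
  model$head$b <- tr$head$b
  model
}

#' Train the two-layer LSTM classifier
#'
#' Supervised training on a dataset containing both classes; the target is
#' 1 for normal beats and 0 for anomalous ones, matching the evaluation
#' module's default positive class. Dropout (rate `dropout_rate`) is applied
#' to the final hidden state during training only.
#'
#' @param dataset a binarized, normalized [beat_dataset()] with both classes
#'   present.
#' @param config a [train_config()]; defaults to 20 epochs.
#' @param units LSTM width per layer (default 100).
#' @param dropout_rate fraction of summary-state units dropped per training
#'   step (default 0.25; must be < 1).
#' @param pooling classifier readout: `"mean"` (default) feeds the head the
#'   time-mean of the second layer's hidden states, so beats whose
#'   discriminative morphology sits mid-sequence contribute directly;
#'   `"final"` uses only the last hidden state.
#' @return An object of class `lstm_model`: `layer1`, `layer2`, `head`
#'   (a sigmoid [dense_layer()]), `dropout_rate`, `pooling`, and per-epoch
#'   `history`.
#' @export
train_lstm <- function(dataset, config = train_config(epochs = 20L),
                       units = 100L, dropout_rate = 0.25,
                       pooling = c("mean", "final")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(dataset, "beat_dataset"), inherits(config, "train_config"))
  if (is.null(dataset$binary_label)) {
    stop("dataset must be binarized (see binarize_labels())")
  }
  if (length(unique(dataset$binary_label)) < 2L) {
    stop("LSTM training requires both normal and anomalous records")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must be in [0, 1)")
  X_all <- dataset$values
  y_all <- as.numeric(dataset$binary_label == "normal")
  n <- nrow(X_all)
  keep <- 1 - dropout_rate

  withr::with_seed(config$seed, {
    model <- list(
      layer1 = lstm_layer_params(1L, units),
      layer2 = lstm_layer_params(units, units),
      head = .init_dense(units, 1L, "sigmoid"),
      dropout_rate = dropout_rate,
      pooling = pooling,
      config = config
    )
    calib <- .seq_cube(X_all[seq_len(min(64L, n)), , drop = FALSE])
    model$layer1 <- .lsuv_scale_inputs(model$layer1, calib)
    h1 <- .lstm_layer_forward(calib, model$layer1)$H
    model$layer2 <- .lsuv_scale_inputs(model$layer2, h1)
    tr <- .lstm_trainable(model)
    opt <- .adam_init(tr)
    hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (idx in .batch_indices(n, config$batch_size)) {
        model <- .lstm_set_trainable(model, tr)
        X <- X_all[perm[idx], , drop = FALSE]
        y <- y_all[perm[idx]]
        nb <- nrow(X)
        l1 <- .lstm_layer_forward(.seq_cube(X), model$layer1)
        l2 <- .lstm_layer_forward(l1$H, model$layer2)
        T_len <- dim(l2$H)[[3L]]
        hS <- if (pooling == "mean") {
          rowMeans(l2$H, dims = 2L)
        } else {
          matrix(l2$H[, , T_len], nrow = nb)
        }
        mask <- matrix(
          (runif(length(hS)) > dropout_rate) / keep,
          nrow = nb
        )
        hD <- hS * mask
        logit <- sweep(hD %*% model$head$W, 2L, model$head$b, `+`)
        p <- plogis(as.numeric(logit))
        losses <- c(losses, bce_loss(y, p))

        dlogit <- matrix((p - y) / nb, ncol = 1L)
        g_head <- list(W = crossprod(hD, dlogit), b = colSums(dlogit))
        dhS <- (dlogit %*% t(model$head$W)) * mask
        dH2 <- array(0, dim = dim(l2$H))
        if (pooling == "mean") {
          dH2 <- array(rep(dhS / T_len, T_len), dim = dim(l2$H))
        } else {
          dH2[, , T_len] <- dhS
        }
        b2 <- .lstm_layer_backward(dH2, l2, model$layer2)
        b1 <- .lstm_layer_backward(b2$dX, l1, model$layer1)
        grads <- list(l1 = b1$grads, l2 = b2$grads, head = g_head)
        res <- .adam_step(tr, grads, opt, lr = config$learning_rate)
        tr <- res$params
        opt <- res$state
      }
      hist[[ep]] <- mean(losses)
    }
    model <- .lstm_set_trainable(model, tr)
    model$history <- data.frame(epoch = seq_len(config$epochs), loss = hist)
    class(model) <- "lstm_model"
    model
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "<lstm_model> 2 x %d units, dropout %.2f, epochs=%d, final BCE=%.4f\n",
    x$layer1$units, x$dropout_rate, nrow(x$history),
    x$history$loss[nrow(x$history)]
  ))
  invisible(x)
}
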