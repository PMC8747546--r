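# Independent reference implementations used to cross-check the package's
# vectorized code. All are deliberately written as plain scalar loops or
# numerical routines so they share no code path with the implementation.

# Dense layer: explicit loop over output units and input sums.
oracle_dense <- function(x, W, b, activation) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    s <- b[j]
    for (i in seq_len(nrow(W))) s <- s + x[i] * W[i, j]
    out[j] <- switch(activation,
      relu = max(s, 0),
      sigmoid = 1 / (1 + exp(-s)),
      linear = s
    )
  }
  out
}

# One LSTM cell update, scalar loops throughout.
oracle_lstm_step <- function(x, h_prev, c_prev, params) {
  units <- params$units
  pre <- function(U, W, b) {
    out <- numeric(units)
    for (j in seq_len(units)) {
      s <- b[j]
      for (i in seq_along(x)) s <- s + x[i] * U[i, j]
      for (k in seq_len(units)) s <- s + h_prev[k] * W[k, j]
      out[j] <- s
    }
    out
  }
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(pre(params$U$f, params$W$f, params$b$f))
  i <- sig(pre(params$U$i, params$W$i, params$b$i))
  o <- sig(pre(params$U$o, params$W$o, params$b$o))
  g <- tanh(pre(params$U$g, params$W$g, params$b$g))
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# KL(N(mu, exp(lv)) || N(0, 1)) by numerical integration, one dimension at
# a time (independent coordinates add).
oracle_kl <- function(mu, logvar) {
  total <- 0
  for (d in seq_along(mu)) {
    s <- exp(logvar[d] / 2)
    integrand <- function(x) {
      q <- stats::dnorm(x, mu[d], s)
      q * (stats::dnorm(x, mu[d], s, log = TRUE) - stats::dnorm(x, log = TRUE))
    }
    total <- total + stats::integrate(integrand,
      lower = mu[d] - 12 * s, upper = mu[d] + 12 * s,
      rel.tol = 1e-13, abs.tol = 1e-13
    )$value
  }
  total
}

# Confusion cells by explicit enumeration.
oracle_confusion <- function(truth, predicted, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    t_pos <- truth[i] == positive
    p_pos <- predicted[i] == positive
    if (t_pos && p_pos) tp <- tp + 1L
    if (!t_pos && !p_pos) tn <- tn + 1L
    if (!t_pos && p_pos) fp <- fp + 1L
    if (t_pos && !p_pos) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Mean absolute error by scalar loop.
oracle_mae <- function(x, xhat) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(xhat[i] - x[i])
  s / length(x)
}

# Binary cross-entropy by scalar loop (with the same clamp as the package).
oracle_bce <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], 1e-7), 1 - 1e-7)
    s <- s - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  s / length(y)
}

# Random small LSTM parameter set (not via the package initializer).
random_lstm_params <- function(input_dim, units) {
  rnd <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  structure(
    list(
      U = list(f = rnd(input_dim, units), i = rnd(input_dim, units),
               o = rnd(input_dim, units), g = rnd(input_dim, units)),
      W = list(f = rnd(units, units), i = rnd(units, units),
               o = rnd(units, units), g = rnd(units, units)),
      b = list(f = rnorm(units), i = rnorm(units),
               o = rnorm(units), g = rnorm(units)),
      units = as.integer(units), input_dim = as.integer(input_dim)
    ),
    class = "lstm_layer_params"
  )
}
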