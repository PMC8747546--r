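# Small synthetic fixtures built in code at test time.

# Generate, split and normalize a small synthetic dataset in one call.
prepared_split <- function(n_normal, n_anomalous, seed = 42L,
                           noise_sd = 0.05, series_length = 140L, ...) {
  ds <- generate_beats(n_normal, n_anomalous,
    noise_sd = noise_sd,
    series_length = series_length, seed = seed, ...
  )
  sp <- split_dataset(ds, seed = seed)
  np <- fit_normalization(sp$train)
  sp$train <- normalize_dataset(sp$train, np)
  sp$validation <- normalize_dataset(sp$validation, np)
  sp$test <- normalize_dataset(sp$test, np)
  sp$normalization <- np
  sp
}

# Concatenate beat datasets (used to pool held-out splits).
bind_beats <- function(a, b) {
  beat_dataset(
    rbind(a$values, b$values),
    c(a$label, b$label),
    if (!is.null(a$binary_label)) c(a$binary_label, b$binary_label)
  )
}

subset_normals <- function(dataset) dataset[dataset$binary_label == "normal"]

# Dense layer filled with a constant (usually zero) for analytic cases.
const_dense <- function(in_dim, out_dim, activation, value = 0) {
  dense_layer(
    matrix(value, in_dim, out_dim), rep(value, out_dim), activation
  )
}

# Zeroed-out parameter stacks for the autoencoder's analytic cases.
zero_ae_params <- function(input_dim = 12L) {
  enc <- encoder_params(input_dim = input_dim)
  dec <- decoder_params(input_dim = input_dim)
  attn <- attention_params()
  enc$layers <- lapply(enc$layers, function(l) {
    const_dense(nrow(l$W), ncol(l$W), l$activation)
  })
  dec$layers <- lapply(dec$layers, function(l) {
    const_dense(nrow(l$W), ncol(l$W), l$activation)
  })
  attn$score_layer <- const_dense(8L, 8L, "linear")
  list(enc = enc, attn = attn, dec = dec)
}
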