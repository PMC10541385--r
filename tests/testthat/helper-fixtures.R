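# Shared fixtures, built once per test run and memoised. The trained network
# and the phantom cohort are used by several files; training them once keeps
# the suite fast without weakening any check.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fixture_phantom_noiseless <- function() {
  memo("phantom_noiseless",
       generate_phantom(phantom_config(noise_sd = 0), seed = 1L))
}

fixture_phantom_noisy <- function() {
  memo("phantom_noisy", generate_phantom(phantom_config(), seed = 3L))
}

# training bank: 128 datasets x 3 AIFs, augmented 3x -> 1152 pairs
fixture_bank <- function() {
  memo("bank", suppressWarnings(make_curve_bank(128L, 3L, seed = 10L)))
}

fixture_train_pairs <- function() {
  memo("train_pairs", augment_pairs(fixture_bank()$pairs, seed = 11L))
}

# held-out validation curves from unseen generator seeds (102 curves)
fixture_val_bank <- function() {
  memo("val_bank", suppressWarnings(make_curve_bank(34L, 3L, seed = 777L)))
}

# network trained at the scaled-down epoch budget used throughout the suite
fixture_model <- function() {
  memo("model", {
    model <- build_cnn(cnn_config(seed = 42L))
    train_cnn(model, fixture_train_pairs(), epochs = 50L)
  })
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# forward model used as an independent oracle for deconvolution tests:
# plain rectangle-rule causal convolution, truncated to the grid
conv_forward <- function(ca_values, r_values, dt) {
  n <- length(ca_values)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- dt * sum(ca_values[1:i] * r_values[i:1])
  out
}

lesion_volume <- function(result, label) {
  v <- result$volumes_mL
  v$volume_mL[v$label == label]
}
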