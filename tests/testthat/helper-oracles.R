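# Independent oracles and shared fixtures, kept deliberately naive so they
# cannot share a defect with the implementation under test.

# Brute-force valid convolution: quadruple loop over output cells and
# filter taps, nothing shared with the C++ kernel.
conv_oracle <- function(input, filters, biases) {
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]
  k <- dim(filters)[1]; F_ <- dim(filters)[4]
  Ho <- H - k + 1; Wo <- W - k + 1
  out <- array(0, dim = c(Ho, Wo, F_))
  for (f in seq_len(F_)) for (y in seq_len(Ho)) for (x in seq_len(Wo)) {
    acc <- biases[f]
    for (c in seq_len(C)) for (i in seq_len(k)) for (j in seq_len(k)) {
      acc <- acc + input[y + i - 1, x + j - 1, c] * filters[i, j, c, f]
    }
    out[y, x, f] <- acc
  }
  out
}

# Central finite-difference derivative of the batch loss w.r.t. weight
# vector entries `idx`.
fd_gradient <- function(spec, wvec, images, labels, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    wp <- wvec; wp[i] <- wp[i] + eps
    wm <- wvec; wm[i] <- wm[i] - eps
    (cnn_loss(spec, restore_weights(wp, spec), images, labels) -
       cnn_loss(spec, restore_weights(wm, spec), images, labels)) / (2 * eps)
  }, numeric(1))
}

# Tiny architectures reused across tests.
tiny_spec <- function(...) {
  build_network(input_shape = c(8, 8, 1), conv_filters = 2L,
                pool_every = 1L, hidden_width = 0L, ...)
}

gradcheck_spec <- function() {
  build_network(input_shape = c(12, 12, 1), conv_filters = c(2L, 3L),
                pool_every = 2L, hidden_width = 5L)
}

# The small-image architecture used for the end-to-end experiments.
small_image_spec <- function(image_size = 32L) {
  build_network(input_shape = c(image_size, image_size, 3L),
                conv_filters = c(4L, 4L), pool_every = 1L, hidden_width = 0L)
}

# Shared seeded synthetic dataset (computed once per test run).
.fixture_env <- new.env(parent = emptyenv())
shared_synth <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_synthetic_dataset(
      n_per_class = 100L, image_size = 32L, n_patients = 4L, seed = 0L)
  .fixture_env$ds
}

random_image <- function(shape, seed) {
  set.seed(seed)
  array(runif(prod(shape)), dim = shape)
}
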