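test_that("build_network resolves shapes and rejects impossible stacks", {
  spec <- build_network()
  expect_identical(spec$final_map, c(9L, 9L, 32L))
  expect_identical(spec$flatten_size, 2592L)

  small <- tiny_spec()
  expect_identical(small$final_map, c(3L, 3L, 2L))

  # two 3x3 convs on a 4x4 input: 4 -> 2 -> impossible
  expect_error(build_network(input_shape = c(4, 4, 1),
                             conv_filters = c(2L, 2L)),
               "invalid architecture")
  expect_error(build_network(input_shape = c(5, 5, 1), conv_filters = c(2L),
                             pool_every = 1L, pool_window = 4L),
               "invalid architecture")
})

test_that("count_weights enumerates parameters per layer", {
  expect_identical(count_weights(tiny_spec()), 58L)
  expect_identical(count_weights(build_network()), 288678L)
  # dense-only network, biases off: n pixels straight to 2 outputs
  dense_only <- build_network(input_shape = c(5, 5, 1),
                              conv_filters = integer(0), hidden_width = 0L,
                              use_bias = FALSE)
  expect_identical(count_weights(dense_only), 2L * 25L)
})

test_that("init_weights is seeded, range-bounded, and centered", {
  spec <- tiny_spec()
  expect_identical(init_weights(spec, "uniform", seed = 1),
                   init_weights(spec, "uniform", seed = 1))
  v <- flatten_weights(init_weights(spec, "uniform", seed = 2), spec)
  expect_true(all(v >= -0.1 & v <= 0.1))

  big <- build_network(input_shape = c(16, 16, 3), conv_filters = c(8L, 8L),
                       hidden_width = 20L)
  vn <- flatten_weights(init_weights(big, "normal", seed = 3), big)
  expect_lt(abs(mean(vn)), 3 * 0.1 / sqrt(length(vn)))
  expect_error(init_weights(spec, "cauchy"), "arg")
})

test_that("convolve_valid matches hand-traced examples", {
  out <- convolve_valid(array(1, c(4, 4, 1)), array(1, c(3, 3, 1, 1)), 0)
  expect_equal(out, array(9, c(2, 2, 1)))
  expect_equal(convolve_valid(random_image(c(5, 5, 2), 1),
                              array(0, c(3, 3, 2, 1)), 0),
               array(0, c(3, 3, 1)))
  x <- random_image(c(3, 3, 1), 2)
  f <- array(x, c(3, 3, 1, 1))
  expect_equal(as.numeric(convolve_valid(x, f, 0)), sum(x^2))
  expect_error(convolve_valid(random_image(c(4, 4, 2), 3),
                              array(1, c(3, 3, 1, 1)), 0), "channels")
})

test_that("convolve_valid equals the brute-force oracle on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    inp <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    fl <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    b <- rnorm(3)
    expect_equal(convolve_valid(inp, fl, b), conv_oracle(inp, fl, b),
                 tolerance = 1e-12)
  }
})

test_that("average_pool takes block means and drops trailing odd edges", {
  expect_equal(average_pool(array(7, c(4, 6, 2))), array(7, c(2, 3, 2)))
  m <- array(matrix(1:16, 4, 4, byrow = TRUE), c(4, 4, 1))
  expect_equal(average_pool(m)[, , 1],
               matrix(c(3.5, 11.5, 5.5, 13.5), 2, 2))
  m5 <- random_image(c(5, 5, 1), 4)
  expect_equal(average_pool(m5), average_pool(m5[1:4, 1:4, , drop = FALSE]))
  expect_error(average_pool(array(1, c(1, 1, 1))), "window")
})

test_that("activations and dense layer behave per definition", {
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))
  expect_equal(relu(-(1:5)), rep(0, 5))
  expect_equal(sigmoid(0), 0.5)
  xs <- seq(-30, 30, by = 3.7)
  expect_equal(sigmoid(xs), 1 - sigmoid(-xs))
  expect_lt(abs(sigmoid(100) - 1), 1e-6)
  expect_equal(sigmoid(c(-1000, 1000)), c(0, 1))  # no overflow/NaN

  expect_equal(dense_forward(c(1, 2), diag(2), c(0, 0)), c(1, 2))
  expect_equal(dense_forward(3, matrix(2), 1), 7)
  expect_equal(dense_forward(c(1, 2), matrix(0, 2, 2), c(4, 5)), c(4, 5))
  expect_error(dense_forward(c(1, 2, 3), diag(2), c(0, 0)), "mismatch")
})

test_that("forward returns normalized scores and composes the layer ops", {
  spec <- tiny_spec()
  for (seed in 1:5) {
    w <- init_weights(spec, "uniform", seed = seed)
    im <- random_image(c(8, 8, 1), seed + 100)
    s <- cnn_forward(spec, w, im)
    expect_equal(sum(s), 1)
    expect_true(all(s >= 0 & s <= 1))
    # explicit layer-by-layer composition
    x <- average_pool(relu(convolve_valid(im, w$conv[[1]]$W, w$conv[[1]]$b)))
    z <- dense_forward(as.numeric(x), w$dense[[1]]$W, w$dense[[1]]$b)
    expect_equal(s, exp(z - max(z)) / sum(exp(z - max(z))))
  }
  w0 <- evocnn:::zero_weights(build_network(input_shape = c(8, 8, 1),
                                            conv_filters = 2L, pool_every = 1L,
                                            hidden_width = 0L, use_bias = FALSE))
  expect_equal(cnn_forward(tiny_spec(use_bias = FALSE), w0,
                           random_image(c(8, 8, 1), 9)), c(0.5, 0.5))
})

test_that("forward is deterministic and flatten size matches the probe map", {
  spec <- gradcheck_spec()
  w <- init_weights(spec, "normal", seed = 5)
  im <- random_image(c(12, 12, 1), 5)
  expect_identical(cnn_forward(spec, w, im), cnn_forward(spec, w, im))
  # shape algebra: produced flattened map length equals spec$flatten_size
  x <- im
  x <- relu(convolve_valid(x, w$conv[[1]]$W, w$conv[[1]]$b))
  x <- relu(convolve_valid(x, w$conv[[2]]$W, w$conv[[2]]$b))
  x <- average_pool(x)
  expect_identical(length(as.numeric(x)), as.integer(spec$flatten_size))
})

test_that("prediction takes the argmax with ties toward benign", {
  spec <- tiny_spec()
  w <- init_weights(spec, seed = 1)
  imgs <- lapply(1:6, function(s) random_image(c(8, 8, 1), s))
  batch <- cnn_predict(spec, w, imgs)
  single <- vapply(imgs, function(im)
    which.max(cnn_forward(spec, w, im)) - 1L, integer(1))
  expect_identical(batch, single)
  # symmetric zero network scores (0.5, 0.5) -> class 0
  spec0 <- tiny_spec(use_bias = FALSE)
  w0 <- evocnn:::zero_weights(spec0)
  expect_identical(cnn_predict(spec0, w0, imgs), rep(0L, 6))
})

test_that("flatten/restore is an exact bijection", {
  for (spec in list(tiny_spec(), gradcheck_spec(),
                    tiny_spec(use_bias = FALSE))) {
    w <- init_weights(spec, "normal", seed = 11)
    v <- flatten_weights(w, spec)
    expect_identical(length(v), as.integer(spec$n_weights))
    expect_identical(restore_weights(v, spec), w)
    set.seed(12)
    v2 <- rnorm(spec$n_weights)
    expect_identical(flatten_weights(restore_weights(v2, spec), spec), v2)
  }
  spec <- tiny_spec()
  expect_error(restore_weights(numeric(3), spec), "length")
  # single-parameter locality
  w <- init_weights(spec, seed = 2)
  w2 <- w
  w2$conv[[1]]$W[2, 3, 1, 1] <- w2$conv[[1]]$W[2, 3, 1, 1] + 1
  expect_identical(sum(flatten_weights(w, spec) != flatten_weights(w2, spec)),
                   1L)
  # zero vector restores to all-zero weights of the right shapes
  wz <- restore_weights(numeric(spec$n_weights), spec)
  expect_true(all(flatten_weights(wz, spec) == 0))
  expect_identical(dim(wz$conv[[1]]$W), c(3L, 3L, 1L, 2L))
})

test_that("checkpoints round-trip spec and weights exactly", {
  spec <- gradcheck_spec()
  w <- init_weights(spec, "normal", seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(spec, w, path)
  ck <- load_checkpoint(path)
  expect_identical(flatten_weights(ck$weights, ck$spec),
                   flatten_weights(w, spec))
  expect_identical(ck$spec$layers, spec$layers)
})
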