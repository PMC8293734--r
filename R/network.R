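#' @useDynLib evocnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

# Run code under a temporary RNG state so seeded helpers do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build a convolutional network specification
#'
#' Resolves the full layer chain of the classifier — a stack of 3x3 "valid"
#' convolutions with ReLU activations, a 2x2 stride-2 average pool after
#' every `pool_every`-th convolution, flattening, an optional hidden dense
#' layer with ReLU, and a final dense layer normalized to class scores —
#' and derives every intermediate shape and the total trainable parameter
#' count. Construction fails if any spatial dimension would drop below 1.
#'
#' The defaults mirror the histopathology classifier this package
#' implements: 210x210 RGB inputs through eight convolutional layers with
#' 8, 8, 16, 16, 24, 24, 32, 32 filters, giving a final 9x9x32 feature map
#' (flatten size 2592).
#'
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param conv_filters integer vector, number of filters per conv layer
#'   (may be empty for a dense-only network).
#' @param kernel_size side of the square convolution kernels.
#' @param pool_every insert an average pool after every `pool_every`-th
#'   conv layer (0 disables pooling).
#' @param pool_window,pool_stride pooling window and stride (stride
#'   defaults to the window); only the standard non-overlapping
#'   `pool_stride == pool_window` case is supported, with trailing odd
#'   rows/columns dropped.
#' @param hidden_width units in the hidden dense layer (0 for none).
#' @param num_classes number of output classes.
#' @param use_bias include bias terms for conv and dense layers.
#' @param output `"softmax"` (default; scores sum to 1) or `"sigmoid"`
#'   (independent per-logit squashing, renormalized for prediction).
#' @return An object of class `cnn_spec`: the settings above plus the
#'   resolved `layers` list, `flatten_size` and `n_weights`.
#' @examples
#' spec <- build_network()
#' spec$flatten_size   # 2592
#' spec$n_weights      # 288678
#' @export
build_network <- function(input_shape = c(210L, 210L, 3L),
                          conv_filters = c(8L, 8L, 16L, 16L, 24L, 24L, 32L, 32L),
                          kernel_size = 3L,
                          pool_every = 2L,
                          pool_window = 2L,
                          pool_stride = NULL,
                          hidden_width = 100L,
                          num_classes = 2L,
                          use_bias = TRUE,
                          output = c("softmax", "sigmoid")) {
  output <- match.arg(output)
  if (is.null(pool_stride)) pool_stride <- pool_window
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, all(input_shape >= 1),
            kernel_size >= 1, num_classes >= 2, hidden_width >= 0,
            pool_window >= 1, pool_stride == pool_window)
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) && any(conv_filters < 1))
    stop("conv_filters must be positive")

  h <- input_shape[1]; w <- input_shape[2]; ch <- input_shape[3]
  layers <- list()
  for (i in seq_along(conv_filters)) {
    f <- conv_filters[i]
    if (h < kernel_size || w < kernel_size)
      stop(sprintf(
        "invalid architecture: conv layer %d needs a %dx%d input, got %dx%d",
        i, kernel_size, kernel_size, h, w))
    h <- h - kernel_size + 1L; w <- w - kernel_size + 1L
    layers[[length(layers) + 1L]] <-
      list(type = "conv", filters = f, in_channels = ch, kernel = kernel_size,
           out_shape = c(h, w, f))
    ch <- f
    layers[[length(layers) + 1L]] <- list(type = "relu")
    if (pool_every > 0 && i %% pool_every == 0) {
      if (h < pool_window || w < pool_window)
        stop(sprintf(
          "invalid architecture: pool after conv layer %d needs a %dx%d input, got %dx%d",
          i, pool_window, pool_window, h, w))
      h <- h %/% pool_window; w <- w %/% pool_window
      layers[[length(layers) + 1L]] <-
        list(type = "pool", window = pool_window, out_shape = c(h, w, ch))
    }
  }
  flatten_size <- as.integer(h * w * ch)
  layers[[length(layers) + 1L]] <- list(type = "flatten", size = flatten_size)
  n_in <- flatten_size
  if (hidden_width > 0) {
    layers[[length(layers) + 1L]] <-
      list(type = "dense", n_in = n_in, n_out = as.integer(hidden_width))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    n_in <- as.integer(hidden_width)
  }
  layers[[length(layers) + 1L]] <-
    list(type = "dense", n_in = n_in, n_out = as.integer(num_classes))

  spec <- structure(list(
    input_shape = input_shape, conv_filters = conv_filters,
    kernel_size = as.integer(kernel_size), pool_every = as.integer(pool_every),
    pool_window = as.integer(pool_window), pool_stride = as.integer(pool_stride),
    hidden_width = as.integer(hidden_width), num_classes = as.integer(num_classes),
    use_bias = isTRUE(use_bias), output = output,
    layers = layers, final_map = c(h, w, ch), flatten_size = flatten_size
  ), class = "cnn_spec")
  spec$n_weights <- count_weights(spec)
  spec
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> input %s | %d conv layer(s) | final map %s | %d weights\n",
              paste(x$input_shape, collapse = "x"), length(x$conv_filters),
              paste(x$final_map, collapse = "x"), x$n_weights))
  invisible(x)
}

#' Count trainable parameters of a network specification
#'
#' Sums conv filter weights, dense weights, and (when enabled) all bias
#' terms. This is the length of the flat weight vector the genetic
#' algorithm uses as its chromosome.
#'
#' @param spec a `cnn_spec`.
#' @return integer parameter count.
#' @export
count_weights <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  n <- 0L
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      n <- n + ly$filters * ly$kernel^2 * ly$in_channels +
        if (spec$use_bias) ly$filters else 0L
    } else if (ly$type == "dense") {
      n <- n + ly$n_out * ly$n_in + if (spec$use_bias) ly$n_out else 0L
    }
  }
  as.integer(n)
}

#' Randomly initialize a weight set
#'
#' Draws every parameter i.i.d. from a uniform or normal distribution.
#' Defaults: uniform on \[-0.1, 0.1\]; normal with mean 0, sd 0.1. The same
#' seed always yields the same weights.
#'
#' @param spec a `cnn_spec`.
#' @param dist `"uniform"` or `"normal"`.
#' @param seed integer seed.
#' @param range half-width of the uniform interval.
#' @param sd standard deviation of the normal.
#' @return A `cnn_weights` object: `conv` (list of `W` kxkxCxF arrays and
#'   `b` length-F vectors) and `dense` (list of `W` out-x-in matrices and
#'   `b` vectors), matching `spec` exactly.
#' @export
init_weights <- function(spec, dist = c("uniform", "normal"), seed = 0L,
                         range = 0.1, sd = 0.1) {
  stopifnot(inherits(spec, "cnn_spec"))
  dist <- match.arg(dist)
  draw <- if (dist == "uniform") {
    function(n) runif(n, -range, range)
  } else {
    function(n) rnorm(n, 0, sd)
  }
  with_seed(seed, {
    conv <- list(); dense <- list()
    for (ly in spec$layers) {
      if (ly$type == "conv") {
        W <- array(draw(ly$kernel^2 * ly$in_channels * ly$filters),
                   dim = c(ly$kernel, ly$kernel, ly$in_channels, ly$filters))
        b <- if (spec$use_bias) draw(ly$filters) else numeric(ly$filters)
        conv[[length(conv) + 1L]] <- list(W = W, b = b)
      } else if (ly$type == "dense") {
        W <- matrix(draw(ly$n_out * ly$n_in), nrow = ly$n_out, ncol = ly$n_in)
        b <- if (spec$use_bias) draw(ly$n_out) else numeric(ly$n_out)
        dense[[length(dense) + 1L]] <- list(W = W, b = b)
      }
    }
    structure(list(conv = conv, dense = dense), class = "cnn_weights")
  })
}

# All-zero weight set with the shapes implied by spec.
zero_weights <- function(spec) {
  w <- init_weights(spec, "uniform", seed = 0L, range = 0)
  for (i in seq_along(w$conv)) w$conv[[i]]$b[] <- 0
  for (i in seq_along(w$dense)) w$dense[[i]]$b[] <- 0
  w
}

#' Valid convolution of a feature map
#'
#' Stride-1, no-padding convolution: each output cell is the dot product of
#' a filter with the aligned input patch, plus that filter's bias.
#'
#' @param input H x W x C numeric array.
#' @param filters k x k x C x F numeric array.
#' @param biases length-F numeric vector.
#' @return (H-k+1) x (W-k+1) x F array.
#' @export
convolve_valid <- function(input, filters, biases = NULL) {
  stopifnot(length(dim(input)) == 3, length(dim(filters)) == 4)
  if (is.null(biases)) biases <- numeric(dim(filters)[4])
  if (dim(filters)[3] != dim(input)[3])
    stop("filter depth must equal input channels")
  if (length(biases) != dim(filters)[4])
    stop("one bias per filter required")
  conv_forward_cpp(input, filters, as.numeric(biases))
}

#' Average pooling
#'
#' Replaces each non-overlapping `window` x `window` block with its mean;
#' trailing rows/columns that do not fill a block are dropped.
#'
#' @param input H x W x C numeric array.
#' @param window pooling window (and stride).
#' @return floor(H/window) x floor(W/window) x C array.
#' @export
average_pool <- function(input, window = 2L) {
  stopifnot(length(dim(input)) == 3)
  avgpool_forward_cpp(input, as.integer(window))
}

#' Rectified linear activation, max(0, x)
#' @param x numeric vector or array.
#' @return same shape, negative entries replaced by 0.
#' @export
relu <- function(x) pmax(x, 0)

#' Logistic sigmoid, 1 / (1 + exp(-x))
#'
#' Numerically stable for large |x| (never overflows).
#' @param x numeric.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Dense (fully connected) layer, y = W x + b
#' @param x input vector.
#' @param w out-x-in weight matrix.
#' @param b length-out bias vector.
#' @return length-out vector.
#' @export
dense_forward <- function(x, w, b) {
  if (ncol(w) != length(x) || nrow(w) != length(b))
    stop("dense layer shape mismatch")
  drop(w %*% x) + b
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Forward pass retaining every intermediate activation (for backprop).
# Returns list(scores=, logits=, cache=list per layer).
forward_cached <- function(spec, weights, image) {
  if (!identical(dim(image), as.integer(spec$input_shape)) &&
      !identical(as.integer(dim(image)), as.integer(spec$input_shape)))
    stop("image does not match spec input_shape")
  ci <- 0L; di <- 0L
  x <- image
  cache <- vector("list", length(spec$layers))
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    if (ly$type == "conv") {
      ci <- ci + 1L
      cache[[li]] <- list(input = x, idx = ci)
      x <- conv_forward_cpp(x, weights$conv[[ci]]$W, weights$conv[[ci]]$b)
    } else if (ly$type == "relu") {
      cache[[li]] <- list(pre = x)
      x <- pmax(x, 0)
    } else if (ly$type == "pool") {
      cache[[li]] <- list(in_dim = dim(x))
      x <- avgpool_forward_cpp(x, ly$window)
    } else if (ly$type == "flatten") {
      cache[[li]] <- list(in_dim = dim(x))
      x <- as.numeric(x)
    } else if (ly$type == "dense") {
      di <- di + 1L
      cache[[li]] <- list(input = x, idx = di)
      x <- drop(weights$dense[[di]]$W %*% x) + weights$dense[[di]]$b
    }
  }
  logits <- x
  scores <- if (spec$output == "softmax") {
    softmax(logits)
  } else {
    s <- sigmoid(logits)
    s / sum(s)
  }
  list(scores = scores, logits = logits, cache = cache)
}

#' CNN forward pass
#'
#' Applies the conv/ReLU/pool chain, flattening, and the dense head of
#' `spec`, returning normalized class scores (non-negative, summing to 1).
#'
#' @param spec a `cnn_spec`.
#' @param weights a matching `cnn_weights`.
#' @param image numeric array shaped like `spec$input_shape`.
#' @return numeric vector of `spec$num_classes` class scores.
#' @export
cnn_forward <- function(spec, weights, image) {
  forward_cached(spec, weights, image)$scores
}

#' Predict class labels
#'
#' Argmax of the class scores per image; ties resolve to the lower class
#' index (0 = benign).
#'
#' @param spec a `cnn_spec`.
#' @param weights a matching `cnn_weights`.
#' @param images a single image array, a list of image arrays, or an
#'   `image_dataset`.
#' @return integer vector of labels (0 = benign, 1 = malignant, ...).
#' @export
cnn_predict <- function(spec, weights, images) {
  imgs <- as_image_list(images)
  vapply(imgs, function(im) {
    s <- cnn_forward(spec, weights, im)
    which.max(s) - 1L   # which.max takes the first maximum: ties -> class 0
  }, integer(1))
}

as_image_list <- function(images) {
  if (inherits(images, "image_dataset")) return(images$images)
  if (is.list(images)) return(images)
  if (is.array(images) && length(dim(images)) == 3) return(list(images))
  stop("images must be an array, a list of arrays, or an image_dataset")
}

#' Flatten a weight set into the GA chromosome vector
#'
#' Serialization order is fixed: conv layers in network order, each filter
#' in turn serialized row-major over (row, column, channel), then the
#' layer's biases; then dense layers, each weight matrix row-major
#' (output-neuron rows), then its biases. When biases are disabled they
#' are omitted. `restore_weights()` inverts this exactly.
#'
#' @param weights a `cnn_weights`.
#' @param spec the owning `cnn_spec`.
#' @return numeric vector of length `count_weights(spec)`.
#' @export
flatten_weights <- function(weights, spec) {
  stopifnot(inherits(weights, "cnn_weights"), inherits(spec, "cnn_spec"))
  parts <- list()
  for (cw in weights$conv) {
    k <- dim(cw$W)[1]; C <- dim(cw$W)[3]; F_ <- dim(cw$W)[4]
    # row-major per filter: channel fastest, then column, then row
    v <- as.numeric(aperm(cw$W, c(3L, 2L, 1L, 4L)))
    parts[[length(parts) + 1L]] <- v
    if (spec$use_bias) parts[[length(parts) + 1L]] <- cw$b
  }
  for (dw in weights$dense) {
    parts[[length(parts) + 1L]] <- as.numeric(t(dw$W))
    if (spec$use_bias) parts[[length(parts) + 1L]] <- dw$b
  }
  out <- unlist(parts, use.names = FALSE)
  if (length(out) != spec$n_weights)
    stop("weight set does not match spec")
  out
}

#' Rebuild a weight set from its flat chromosome vector
#'
#' Exact inverse of [flatten_weights()].
#'
#' @param vec numeric vector of length `count_weights(spec)`.
#' @param spec a `cnn_spec`.
#' @return a `cnn_weights`.
#' @export
restore_weights <- function(vec, spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (length(vec) != spec$n_weights)
    stop(sprintf("weight vector length %d does not match spec (%d)",
                 length(vec), spec$n_weights))
  pos <- 0L
  take <- function(n) {
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + as.integer(n)
    out
  }
  conv <- list(); dense <- list()
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      k <- ly$kernel; C <- ly$in_channels; F_ <- ly$filters
      v <- take(k * k * C * F_)
      W <- aperm(array(v, dim = c(C, k, k, F_)), c(3L, 2L, 1L, 4L))
      b <- if (spec$use_bias) take(F_) else numeric(F_)
      conv[[length(conv) + 1L]] <- list(W = W, b = b)
    } else if (ly$type == "dense") {
      W <- t(matrix(take(ly$n_out * ly$n_in), nrow = ly$n_in, ncol = ly$n_out))
      b <- if (spec$use_bias) take(ly$n_out) else numeric(ly$n_out)
      dense[[length(dense) + 1L]] <- list(W = W, b = b)
    }
  }
  structure(list(conv = conv, dense = dense), class = "cnn_weights")
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single JSON file holding the architecture settings and
#' the flat weight vector at full double precision; `load_checkpoint()`
#' round-trips it exactly.
#'
#' @param spec a `cnn_spec`.
#' @param weights a matching `cnn_weights`.
#' @param path file to write / read.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns `list(spec=, weights=)`.
#' @export
save_checkpoint <- function(spec, weights, path) {
  payload <- list(
    format = "evocnn-checkpoint-1",
    spec = list(
      input_shape = spec$input_shape, conv_filters = spec$conv_filters,
      kernel_size = spec$kernel_size, pool_every = spec$pool_every,
      pool_window = spec$pool_window, hidden_width = spec$hidden_width,
      num_classes = spec$num_classes, use_bias = spec$use_bias,
      output = spec$output),
    weights = flatten_weights(weights, spec)
  )
  # I(17): 17 significant digits, the shortest representation that
  # round-trips IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "evocnn-checkpoint-1"))
    stop("not an evocnn checkpoint: ", path)
  s <- payload$spec
  spec <- build_network(
    input_shape = s$input_shape, conv_filters = s$conv_filters,
    kernel_size = s$kernel_size, pool_every = s$pool_every,
    pool_window = s$pool_window, pool_stride = s$pool_window,
    hidden_width = s$hidden_width, num_classes = s$num_classes,
    use_bias = s$use_bias, output = s$output)
  list(spec = spec, weights = restore_weights(as.numeric(payload$weights), spec))
}
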