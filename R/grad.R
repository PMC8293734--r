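#' Gradient-descent configuration
#'
#' @param learning_rate step size alpha (default 0.001).
#' @param batch_size images per mini-batch (default 32).
#' @param iterations number of mini-batch updates.
#' @param init_dist `"uniform"` or `"normal"` initialization.
#' @param seed integer seed.
#' @return a `gd_config` list.
#' @export
gd_config <- function(learning_rate = 0.001, batch_size = 32L,
                      iterations = 100L, init_dist = c("uniform", "normal"),
                      seed = 0L) {
  init_dist <- match.arg(init_dist)
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 init_dist = init_dist, seed = as.integer(seed)),
            class = "gd_config")
}

#' Adam configuration
#'
#' Standard exponential-moment constants: beta1 = 0.9, beta2 = 0.999,
#' epsilon = 1e-8.
#'
#' @inheritParams gd_config
#' @param beta1,beta2 moment decay rates in \[0, 1).
#' @param epsilon denominator stabilizer (> 0).
#' @return an `adam_config` list.
#' @export
adam_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, batch_size = 32L, iterations = 100L,
                        init_dist = c("uniform", "normal"), seed = 0L) {
  init_dist <- match.arg(init_dist)
  stopifnot(learning_rate > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            epsilon > 0, batch_size >= 1, iterations >= 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), init_dist = init_dist,
                 seed = as.integer(seed)),
            class = "adam_config")
}

#' Mean cross-entropy loss of the network on a batch
#'
#' Mean categorical cross-entropy of the softmax class scores against the
#' true labels; the differentiable surrogate the gradient trainers
#' minimize (the GA minimizes the error rate directly).
#'
#' @param spec a `cnn_spec`.
#' @param weights a `cnn_weights`.
#' @param images list of image arrays or an `image_dataset`.
#' @param labels integer 0-based truth labels.
#' @return non-negative scalar loss.
#' @export
cnn_loss <- function(spec, weights, images, labels = NULL) {
  if (inherits(images, "image_dataset") && is.null(labels))
    labels <- images$meta$y
  imgs <- as_image_list(images)
  if (length(imgs) == 0) stop("loss batch must be non-empty")
  stopifnot(length(labels) == length(imgs))
  p <- vapply(seq_along(imgs), function(i) {
    s <- cnn_forward(spec, weights, imgs[[i]])
    s[labels[i] + 1L]
  }, numeric(1))
  -mean(log(pmax(p, 1e-300)))
}

#' Gradient of the loss with respect to every parameter
#'
#' Exact reverse-mode differentiation of [cnn_loss()] through the dense,
#' ReLU, flatten, average-pool and convolution layers. The batch gradient
#' is the mean of the per-example gradients.
#'
#' @inheritParams cnn_loss
#' @return a `cnn_weights`-shaped gradient.
#' @export
cnn_backward <- function(spec, weights, images, labels = NULL) {
  if (inherits(images, "image_dataset") && is.null(labels))
    labels <- images$meta$y
  imgs <- as_image_list(images)
  if (length(imgs) == 0) stop("gradient batch must be non-empty")
  stopifnot(length(labels) == length(imgs))
  if (spec$output != "softmax")
    stop("gradient training requires output = \"softmax\"")
  grad <- zero_weights(spec)
  nb <- length(imgs)
  for (i in seq_len(nb)) {
    g1 <- backward_single(spec, weights, imgs[[i]], labels[i])
    for (l in seq_along(grad$conv)) {
      grad$conv[[l]]$W <- grad$conv[[l]]$W + g1$conv[[l]]$W / nb
      grad$conv[[l]]$b <- grad$conv[[l]]$b + g1$conv[[l]]$b / nb
    }
    for (l in seq_along(grad$dense)) {
      grad$dense[[l]]$W <- grad$dense[[l]]$W + g1$dense[[l]]$W / nb
      grad$dense[[l]]$b <- grad$dense[[l]]$b + g1$dense[[l]]$b / nb
    }
  }
  grad
}

# Per-example reverse pass. Softmax + cross-entropy combine to the
# classical logit gradient p - onehot(y).
backward_single <- function(spec, weights, image, label) {
  fw <- forward_cached(spec, weights, image)
  g <- fw$scores
  g[label + 1L] <- g[label + 1L] - 1
  grad <- list(conv = vector("list", length(weights$conv)),
               dense = vector("list", length(weights$dense)))
  for (li in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[li]]
    cc <- fw$cache[[li]]
    if (ly$type == "dense") {
      W <- weights$dense[[cc$idx]]$W
      grad$dense[[cc$idx]] <- list(W = outer(g, cc$input), b = g)
      g <- drop(crossprod(W, g))
    } else if (ly$type == "relu") {
      g <- g * (cc$pre > 0)
    } else if (ly$type == "flatten") {
      g <- array(g, dim = cc$in_dim)
    } else if (ly$type == "pool") {
      g <- avgpool_backward_cpp(g, cc$in_dim[1], cc$in_dim[2], ly$window)
    } else if (ly$type == "conv") {
      bk <- conv_backward_cpp(cc$input, weights$conv[[cc$idx]]$W, g)
      grad$conv[[cc$idx]] <- list(W = bk$filters, b = bk$biases)
      g <- bk$input
    }
  }
  if (!spec$use_bias) {
    for (l in seq_along(grad$conv)) grad$conv[[l]]$b[] <- 0
    for (l in seq_along(grad$dense)) grad$dense[[l]]$b[] <- 0
  }
  grad
}

#' One gradient-descent step, w - alpha * g
#'
#' @param w numeric weight vector.
#' @param g gradient vector of the same length.
#' @param alpha learning rate.
#' @return updated weight vector.
#' @export
gd_step <- function(w, g, alpha) {
  if (length(w) != length(g)) stop("weight/gradient length mismatch")
  w - alpha * g
}

#' Initialize Adam optimizer state
#'
#' @param n weight-vector length.
#' @return list with zero first/second moment vectors `m`, `v` and step
#'   counter `t = 0`.
#' @export
adam_state_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

#' One Adam step
#'
#' Bias-corrected first/second-moment update:
#' `m <- beta1 m + (1-beta1) g`, `v <- beta2 v + (1-beta2) g^2`,
#' `w <- w - lr * mhat / (sqrt(vhat) + epsilon)`.
#'
#' @param state an [adam_state_init()] list.
#' @param w weight vector.
#' @param g gradient vector.
#' @param config an `adam_config`.
#' @return `list(state=, w=)` with `t` incremented.
#' @export
adam_step <- function(state, w, g, config) {
  if (length(w) != length(g) || length(state$m) != length(w))
    stop("weight/gradient/state length mismatch")
  t <- state$t + 1L
  m <- config$beta1 * state$m + (1 - config$beta1) * g
  v <- config$beta2 * state$v + (1 - config$beta2) * g * g
  mhat <- m / (1 - config$beta1^t)
  vhat <- v / (1 - config$beta2^t)
  list(state = list(m = m, v = v, t = t),
       w = w - config$learning_rate * mhat / (sqrt(vhat) + config$epsilon))
}

#' Train with mini-batch gradient descent
#'
#' Seeded initialization, then one mini-batch update per iteration
#' (batches cycle through a seeded shuffle of the training set). The loss
#' recorded at each iteration is the batch loss at the pre-update weights.
#'
#' @param spec a `cnn_spec`.
#' @param train_set a non-empty `image_dataset`.
#' @param config a `gd_config`.
#' @return `list(weights=, loss_history=)` (history length = iterations).
#' @export
train_gd <- function(spec, train_set, config) {
  train_sgd_core(spec, train_set, config, adam = FALSE)
}

#' Train with the Adam optimizer
#'
#' As [train_gd()] but with [adam_step()] updates.
#'
#' @param spec a `cnn_spec`.
#' @param train_set a non-empty `image_dataset`.
#' @param config an `adam_config`.
#' @return `list(weights=, loss_history=)`.
#' @export
train_adam <- function(spec, train_set, config) {
  train_sgd_core(spec, train_set, config, adam = TRUE)
}

train_sgd_core <- function(spec, train_set, config, adam) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(train_set, "image_dataset"))
  n <- length(train_set$images)
  if (n == 0) stop("training set is empty")
  labels <- train_set$meta$y
  with_seed(config$seed, {
    init_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    weights <- init_weights(spec, config$init_dist, seed = init_seed)
    wv <- flatten_weights(weights, spec)
    state <- if (adam) adam_state_init(length(wv))
    next_batch <- make_batch_cycle(n, min(config$batch_size, n))
    history <- numeric(config$iterations)
    if (config$iterations > 0) {
      for (it in seq_len(config$iterations)) {
        idx <- next_batch()
        w <- restore_weights(wv, spec)
        history[it] <- cnn_loss(spec, w, train_set$images[idx], labels[idx])
        g <- flatten_weights(cnn_backward(spec, w, train_set$images[idx],
                                          labels[idx]), spec)
        if (adam) {
          st <- adam_step(state, wv, g, config)
          state <- st$state
          wv <- st$w
        } else {
          wv <- gd_step(wv, g, config$learning_rate)
        }
      }
    }
    list(weights = restore_weights(wv, spec), loss_history = history)
  })
}
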