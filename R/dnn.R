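#' Architecture of the feedforward classifier
#'
#' A fully connected network with ReLU hidden layers (two by default) and
#' a softmax output layer, one output unit per class. Weights are
#' initialized with a scaled-uniform fan-in scheme,
#' U(-sqrt(6/fan_in), sqrt(6/fan_in)), suited to ReLU units; biases start
#' at zero.
#'
#' @param n_input Input dimension m (number of selected genes).
#' @param hidden Integer vector of hidden-layer widths; default `c(64, 32)`.
#' @param n_output Number of classes (softmax width); default 2.
#' @param init_seed Seed for the weight initialization.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_input, hidden = c(64L, 32L), n_output = 2L,
                         init_seed = 1L) {
  sizes <- c(as.integer(n_input), as.integer(hidden), as.integer(n_output))
  if (any(sizes < 1L)) stop("all layer sizes must be >= 1")
  structure(
    list(layer_sizes = sizes, hidden = as.integer(hidden),
         n_input = as.integer(n_input), n_output = as.integer(n_output),
         init_seed = as.integer(init_seed)),
    class = "network_spec"
  )
}

#' Initialize network parameters
#'
#' @param spec A [network_spec()].
#' @return An object of class `network_params`: lists `W` (fan_in x
#'   fan_out weight matrices) and `b` (bias vectors), one per layer.
#' @export
init_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- spec$layer_sizes
  n_layers <- length(sizes) - 1L
  with_seed(spec$init_seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- sizes[l]
      limit <- sqrt(6 / fan_in)
      W[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1], -limit, limit),
                       fan_in, sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(W = W, b = b), class = "network_params")
  })
}

#' Softmax over the last dimension
#'
#' `exp(z_i - max z) / sum_j exp(z_j - max z)`: shift-invariant and safe
#' against overflow; rows sum to one.
#'
#' @param z Numeric vector, or matrix with one logit row per sample.
#' @return Probabilities with the same shape as `z`.
#' @examples
#' softmax(c(0, 0))          # 0.5 0.5
#' softmax(log(c(1, 3)))     # 0.25 0.75
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    shifted <- z - apply(z, 1, max)
    e <- exp(shifted)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Forward pass through the network
#'
#' Hidden layers compute `A_{l+1} = relu(A_l W_l + b_l)`; the last layer
#' applies [softmax()]. All intermediate pre-activations and activations
#' are returned for backpropagation.
#'
#' @param params A `network_params`.
#' @param x Input: numeric vector (one sample) or samples x features
#'   matrix.
#' @return list `a` (activations; `a[[1]]` is the input, the last element
#'   the class probabilities) and `z` (pre-activations per layer).
#' @export
dnn_forward <- function(params, x) {
  stopifnot(inherits(params, "network_params"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(params$W[[1]])) {
    stop("input has ", ncol(x), " features but the network expects ",
         nrow(params$W[[1]]))
  }
  n_layers <- length(params$W)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  a[[1]] <- x
  for (l in seq_len(n_layers)) {
    z[[l]] <- sweep(a[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    a[[l + 1]] <- if (l < n_layers) pmax(z[[l]], 0) else softmax(z[[l]])
  }
  list(a = a, z = z)
}

#' Squared-error loss
#'
#' `||t - p||^2 / 2` between the one-hot target and predicted
#' probabilities of a single sample.
#'
#' @param t Target vector.
#' @param p Prediction vector of the same length.
#' @return The loss value.
#' @export
loss_squared <- function(t, p) {
  if (length(t) != length(p)) stop("target and prediction lengths differ")
  sum((t - p)^2) / 2
}

#' Negative log-likelihood loss
#'
#' `-log p[t]` for the true class index `t`. The probability is floored
#' at 1e-12 so a confidently wrong prediction yields a large finite loss
#' rather than infinity.
#'
#' @param t True class index (1-based).
#' @param p Probability vector.
#' @return The loss value.
#' @export
loss_nll <- function(t, p) {
  -log(max(p[t], 1e-12))
}

#' Backpropagation through the network
#'
#' Gradients of the mean per-sample loss over the batch with respect to
#' every weight and bias. For the NLL loss the softmax and log combine
#' into the output delta `p - onehot(t)`; the squared loss propagates
#' through the softmax Jacobian.
#'
#' @param params A `network_params`.
#' @param activations Output of [dnn_forward()] on the same batch.
#' @param t Integer vector of true class indices (1-based), one per
#'   sample in the batch.
#' @param loss `"nll"` or `"squared"`.
#' @return list `W` and `b` of gradients, shaped like the parameters.
#' @export
dnn_backward <- function(params, activations, t, loss = c("nll", "squared")) {
  loss <- match.arg(loss)
  a <- activations$a
  z <- activations$z
  n_layers <- length(params$W)
  n <- nrow(a[[1]])
  n_out <- ncol(a[[n_layers + 1L]])
  P <- a[[n_layers + 1L]]
  Tm <- matrix(0, n, n_out)
  Tm[cbind(seq_len(n), t)] <- 1

  delta <- switch(loss,
    nll = (P - Tm) / n,
    squared = {
      g <- P - Tm                      # dL/dp
      (P * (g - rowSums(g * P))) / n   # through the softmax Jacobian
    })

  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (z[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' RMSprop optimizer state
#'
#' RMSprop keeps an exponentially decaying average of squared gradients,
#' `G_t = beta * G_{t-1} + (1 - beta) * g (.) g`, and scales each
#' parameter's step by the inverse root of that accumulator:
#' `theta <- theta - alpha * g / sqrt(G_t + eps)`.
#'
#' @param learning_rate Step size alpha; default 1e-3.
#' @param decay Accumulator decay beta in \[0, 1); default 0.9.
#' @param epsilon Stabilizer added inside the square root; default 1e-8.
#' @return An object of class `rmsprop_state` with a zero accumulator and
#'   step counter `t = 0`.
#' @export
rmsprop_state <- function(learning_rate = 1e-3, decay = 0.9,
                          epsilon = 1e-8) {
  if (decay < 0 || decay >= 1) stop("decay must be in [0, 1)")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(
    list(G = NULL, alpha = learning_rate, beta = decay, epsilon = epsilon,
         t = 0L),
    class = "rmsprop_state"
  )
}

#' One RMSprop parameter update
#'
#' Applies the accumulator update and scaled step to every tensor in
#' `params`. The accumulator is allocated (all zeros) on the first call.
#'
#' @param state An [rmsprop_state()].
#' @param params Parameters: a `network_params`, or any (possibly nested)
#'   list of numeric arrays, or a bare numeric vector.
#' @param grads Gradients with the same shape as `params`.
#' @return list `params` (updated) and `state` (updated accumulator, step
#'   counter incremented).
#' @export
rmsprop_update <- function(state, params, grads) {
  stopifnot(inherits(state, "rmsprop_state"))
  if (is.null(state$G)) state$G <- zeros_like(params)
  upd <- rms_step(state$G, params, grads, state$alpha, state$beta,
                  state$epsilon)
  state$G <- upd$G
  state$t <- state$t + 1L
  list(params = upd$params, state = state)
}

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

rms_step <- function(G, params, grads, alpha, beta, eps) {
  if (is.list(params)) {
    out_p <- params
    out_G <- G
    for (i in seq_along(params)) {
      r <- rms_step(G[[i]], params[[i]], grads[[i]], alpha, beta, eps)
      out_p[[i]] <- r$params
      out_G[[i]] <- r$G
    }
    # keep the network_params class on the updated container
    attributes(out_p) <- attributes(params)
    list(params = out_p, G = out_G)
  } else {
    G_new <- beta * G + (1 - beta) * grads * grads
    list(params = params - alpha * grads / sqrt(G_new + eps), G = G_new)
  }
}

#' Training options
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size. The default of 8 is deliberately
#'   small: expression cohorts have few samples and many features, and
#'   small-batch gradient noise is the only regularizer this plain
#'   network has.
#' @param loss `"nll"` (default) or `"squared"`.
#' @param shuffle_seed Seed for the per-epoch shuffle.
#' @param record_history Record per-epoch loss/accuracy.
#' @return An object of class `training_options`.
#' @export
training_options <- function(epochs = 200L, batch_size = 8L,
                             loss = c("nll", "squared"),
                             shuffle_seed = 1L, record_history = TRUE) {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         loss = loss, shuffle_seed = as.integer(shuffle_seed),
         record_history = isTRUE(record_history)),
    class = "training_options"
  )
}

#' Train the classifier with RMSprop
#'
#' Mini-batch gradient descent with seeded shuffling: each epoch permutes
#' the samples, walks them in batches, and applies one [rmsprop_update()]
#' per batch. Training is fully deterministic given `spec$init_seed` and
#' `opts$shuffle_seed`.
#'
#' @param spec A [network_spec()].
#' @param x Training inputs, samples x features matrix.
#' @param y Integer class indices (1-based) or a factor.
#' @param opts A [training_options()].
#' @param learning_rate,decay,epsilon RMSprop settings, see
#'   [rmsprop_state()].
#' @param x_val,y_val Optional validation set recorded in the history.
#' @return list `params` (trained `network_params`), `history` (data
#'   frame per epoch: `epoch`, `loss`, `accuracy`, and validation columns
#'   if a validation set was given), `spec`, `opts`.
#' @export
dnn_train <- function(spec, x, y, opts = training_options(),
                      learning_rate = 1e-3, decay = 0.9, epsilon = 1e-8,
                      x_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(opts, "training_options"))
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  n <- nrow(x)
  if (length(y) != n) stop("x and y disagree on the number of samples")
  if (ncol(x) != spec$n_input) {
    stop("x has ", ncol(x), " features but the spec expects ", spec$n_input)
  }
  params <- init_network(spec)
  state <- rmsprop_state(learning_rate, decay, epsilon)
  history <- NULL

  for (epoch in seq_len(opts$epochs)) {
    order <- with_seed(opts$shuffle_seed + epoch, sample.int(n))
    starts <- seq(1L, n, by = opts$batch_size)
    for (s in starts) {
      idx <- order[s:min(s + opts$batch_size - 1L, n)]
      acts <- dnn_forward(params, x[idx, , drop = FALSE])
      grads <- dnn_backward(params, acts, y[idx], opts$loss)
      upd <- rmsprop_update(state, params, grads)
      params <- upd$params
      state <- upd$state
    }
    if (opts$record_history) {
      tr <- evaluate_epoch(params, x, y, opts$loss)
      row <- data.frame(epoch = epoch, loss = tr$loss, accuracy = tr$acc)
      if (!is.null(x_val)) {
        va <- evaluate_epoch(params, as.matrix(x_val), as.integer(y_val),
                             opts$loss)
        row$val_loss <- va$loss
        row$val_accuracy <- va$acc
      }
      if (!is.finite(tr$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      history <- rbind(history, row)
    }
  }
  list(params = params, history = history, spec = spec, opts = opts)
}

evaluate_epoch <- function(params, x, y, loss) {
  P <- dnn_forward(params, x)$a[[length(params$W) + 1L]]
  n <- nrow(P)
  l <- if (loss == "nll") {
    mean(-log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  } else {
    Tm <- matrix(0, n, ncol(P))
    Tm[cbind(seq_len(n), y)] <- 1
    mean(rowSums((Tm - P)^2) / 2)
  }
  pred <- max.col(P, ties.method = "first")
  list(loss = l, acc = mean(pred == y))
}

#' Predict classes and probabilities
#'
#' @param params A trained `network_params`.
#' @param x Samples x features matrix (or one sample as a vector).
#' @return list `labels` (integer class indices; ties broken toward the
#'   lower index) and `probabilities` (samples x classes matrix of
#'   softmax rows).
#' @export
dnn_predict <- function(params, x) {
  P <- dnn_forward(params, x)$a[[length(params$W) + 1L]]
  list(labels = max.col(P, ties.method = "first"), probabilities = P)
}

#' Serialize a trained model to JSON
#'
#' Stores layer shapes, flattened weights and biases at full precision,
#' and the originating spec/options, so [read_dnn()] restores a
#' numerically identical model.
#'
#' @param fit The list returned by [dnn_train()].
#' @param path Output path.
#' @export
write_dnn <- function(fit, path) {
  obj <- list(
    layer_sizes = fit$spec$layer_sizes,
    init_seed = fit$spec$init_seed,
    loss = fit$opts$loss,
    W = lapply(fit$params$W, function(w) list(dim = dim(w),
                                              data = as.numeric(w))),
    b = fit$params$b
  )
  atomic_write(path, function(tmp) {
    # I(17) significant digits: doubles survive the text round trip exactly
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17))
  })
}

#' Restore a model written by [write_dnn()]
#'
#' @param path JSON file path.
#' @return A list with `params` (a `network_params`) and `layer_sizes`.
#' @export
read_dnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  W <- lapply(obj$W, function(w) {
    matrix(vapply(w$data, as.numeric, numeric(1)),
           w$dim[[1]], w$dim[[2]])
  })
  b <- lapply(obj$b, function(bb) vapply(bb, as.numeric, numeric(1)))
  list(params = structure(list(W = W, b = b), class = "network_params"),
       layer_sizes = unlist(obj$layer_sizes))
}
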