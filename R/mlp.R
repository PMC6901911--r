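# Small feed-forward multilayer perceptron with bipolar-sigmoid activation
# trained by batch back-propagation with momentum. Default architecture
# 8:5:1 for the eight discriminant latent variables; targets are coded
# DIL = +1, NT = -1 and the loss is mean squared error.

# Bipolar sigmoid f(x) = 2 / (1 + exp(-x)) - 1 = tanh(x/2); derivative in
# terms of the output: f'(x) = (1 - f^2) / 2.
bipolar_sigmoid <- function(x) 2 / (1 + exp(-x)) - 1
bipolar_sigmoid_deriv <- function(f) (1 - f^2) / 2

#' Create an untrained MLP
#'
#' Weights (including bias terms) are drawn uniformly from \[-0.5, 0.5\]
#' using the stored seed, so the same seed always yields the same initial
#' network.
#'
#' @param n_input input dimension (8 for the latent feature set).
#' @param n_hidden hidden-layer size (default 5).
#' @param seed initialization seed.
#' @return object of class `mlp_model` with weight matrices `W1`
#'   (hidden x input+1) and `W2` (1 x hidden+1).
#' @export
mlp_new <- function(n_input = 8L, n_hidden = 5L, seed = 1L) {
  withr::with_seed(seed, {
    W1 <- matrix(runif(n_hidden * (n_input + 1L), -0.5, 0.5),
                 n_hidden, n_input + 1L)
    W2 <- matrix(runif(n_hidden + 1L, -0.5, 0.5), 1L, n_hidden + 1L)
  })
  structure(list(W1 = W1, W2 = W2, n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d:%d:1, bipolar sigmoid, seed %d\n",
              x$n_input, x$n_hidden, x$seed))
  invisible(x)
}

#' Training configuration for the MLP
#'
#' @param learning_rate gradient step size (default 0.01).
#' @param momentum fraction of the previous update carried over, in \[0, 1).
#' @param max_epochs batch epochs to run.
#' @return list of class `mlp_train_config`.
#' @export
mlp_train_config <- function(learning_rate = 0.01, momentum = 0.01,
                             max_epochs = 300L) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs)),
            class = "mlp_train_config")
}

#' Forward pass of the MLP
#'
#' @param model an `mlp_model`.
#' @param x numeric vector of length `n_input` or a matrix (rows = samples).
#' @return numeric vector of scores in (-1, 1), one per sample.
#' @export
mlp_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_input)
    stop("input length ", ncol(x), " does not match n_input ", model$n_input)
  xb <- cbind(x, 1)
  h <- bipolar_sigmoid(xb %*% t(model$W1))
  hb <- cbind(h, 1)
  as.numeric(bipolar_sigmoid(hb %*% t(model$W2)))
}

# Batch gradient of the MSE loss E = mean((out - t)^2) over all samples.
mlp_gradient <- function(model, x, target) {
  n <- nrow(x)
  xb <- cbind(x, 1)
  h <- bipolar_sigmoid(xb %*% t(model$W1))
  hb <- cbind(h, 1)
  out <- as.numeric(bipolar_sigmoid(hb %*% t(model$W2)))
  err <- out - target
  delta_out <- 2 * err * bipolar_sigmoid_deriv(out) / n     # n-vector
  gW2 <- matrix(delta_out, 1) %*% hb                        # 1 x (H+1)
  delta_h <- (delta_out %*% model$W2[, seq_len(model$n_hidden), drop = FALSE]) *
    bipolar_sigmoid_deriv(h)                                # n x H
  gW1 <- t(delta_h) %*% xb                                  # H x (in+1)
  list(W1 = gW1, W2 = gW2, mse = mean(err^2), out = out)
}

#' Train the MLP by batch back-propagation with momentum
#'
#' Weight changes are accumulated over the full training set each epoch
#' (batch mode) and applied once per epoch with a momentum term. Identical
#' inputs and initial weights give identical trajectories.
#'
#' @param model an `mlp_model`.
#' @param x training inputs (n x n_input matrix).
#' @param target numeric targets in `{-1, +1}` (DIL = +1, NT = -1).
#' @param config an [mlp_train_config()].
#' @param monitor optional function(epoch, model) called after each epoch;
#'   its results are collected and returned.
#' @return the trained `mlp_model` with an `mse_trace` element (one MSE per
#'   epoch, computed before that epoch's update) and, if `monitor` is given,
#'   a `monitor` list.
#' @export
mlp_train <- function(model, x, target, config = mlp_train_config(),
                      monitor = NULL) {
  stopifnot(nrow(x) == length(target))
  vW1 <- model$W1 * 0
  vW2 <- model$W2 * 0
  trace <- numeric(config$max_epochs)
  mon <- if (is.null(monitor)) NULL else vector("list", config$max_epochs)
  for (ep in seq_len(config$max_epochs)) {
    g <- mlp_gradient(model, x, target)
    if (!is.finite(g$mse)) stop("non-finite training loss at epoch ", ep)
    trace[ep] <- g$mse
    vW1 <- -config$learning_rate * g$W1 + config$momentum * vW1
    vW2 <- -config$learning_rate * g$W2 + config$momentum * vW2
    model$W1 <- model$W1 + vW1
    model$W2 <- model$W2 + vW2
    if (!is.null(monitor)) mon[[ep]] <- monitor(ep, model)
  }
  model$mse_trace <- trace
  if (!is.null(monitor)) model$monitor <- mon
  model
}

#' Map an MLP score to a probability
#'
#' Linear mapping of the bipolar output (-1, 1) onto (0, 1).
#' @param score numeric scores from [mlp_forward()].
#' @return probabilities in (0, 1).
#' @export
score_to_probability <- function(score) (score + 1) / 2
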