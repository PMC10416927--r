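#' Elementwise activation functions
#'
#' @param name one of \code{"relu"}, \code{"softplus"}, \code{"sigmoid"}.
#' @param v numeric vector or matrix.
#' @return the transformed array.  \code{softplus} is computed
#'   overflow-safely as \code{pmax(x, 0) + log1p(exp(-|x|))}.
#' @export
apply_activation <- function(name, v) {
  switch(name,
         relu = pmax(v, 0),
         softplus = pmax(v, 0) + log1p(exp(-abs(v))),
         sigmoid = 1 / (1 + exp(-v)),
         stop(sprintf("unknown activation '%s'", name)))
}

# derivative of the activation evaluated at pre-activation z
activation_grad <- function(name, z) {
  switch(name,
         relu = (z > 0) + 0,
         softplus = 1 / (1 + exp(-z)),
         sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         stop(sprintf("unknown activation '%s'", name)))
}

#' Hyperparameter set constructor
#'
#' Bundles and validates the training hyperparameters.  RINNs always have
#' eight hidden layers; a scalar \code{hidden_sizes} is recycled.
#'
#' @param learning_rate positive SGD step size.
#' @param l1 nonnegative L1 regularization rate applied to all weight
#'   matrices (biases are not penalized).
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param activation hidden-layer activation name.
#' @param hidden_sizes integer vector of hidden layer sizes; length 8 for
#'   RINN, free for DNN.
#' @param architecture \code{"RINN"} or \code{"DNN"}.
#' @return a list of class \code{rinn_hp}.
#' @export
rinn_hp <- function(learning_rate = 0.1, l1 = 1e-4, epochs = 50,
                    batch_size = 32, activation = "softplus",
                    hidden_sizes = 10, architecture = "RINN") {
  architecture <- match.arg(architecture, c("RINN", "DNN"))
  activation <- match.arg(activation, c("relu", "softplus", "sigmoid"))
  if (architecture == "RINN") {
    if (length(hidden_sizes) == 1L) hidden_sizes <- rep(hidden_sizes, 8L)
    if (length(hidden_sizes) != 8L) {
      stop("RINN requires exactly 8 hidden layers")
    }
  }
  hidden_sizes <- as.integer(hidden_sizes)
  stopifnot(learning_rate > 0, l1 >= 0, epochs >= 0, batch_size >= 1,
            length(hidden_sizes) >= 1L, all(hidden_sizes >= 1L))
  structure(list(learning_rate = learning_rate, l1 = l1,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 activation = activation, hidden_sizes = hidden_sizes,
                 architecture = architecture),
            class = "rinn_hp")
}

#' Initialize network weights
#'
#' Weights are drawn from a symmetric uniform distribution scaled by the
#' fan-in of each layer (\code{U(-1/sqrt(fan_in), 1/sqrt(fan_in))});
#' biases start at zero.  For an RINN the input vector is concatenated
#' onto hidden layers 2--8, so those weight matrices carry
#' \code{n_inputs} extra "redundant-input" rows; the output matrix does
#' not (the redundant copies never feed the output layer).
#'
#' @param architecture \code{"RINN"} or \code{"DNN"}.
#' @param n_inputs,n_outputs input (SGA) and output (DEG) dimensions.
#' @param hp an [rinn_hp()] object (only \code{hidden_sizes} and
#'   \code{activation} are used).
#' @param seed integer seed.
#' @return an object of class \code{rinn_weights} with components
#'   \code{W} (list of weight matrices) and \code{b} (list of bias
#'   vectors).
#' @export
init_network <- function(architecture, n_inputs, n_outputs, hp, seed = 1L) {
  architecture <- match.arg(architecture, c("RINN", "DNN"))
  stopifnot(n_inputs >= 1, n_outputs >= 1)
  h <- hp$hidden_sizes
  if (architecture == "RINN" && length(h) != 8L) {
    stop("RINN requires exactly 8 hidden layers")
  }
  if (architecture == "RINN") {
    in_dims <- c(n_inputs, head(h, -1L) + n_inputs, h[length(h)])
  } else {
    in_dims <- c(n_inputs, h)
  }
  out_dims <- c(h, n_outputs)
  with_seed(seed, {
    W <- mapply(function(fi, fo) {
      s <- 1 / sqrt(fi)
      matrix(stats::runif(fi * fo, -s, s), fi, fo)
    }, in_dims, out_dims, SIMPLIFY = FALSE)
    b <- lapply(out_dims, numeric)
    structure(list(architecture = architecture, activation = hp$activation,
                   W = W, b = b, n_inputs = as.integer(n_inputs),
                   n_outputs = as.integer(n_outputs), hidden_sizes = h),
              class = "rinn_weights")
  })
}

# Forward pass keeping pre-activations and layer inputs for backprop.
forward_cache <- function(weights, X) {
  act <- weights$activation
  rinn <- weights$architecture == "RINN"
  nW <- length(weights$W)
  A <- vector("list", nW)   # input to each weight matrix
  Z <- vector("list", nW)   # pre-activations
  H <- X
  for (i in seq_len(nW - 1L)) {
    A[[i]] <- if (rinn && i > 1L) cbind(H, X) else H
    Z[[i]] <- sweep(A[[i]] %*% weights$W[[i]], 2L, weights$b[[i]], "+")
    H <- apply_activation(act, Z[[i]])
  }
  A[[nW]] <- H
  Z[[nW]] <- sweep(H %*% weights$W[[nW]], 2L, weights$b[[nW]], "+")
  P <- 1 / (1 + exp(-Z[[nW]]))  # sigmoid output head, always
  list(A = A, Z = Z, P = P)
}

#' Forward pass of a redundant-input network
#'
#' Hidden layer \eqn{i} is \eqn{h^{(i)} = \phi([h^{(i-1)}, x] W_i + b_i)}
#' for \eqn{i = 2..8} (with \eqn{h^{(1)} = \phi(x W_1 + b_1)}); the output
#' is always a sigmoid over \eqn{h^{(8)} W_9 + b_9}.
#'
#' @param weights an \code{rinn_weights} object with
#'   \code{architecture == "RINN"}.
#' @param X numeric matrix, samples x inputs.
#' @return prediction matrix in (0, 1), samples x outputs.
#' @export
forward_rinn <- function(weights, X) {
  stopifnot(inherits(weights, "rinn_weights"), weights$architecture == "RINN")
  X <- as.matrix(X)
  if (ncol(X) != weights$n_inputs) stop("input dimension mismatch")
  forward_cache(weights, X)$P
}

#' Forward pass of a plain deep network
#'
#' As [forward_rinn()] but without input concatenation:
#' \eqn{h^{(i)} = \phi(h^{(i-1)} W_i + b_i)} with a sigmoid output head.
#'
#' @inheritParams forward_rinn
#' @return prediction matrix in (0, 1).
#' @export
forward_dnn <- function(weights, X) {
  stopifnot(inherits(weights, "rinn_weights"), weights$architecture == "DNN")
  X <- as.matrix(X)
  if (ncol(X) != weights$n_inputs) stop("input dimension mismatch")
  forward_cache(weights, X)$P
}

network_forward <- function(weights, X) {
  if (weights$architecture == "RINN") forward_rinn(weights, X) else forward_dnn(weights, X)
}

#' L1-regularized binary cross-entropy objective
#'
#' The loss is the mean over all prediction-matrix entries of the binary
#' cross-entropy in natural-log units (nats), plus \code{rr} times the sum
#' of absolute values over all weight matrices.  Biases are not
#' penalized.  Predictions are clamped to \code{[1e-12, 1 - 1e-12]}
#' before taking logs.
#'
#' @param preds prediction matrix in (0, 1).
#' @param y binary matrix of the same shape.
#' @param weights an \code{rinn_weights} object (for the L1 term).
#' @param rr nonnegative regularization rate.
#' @return list with components \code{cel} (nats), \code{l1}
#'   (\eqn{\sum |w|}) and \code{total = cel + rr * l1}.
#' @export
objective <- function(preds, y, weights, rr = 0) {
  if (!identical(dim(preds), dim(y))) stop("shape mismatch between 'preds' and 'y'")
  p <- pmin(pmax(preds, 1e-12), 1 - 1e-12)
  cel <- -mean(y * log(p) + (1 - y) * log(1 - p))
  l1 <- sum(vapply(weights$W, function(w) sum(abs(w)), numeric(1)))
  list(cel = cel, l1 = l1, total = cel + rr * l1)
}

#' Analytic gradients of the regularized objective
#'
#' Backpropagation through the (R)INN, returning the gradient of
#' \code{objective(...)$total} with respect to every weight matrix and
#' bias vector.  The L1 term contributes \code{rr * sign(w)} (zero at
#' exactly zero weights).
#'
#' @param weights an \code{rinn_weights} object.
#' @param X input matrix, samples x inputs.
#' @param y binary output matrix, samples x outputs.
#' @param rr nonnegative L1 rate.
#' @return list with components \code{W} and \code{b}, matching the
#'   shapes of \code{weights$W} and \code{weights$b}.
#' @export
network_gradients <- function(weights, X, y, rr = 0) {
  X <- as.matrix(X)
  cache <- forward_cache(weights, X)
  obj <- objective(cache$P, y, weights, rr)
  nW <- length(weights$W)
  m <- weights$n_inputs
  act <- weights$activation
  n_entries <- length(y)
  gW <- vector("list", nW); gb <- vector("list", nW)

  # output head: d(total)/dZ for mean BCE with sigmoid output
  G <- (cache$P - y) / n_entries
  for (i in nW:1L) {
    gW[[i]] <- crossprod(cache$A[[i]], G) + rr * sign(weights$W[[i]])
    gb[[i]] <- colSums(G)
    if (i > 1L) {
      GA <- G %*% t(weights$W[[i]])
      if (weights$architecture == "RINN" && i < nW) {
        # hidden layers 2..8 take [h, x]: drop the gradient w.r.t. the
        # redundant input columns (the output head never sees them)
        GA <- GA[, seq_len(ncol(GA) - m), drop = FALSE]
      }
      G <- GA * activation_grad(act, cache$Z[[i - 1L]])
    }
  }
  list(W = gW, b = gb, objective = obj)
}

#' Train a network by minibatch stochastic gradient descent
#'
#' Minimizes the L1-regularized binary cross-entropy by plain SGD with
#' per-epoch reshuffling.  All randomness (initialization and shuffling)
#' derives from \code{seed}.
#'
#' @param data an [rinn_data()] object, or a list with binary matrices
#'   \code{sga} and \code{deg}.
#' @param architecture \code{"RINN"} or \code{"DNN"}.
#' @param hp an [rinn_hp()] object.
#' @param seed integer seed.
#' @param init optional \code{rinn_weights} starting point.
#' @return list with \code{weights} (trained \code{rinn_weights}) and
#'   \code{history} (full-data total objective after each epoch).
#' @export
train_network <- function(data, architecture, hp, seed = 1L, init = NULL) {
  X <- data$sga; Y <- data$deg
  stopifnot(nrow(X) >= 1L, nrow(X) == nrow(Y))
  if (hp$batch_size > nrow(X)) stop("'batch_size' exceeds the number of samples")
  weights <- init %||% init_network(architecture, ncol(X), ncol(Y), hp,
                                    seed = derive_seed(seed, 0L, 0L))
  lr <- hp$learning_rate; rr <- hp$l1
  history <- numeric(hp$epochs)
  n <- nrow(X)
  with_seed(derive_seed(seed, 1L, 0L), {
    for (epoch in seq_len(hp$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = hp$batch_size)
      tot <- 0; wt <- 0
      for (bi in seq_along(starts)) {
        rows <- idx[starts[bi]:min(starts[bi] + hp$batch_size - 1L, n)]
        g <- network_gradients(weights, X[rows, , drop = FALSE],
                               Y[rows, , drop = FALSE], rr)
        if (!is.finite(g$objective$total)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d; reduce the learning rate",
                       epoch, bi))
        }
        tot <- tot + g$objective$total * length(rows)
        wt <- wt + length(rows)
        for (i in seq_along(weights$W)) {
          weights$W[[i]] <- weights$W[[i]] - lr * g$W[[i]]
          weights$b[[i]] <- weights$b[[i]] - lr * g$b[[i]]
        }
      }
      # per-epoch objective: sample-weighted mean of the minibatch values
      history[epoch] <- tot / wt
    }
  })
  list(weights = weights, history = history)
}

#' @export
print.rinn_weights <- function(x, ...) {
  cat(sprintf("%s weights: %d inputs -> [%s] -> %d outputs (%s hidden activation)\n",
              x$architecture, x$n_inputs, paste(x$hidden_sizes, collapse = ", "),
              x$n_outputs, x$activation))
  cat(sprintf("  %d weight matrices, sum|w| = %.4f\n", length(x$W),
              sum(vapply(x$W, function(w) sum(abs(w)), numeric(1)))))
  invisible(x)
}
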