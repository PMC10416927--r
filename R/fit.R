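#' Fit a redundant-input neural network to SGA/DEG data
#'
#' The central fitting function of the package.  A redundant-input neural
#' network (RINN) is a feedforward network in which a copy of the input
#' vector is concatenated onto every hidden layer (layers 2--8), so that
#' each binary somatic genomic alteration (SGA) can connect directly to
#' latent nodes at any depth.  The network is trained by minibatch SGD to
#' predict binary differential-expression calls (DEGs), minimizing binary
#' cross-entropy plus an L1 penalty on all weights; the sparsity induced
#' by the penalty is what makes the surviving SGA-to-hidden weights
#' interpretable as a latent causal structure.
#'
#' @param data an [rinn_data()] object (or list with binary matrices
#'   \code{sga} and \code{deg}).
#' @param architecture \code{"RINN"} (default) or \code{"DNN"} for a
#'   conventional network without redundant inputs.
#' @param hidden_sizes hidden layer sizes; a scalar is recycled to the 8
#'   layers of an RINN.
#' @param activation hidden activation: \code{"softplus"} (default),
#'   \code{"relu"} or \code{"sigmoid"}.  The output is always sigmoid.
#' @param learning_rate,l1,epochs,batch_size SGD hyperparameters; see
#'   [rinn_hp()].
#' @param seed integer seed controlling initialization and shuffling.
#' @return An object of class \code{"rinn"}: a list with the trained
#'   \code{weights}, per-epoch objective \code{history}, the
#'   hyperparameters \code{hp}, the \code{seed} and the matched
#'   \code{call}.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}.
#' @examples
#' dag <- build_ground_truth(n_sga = 6, pathway_sizes = c(3), layer_sizes = c(3, 3),
#'                           n_deg = 12, seed = 1)
#' dat <- simulate_binary_dataset(dag, n_samples = 120, seed = 1)
#' fit <- rinn(dat, hidden_sizes = 4, epochs = 5, learning_rate = 0.2,
#'             l1 = 1e-4, seed = 1)
#' fit
#' head(predict(fit, dat$sga)[, 1:4])
#' @export
rinn <- function(data, architecture = c("RINN", "DNN"), hidden_sizes = 10,
                 activation = "softplus", learning_rate = 0.1, l1 = 1e-4,
                 epochs = 50, batch_size = 32, seed = 1L) {
  architecture <- match.arg(architecture)
  hp <- rinn_hp(learning_rate = learning_rate, l1 = l1, epochs = epochs,
                batch_size = min(batch_size, nrow(data$sga)),
                activation = activation, hidden_sizes = hidden_sizes,
                architecture = architecture)
  fit <- train_network(data, architecture, hp, seed = seed)
  obj <- objective(network_forward(fit$weights, data$sga), data$deg,
                   fit$weights, hp$l1)
  structure(list(weights = fit$weights, history = fit$history, hp = hp,
                 seed = as.integer(seed), objective = obj,
                 sga_ids = colnames(data$sga), deg_ids = colnames(data$deg),
                 n_samples = nrow(data$sga), call = match.call()),
            class = "rinn")
}

#' @export
print.rinn <- function(x, ...) {
  cat(sprintf("%s fit: %d SGAs -> [%s] -> %d DEGs (%s)\n",
              x$hp$architecture, x$weights$n_inputs,
              paste(x$weights$hidden_sizes, collapse = ", "),
              x$weights$n_outputs, x$hp$activation))
  cat(sprintf("  trained %d epochs on %d samples; cross-entropy %.4f nats, sum|w| %.2f\n",
              x$hp$epochs, x$n_samples, x$objective$cel, x$objective$l1))
  invisible(x)
}

#' @export
summary.rinn <- function(object, ...) {
  w <- object$weights
  per_mat <- vapply(w$W, function(m) sum(abs(m)), numeric(1))
  near_zero <- vapply(w$W, function(m) mean(abs(m) < 1e-3), numeric(1))
  out <- list(architecture = w$architecture, activation = w$activation,
              dims = c(inputs = w$n_inputs, outputs = w$n_outputs),
              hidden_sizes = w$hidden_sizes, hp = object$hp,
              cel = object$objective$cel, sum_abs_w = object$objective$l1,
              total = object$objective$total, per_matrix_l1 = per_mat,
              frac_near_zero = near_zero, history = object$history)
  class(out) <- "summary.rinn"
  out
}

#' @export
print.summary.rinn <- function(x, ...) {
  cat(sprintf("%s (%s activation): %d -> [%s] -> %d\n", x$architecture,
              x$activation, x$dims["inputs"],
              paste(x$hidden_sizes, collapse = ", "), x$dims["outputs"]))
  cat(sprintf("Training objective: cross-entropy %.4f nats + %.1e * L1(%.2f) = %.4f\n",
              x$cel, x$hp$l1, x$sum_abs_w, x$total))
  cat("Per-matrix sum|w| (fraction of |w| < 1e-3):\n")
  for (i in seq_along(x$per_matrix_l1)) {
    cat(sprintf("  W%-2d %10.3f  (%.0f%%)\n", i, x$per_matrix_l1[i],
                100 * x$frac_near_zero[i]))
  }
  invisible(x)
}

#' @export
coef.rinn <- function(object, ...) object$weights$W

#' Predict DEG probabilities for new SGA profiles
#'
#' @param object a fitted [rinn()] model.
#' @param newdata binary matrix of SGA profiles (samples x SGAs), or an
#'   \code{rinn_data} object.
#' @param type \code{"response"} for probabilities, \code{"class"} for
#'   0/1 calls at 0.5.
#' @param ... unused.
#' @return matrix of predicted DEG probabilities (or calls).
#' @export
predict.rinn <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "rinn_data")) newdata$sga else as.matrix(newdata)
  P <- network_forward(object$weights, X)
  colnames(P) <- object$deg_ids
  rownames(P) <- rownames(X)
  if (type == "class") P <- (P > 0.5) + 0L
  P
}

#' @export
plot.rinn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "total objective (nats + L1 term)",
                 main = sprintf("%s training history", x$hp$architecture), ...)
  invisible(x)
}
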