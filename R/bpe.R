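#' Back-propagation network configuration
#'
#' One hidden layer of logistic units and a single output unit (logistic by
#' default, so the scaled-target interval \[0.1, 0.9\] keeps every training
#' value representable with headroom; a linear output is available for
#' ablation). Training is per-pattern (on-line) gradient descent with a
#' momentum term: `dw(t) = -learning_rate * dE/dw + momentum * dw(t-1)`,
#' `E = (output - target)^2 / 2`. The defaults — learning rate 0.1,
#' momentum 0.01, 1000 epochs — are the standard settings for this kind of
#' QSAR network.
#'
#' @param hidden_neurons number of hidden units (>= 1); typical grid values
#'   are 5, 10 and 12.
#' @param learning_rate positive step size.
#' @param momentum momentum coefficient, >= 0.
#' @param epochs full passes over the training objects.
#' @param seed seed for weight initialization and presentation order.
#' @param init_range weights start uniform in `[-init_range, init_range]`.
#' @param output `"sigmoid"` (default) or `"linear"` output activation.
#' @return an object of class `bpe_config`.
#' @export
bpe_config <- function(hidden_neurons, learning_rate = 0.1, momentum = 0.01,
                       epochs = 1000, seed = 1L, init_range = 0.5,
                       output = c("sigmoid", "linear")) {
  output <- match.arg(output)
  hidden_neurons <- as.integer(hidden_neurons)
  epochs <- as.integer(epochs)
  if (hidden_neurons < 1L) stop("hidden_neurons must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (momentum < 0) stop("momentum must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (init_range <= 0) stop("init_range must be > 0")
  structure(list(hidden_neurons = hidden_neurons,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = epochs, seed = as.integer(seed),
                 init_range = init_range, output = output),
            class = "bpe_config")
}

new_bpe_network <- function(W1, W2, P1, P2, config, trace = numeric(0)) {
  structure(list(W1 = W1, W2 = W2, P1 = P1, P2 = P2,
                 config = config, trace = trace,
                 n_inputs = nrow(W1) - 1L),
            class = "bpe_network")
}

#' Initialize an untrained back-propagation network
#'
#' Weights (including biases, handled as constant-1 inputs) start uniform
#' in `[-init_range, init_range]`; the momentum state starts at zero.
#'
#' @param n_inputs input-layer size (= number of descriptors).
#' @param config a [bpe_config()].
#' @return an object of class `bpe_network`.
#' @export
init_bpe <- function(n_inputs, config) {
  stopifnot(inherits(config, "bpe_config"))
  h <- config$hidden_neurons
  set.seed(config$seed)
  W1 <- matrix(stats::runif((n_inputs + 1L) * h, -config$init_range,
                            config$init_range),
               nrow = n_inputs + 1L, ncol = h)
  W2 <- stats::runif(h + 1L, -config$init_range, config$init_range)
  new_bpe_network(W1, W2, matrix(0, n_inputs + 1L, h), numeric(h + 1L), config)
}

#' Forward pass through a back-propagation network
#'
#' `hidden_j = sigma(sum_i w_ij x_i + b_j)`,
#' `output = sigma(sum_j v_j hidden_j + c)` with the logistic
#' `sigma(z) = 1 / (1 + exp(-z))` (output linear when configured so).
#'
#' @param net a `bpe_network`.
#' @param x scaled input vector of length `net$n_inputs`.
#' @return list with `output` (in (0, 1) for a sigmoid output) and
#'   `hidden` activations.
#' @export
forward_bpe <- function(net, x) {
  stopifnot(inherits(net, "bpe_network"))
  cpp_bpe_forward(net$W1, net$W2, as.numeric(x), net$config$output == "linear")
}

#' Single on-line back-propagation step
#'
#' Applies the delta rule with momentum for one (input, target) pattern and
#' returns the updated network; the momentum state is replaced by the new
#' weight changes. Exposed mainly so the gradients can be checked against
#' finite differences.
#'
#' @param net a `bpe_network`.
#' @param x scaled input vector.
#' @param target scaled target value.
#' @return the updated `bpe_network`, with attribute `"output"` holding the
#'   pre-update output.
#' @export
backprop_step <- function(net, x, target) {
  stopifnot(inherits(net, "bpe_network"), is.finite(target))
  res <- cpp_bpe_step(net$W1, net$W2, net$P1, net$P2, as.numeric(x), target,
                      net$config$learning_rate, net$config$momentum,
                      net$config$output == "linear")
  out <- new_bpe_network(res$W1, res$W2, res$P1, res$P2, net$config, net$trace)
  attr(out, "output") <- res$output
  out
}

#' Train a back-propagation network on extracted neurons (Stage II)
#'
#' The training objects are the k neurons of a trained counter-propagation
#' model — never the original compounds — presented in a freshly shuffled
#' order each epoch. Accepts only a [neuron_dataset()], which enforces the
#' two-stage contract by type. A non-finite loss aborts with a diagnostic
#' rather than being clipped, so a mis-set learning rate surfaces honestly.
#'
#' @param neurons a [neuron_dataset()] with targets in \[0, 1\].
#' @param config a [bpe_config()].
#' @return a `bpe_network`; `$trace` holds the per-epoch training RMSE
#'   (scaled units, computed from the pre-update outputs seen during the
#'   epoch).
#' @export
train_bpe <- function(neurons, config) {
  if (!inherits(neurons, "neuron_dataset"))
    stop("train_bpe() trains on a neuron_dataset only; ",
         "Stage II never sees compounds directly")
  stopifnot(inherits(config, "bpe_config"))
  if (any(neurons$targets < 0 | neurons$targets > 1))
    stop("neuron targets must lie in [0, 1] (scaled target space)")
  net <- init_bpe(ncol(neurons$inputs), config)
  fit <- cpp_train_bpe(neurons$inputs, neurons$targets, net$W1, net$W2,
                       config$epochs, config$learning_rate, config$momentum,
                       config$output == "linear")
  new_bpe_network(fit$W1, fit$W2, fit$P1, fit$P2, config,
                  trace = as.numeric(fit$trace))
}

#' Predict with a back-propagation network (scaled units)
#'
#' @param net a `bpe_network`.
#' @param x scaled input vector, or matrix with one row per object.
#' @return scaled output value(s).
#' @export
predict_bpe <- function(net, x) {
  stopifnot(inherits(net, "bpe_network"))
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  out <- cpp_bpe_predict(net$W1, net$W2, X, net$config$output == "linear")
  if (is.null(dim(x))) out[1L] else out
}

#' @export
print.bpe_network <- function(x, ...) {
  cat("BPE network:", x$n_inputs, "inputs ->", x$config$hidden_neurons,
      "hidden -> 1 output (", x$config$output, ")\n")
  if (length(x$trace) > 0L)
    cat("  final training RMSE (scaled):", format(x$trace[length(x$trace)]), "\n")
  invisible(x)
}
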