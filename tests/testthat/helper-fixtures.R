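# Small fixtures shared across test files; everything is generated in code.

tiny_dataset <- function(m = 12, n = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(m * n), m, n, dimnames = list(NULL, paste0("D", 1:n)))
  qsar_dataset(sprintf("c%03d", 1:m), X, rowSums(X) - 2)
}

# deterministic 2-2-1 network with hand-set weights, zero momentum state
hand_net <- function(W1 = matrix(c(0.2, -0.4, 0.1, 0.5, -0.3, 0.2), 3, 2),
                     W2 = c(0.7, -0.6, 0.05), config = bpe_config(2)) {
  net <- init_bpe(nrow(W1) - 1L, config)
  net$W1 <- W1
  net$W2 <- W2
  net$P1[] <- 0
  net$P2[] <- 0
  net
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# total loss of a network on one pattern, given flattened weights
bpe_loss_at <- function(net, w_flat, x, target) {
  n1 <- length(net$W1)
  net$W1[] <- w_flat[seq_len(n1)]
  net$W2[] <- w_flat[-seq_len(n1)]
  0.5 * (forward_bpe(net, x)$output - target)^2
}
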