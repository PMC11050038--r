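test_that("forward pass matches a hand-computed 2-2-1 network", {
  net <- hand_net()
  x <- c(0.3, 0.8)
  h1 <- sigmoid(0.2 * 0.3 - 0.4 * 0.8 + 0.1)
  h2 <- sigmoid(0.5 * 0.3 - 0.3 * 0.8 + 0.2)
  out <- sigmoid(0.7 * h1 - 0.6 * h2 + 0.05)
  fw <- forward_bpe(net, x)
  expect_equal(fw$hidden, c(h1, h2), tolerance = 1e-12)
  expect_equal(fw$output, out, tolerance = 1e-12)
  # all-zero weights give 0.5 everywhere
  z <- hand_net(W1 = matrix(0, 3, 2), W2 = c(0, 0, 0))
  fz <- forward_bpe(z, x)
  expect_equal(fz$hidden, c(0.5, 0.5))
  expect_equal(fz$output, 0.5)
  # sigmoid output stays inside (0,1) for wild inputs
  expect_true(forward_bpe(net, c(1e3, -1e3))$output > 0)
  expect_true(forward_bpe(net, c(1e3, -1e3))$output < 1)
  expect_error(forward_bpe(net, c(1, 2, 3)), "input")
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(1:20, 1)
    h <- sample(1:12, 1)
    cfg <- bpe_config(h, learning_rate = 1, momentum = 0, seed = rep)
    net <- init_bpe(n, cfg)
    x <- runif(n)
    target <- runif(1, 0.1, 0.9)
    # analytic gradient from one momentum-free unit-learning-rate step
    stepped <- backprop_step(net, x, target)
    ga <- c(net$W1 - stepped$W1, net$W2 - stepped$W2)  # eta = 1
    # central finite differences of the loss
    w0 <- c(net$W1, net$W2)
    eps <- 1e-5
    gf <- vapply(seq_along(w0), function(i) {
      wp <- w0; wp[i] <- wp[i] + eps
      wm <- w0; wm[i] <- wm[i] - eps
      (bpe_loss_at(net, wp, x, target) - bpe_loss_at(net, wm, x, target)) /
        (2 * eps)
    }, numeric(1))
    rel <- sqrt(sum((ga - gf)^2)) / max(sqrt(sum(gf^2)), 1e-8)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("a momentum-free step descends, and a zero-gradient point is fixed", {
  net <- hand_net(config = bpe_config(2, learning_rate = 0.1, momentum = 0))
  x <- c(0.4, 0.6); target <- 0.2
  loss0 <- 0.5 * (forward_bpe(net, x)$output - target)^2
  s1 <- backprop_step(net, x, target)
  loss1 <- 0.5 * (forward_bpe(s1, x)$output - target)^2
  s2 <- backprop_step(s1, x, target)
  loss2 <- 0.5 * (forward_bpe(s2, x)$output - target)^2
  expect_lt(loss1, loss0)
  expect_lt(loss2, loss1)
  # target equal to the current output: all deltas vanish
  out <- forward_bpe(net, x)$output
  s0 <- backprop_step(net, x, out)
  expect_equal(s0$W1, net$W1, tolerance = 1e-15)
  expect_equal(s0$W2, net$W2, tolerance = 1e-15)
})

test_that("training solves an XOR-like pattern set", {
  inputs <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  targets <- c(0.1, 0.9, 0.9, 0.1)
  neurons <- neuron_dataset(inputs, targets)
  net <- train_bpe(neurons, bpe_config(5, learning_rate = 0.5, momentum = 0.01,
                                       epochs = 20000, seed = 2))
  preds <- predict_bpe(net, inputs)
  expect_lt(rmse(preds, targets), 0.05)
  # trace is finite and the final epoch improves on the first
  expect_true(all(is.finite(net$trace)))
  expect_lt(net$trace[length(net$trace)], net$trace[1])
})

test_that("train_bpe is deterministic and guards its type contract", {
  neurons <- neuron_dataset(matrix(runif(20, 0.1, 0.9), 10, 2),
                            seq(0.1, 0.9, length.out = 10))
  cfg <- bpe_config(4, epochs = 200, seed = 8)
  n1 <- train_bpe(neurons, cfg)
  n2 <- train_bpe(neurons, cfg)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$W2, n2$W2)
  # compounds can never be fed to Stage II directly
  ds <- tiny_dataset()
  expect_error(train_bpe(ds, cfg), "neuron_dataset")
  expect_error(train_bpe(neuron_dataset(matrix(0.5, 2, 2), c(0.5, 1.5)), cfg),
               "\\[0, 1\\]")
})

test_that("predictions are smooth and match the forward pass", {
  net <- hand_net()
  x <- c(0.25, 0.75)
  expect_identical(predict_bpe(net, x), forward_bpe(net, x)$output)
  delta <- 1e-8
  expect_lt(abs(predict_bpe(net, x + delta) - predict_bpe(net, x)), 1e-4)
})

test_that("divergent training aborts with a diagnostic", {
  set.seed(77)
  neurons <- neuron_dataset(matrix(runif(40), 20, 2), runif(20, 0.1, 0.9))
  # an absurd learning rate on a linear output drives weights to overflow;
  # the run must abort with a diagnostic, not clip silently
  expect_error(
    train_bpe(neurons, bpe_config(3, learning_rate = 1e8, epochs = 2000,
                                  seed = 1, output = "linear")),
    "diverged")
})
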