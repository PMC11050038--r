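test_that("find_winner agrees with exhaustive search and breaks ties low", {
  set.seed(11)
  for (rep in 1:200) {
    k <- sample(4:12, 1); n <- sample(1:6, 1)
    W <- matrix(runif(k * n), k, n)
    x <- runif(n)
    d <- sqrt(rowSums(sweep(W, 2, x)^2))
    w <- find_winner(W, x, map_cols = k)  # 1 x k grid
    expect_equal(w$index, which.min(d))
    expect_equal(w$distance, min(d), tolerance = 1e-12)
  }
  # exact match wins with distance 0
  W <- matrix(runif(12), 6, 2)
  w <- find_winner(W, W[4, ], map_cols = 3)
  expect_equal(w$index, 4)
  expect_equal(w$row, 2)
  expect_equal(w$col, 1)
  expect_equal(w$distance, 0)
  # two identical neurons: smallest row-major index wins
  W[6, ] <- W[1, ]
  expect_equal(find_winner(W, W[1, ], map_cols = 3)$index, 1)
  expect_error(find_winner(W, c(1, 2, 3), map_cols = 3), "match")
})

test_that("neighborhood factor is local, monotone and wraps on a torus", {
  expect_equal(neighborhood_factor(c(2, 2), c(2, 2), 3, 5, 5), 1)
  expect_equal(neighborhood_factor(c(2, 2), c(2, 2), 0, 5, 5), 1)
  # radius 0: any non-winner neuron has factor 0 (triangular)
  expect_equal(neighborhood_factor(c(1, 1), c(1, 2), 0, 5, 5), 0)
  # monotone non-increasing in grid distance
  f <- sapply(1:4, function(d) neighborhood_factor(c(1, 1), c(1, 1 + d), 3, 5, 9))
  expect_true(all(diff(f) <= 0))
  # toroidal wrap: corners of a 5x5 are neighbours at distance 1
  expect_equal(neighborhood_factor(c(1, 1), c(5, 5), 1, 5, 5,
                                   topology = "toroidal"), 0.5)
  expect_equal(neighborhood_factor(c(1, 1), c(5, 5), 1, 5, 5,
                                   topology = "toroidal",
                                   shape = "rectangular"), 1)
  # same pair on a planar map is far away
  expect_equal(neighborhood_factor(c(1, 1), c(5, 5), 1, 5, 5), 0)
})

test_that("a 1x1-equivalent map converges to the single training compound", {
  # smallest legal map is 2 neurons; with one compound both converge to it
  ds <- tiny_dataset(m = 1, n = 3)
  cfg <- cpann_config(1, 2, epochs = 100, seed = 1)
  expect_warning(model <- train_cpann(ds, cfg), "constant")
  # constant columns scale to 0.5; the winner's weights converge there
  xs <- scale_descriptors(ds$X, model$scaling)
  w <- model$winners[1]
  expect_lt(max(abs(model$kohonen[w, ] - xs[1, ])), 1e-3)
  p <- predict_cpann(model, ds$X[1, ])
  expect_equal(p$value, ds$targets[1], tolerance = 1e-3)
})

test_that("two separated clusters on a 2x1 map recover cluster mean targets", {
  set.seed(21)
  m <- 40
  cl <- rep(c(0, 1), each = m / 2)
  X <- cbind(cl + runif(m, -0.05, 0.05), cl + runif(m, -0.05, 0.05))
  colnames(X) <- c("D1", "D2")
  targets <- ifelse(cl == 0, -6, 2) + runif(m, -0.1, 0.1)
  ds <- qsar_dataset(sprintf("c%02d", 1:m), X, targets)
  model <- train_cpann(ds, cpann_config(2, 1, epochs = 400, seed = 3))
  sc_t <- scale_target(targets, model$scaling)
  for (neuron in 1:2) {
    members <- which(model$winners == neuron)
    expect_gt(length(members), 0)
    expect_lt(abs(model$grossberg[neuron] - mean(sc_t[members])), 0.05)
  }
  # the two clusters land on different neurons
  expect_equal(sort(unique(model$winners)), c(1L, 2L))
})

test_that("training is deterministic given the seed", {
  ds <- tiny_dataset(m = 30, n = 4, seed = 6)
  cfg <- cpann_config(3, 3, epochs = 50, seed = 99)
  m1 <- train_cpann(ds, cfg)
  m2 <- train_cpann(ds, cfg)
  expect_identical(m1, m2)
  m3 <- train_cpann(ds, cpann_config(3, 3, epochs = 50, seed = 100))
  expect_false(identical(m1$kohonen, m3$kohonen))
})

test_that("CP-ANN predictions take at most k distinct values", {
  ds <- tiny_dataset(m = 50, n = 3, seed = 2)
  model <- train_cpann(ds, cpann_config(3, 3, epochs = 60, seed = 5))
  set.seed(77)
  probes <- matrix(runif(3000), ncol = 3)
  # map probes back to raw units so predict_cpann rescales them
  raw <- sweep(sweep(probes, 2, model$scaling$x_max - model$scaling$x_min, "*"),
               2, model$scaling$x_min, "+")
  vals <- predict_cpann(model, raw)$value
  expect_lte(length(unique(vals)), 9)
  # same winner implies the same prediction
  p1 <- predict_cpann(model, ds$X[1, ])
  again <- predict_cpann(model, ds$X[1, ] + 1e-9)
  expect_equal(p1$value, again$value)
})

test_that("extract_neurons returns every neuron with matching weights", {
  ds <- tiny_dataset(m = 40, n = 4, seed = 13)
  model <- train_cpann(ds, cpann_config(5, 4, epochs = 40, seed = 1))
  neurons <- extract_neurons(model)
  expect_equal(nrow(neurons$inputs), 20)
  expect_identical(unname(neurons$inputs), unname(model$kohonen))
  expect_identical(neurons$targets, model$grossberg)
  # row-major coordinates
  j <- 7  # row 2, col 3 on a 4-column grid
  expect_equal(unname(neurons$coords[j, ]), c(2, 3))
  expect_identical(neurons$inputs[j, ], model$kohonen[j, ])
  # occupied-only mode drops empty neurons
  occ <- extract_neurons(model, occupied_only = TRUE)
  expect_equal(nrow(occ$inputs), sum(model$occupancy > 0))
})

test_that("an update at radius 0 changes exactly one neuron", {
  # triangular neighborhood at radius 0: factor 1 for the winner, 0 beyond
  a <- sapply(0:3, function(d)
    neighborhood_factor(c(1, 1), c(1, 1 + d), 0, 1, 4))
  expect_equal(a, c(1, 0, 0, 0))
  set.seed(31)
  W0 <- matrix(runif(12), 6, 2)
  g0 <- runif(6)
  x <- matrix(runif(2), 1, 2)
  fit <- cpbpe:::cpp_train_cpann(x, 0.5, 2, 3, 1, 0.3, 0.3, FALSE, FALSE,
                                 W0, g0, TRUE, radius_override = 0)
  moved <- which(rowSums(abs(fit$kohonen - W0)) > 0)
  expect_length(moved, 1)
  expect_equal(moved, fit$winner[1])
})

test_that("a model whose compounds sit on its neurons is a fixed point", {
  # training compounds equal to neuron weights and targets equal to
  # Grossberg values: at radius 0 the winner's corrections (x - w) and
  # (t - g) are zero, so one epoch at any learning rate changes nothing
  set.seed(41)
  W <- matrix(runif(8), 4, 2)
  g <- runif(4)
  fit <- cpbpe:::cpp_train_cpann(W, g, 2, 2, 1, 0.9, 0.9, FALSE, FALSE,
                                 W, g, TRUE, radius_override = 0)
  expect_lt(max(abs(fit$kohonen - W)), 1e-12)
  expect_lt(max(abs(fit$grossberg - g)), 1e-12)
})
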