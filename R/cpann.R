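#' Counter-propagation network configuration
#'
#' Training follows the classical counter-propagation recipe: weights start
#' uniform in \[0, 1\] (scaled space), compounds are presented one at a time
#' in a freshly shuffled order each epoch, the learning rate decays linearly
#' from `eta_max` to `eta_min`, and the neighbourhood radius decays linearly
#' from `max(map_rows, map_cols) / 2` to 0 over the epochs.
#'
#' @param map_rows,map_cols grid dimensions of the Kohonen layer; typical
#'   QSAR maps are 9x9 up to 25x25.
#' @param epochs number of full passes over the training compounds.
#' @param eta_max,eta_min initial and final learning rate,
#'   `eta_max >= eta_min > 0`.
#' @param topology `"planar"` (default) or `"toroidal"` (edges wrap).
#' @param neighborhood `"triangular"` (factor `max(0, 1 - d/(radius+1))` in
#'   the Chebyshev grid distance `d`) or `"rectangular"` (1 within the
#'   radius, 0 outside).
#' @param seed integer seed controlling weight initialization and the
#'   per-epoch presentation order.
#' @return an object of class `cpann_config`.
#' @export
cpann_config <- function(map_rows, map_cols, epochs = 100,
                         eta_max = 0.5, eta_min = 0.01,
                         topology = c("planar", "toroidal"),
                         neighborhood = c("triangular", "rectangular"),
                         seed = 1L) {
  topology <- match.arg(topology)
  neighborhood <- match.arg(neighborhood)
  map_rows <- as.integer(map_rows); map_cols <- as.integer(map_cols)
  epochs <- as.integer(epochs)
  if (map_rows < 1L || map_cols < 1L || map_rows * map_cols < 2L)
    stop("the map needs at least two neurons")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!(eta_max >= eta_min && eta_min > 0))
    stop("need eta_max >= eta_min > 0")
  structure(list(map_rows = map_rows, map_cols = map_cols, epochs = epochs,
                 eta_max = eta_max, eta_min = eta_min, topology = topology,
                 neighborhood = neighborhood, seed = as.integer(seed)),
            class = "cpann_config")
}

neuron_index_to_coords <- function(index, map_cols) {
  list(row = (index - 1L) %/% map_cols + 1L,
       col = (index - 1L) %% map_cols + 1L)
}

# Shared kernel driver: X is already scaled, targets in scaled units (or
# zeros when supervised = FALSE). Consumes R's RNG stream.
run_cpann_kernel <- function(X, targets, config, supervised) {
  k <- config$map_rows * config$map_cols
  n <- ncol(X)
  set.seed(config$seed)
  koh0 <- matrix(stats::runif(k * n), nrow = k, ncol = n)
  gro0 <- stats::runif(k)
  cpp_train_cpann(X, targets, config$map_rows, config$map_cols,
                  config$epochs, config$eta_max, config$eta_min,
                  config$topology == "toroidal",
                  config$neighborhood == "rectangular",
                  koh0, gro0, supervised)
}

#' Train a counter-propagation network (Stage I)
#'
#' Trains the competitive Kohonen layer and the supervised Grossberg output
#' layer in the same pass: for each presented compound the winning neuron is
#' the one closest (Euclidean, scaled space) to its descriptor vector, and
#' every neuron `j` is corrected by `eta * a(j)` toward the compound's
#' descriptors (Kohonen layer) and toward its target (Grossberg layer),
#' where `a(j)` is the neighbourhood factor around the winner.
#'
#' @param dataset a [qsar_dataset()] in raw units (the training set).
#' @param config a [cpann_config()].
#' @param scaling optional pre-fitted [fit_scaling()] parameters; fitted on
#'   `dataset` when `NULL`.
#' @return an object of class `cpann_model` with elements `kohonen`
#'   (k x n weight matrix, neurons in row-major grid order), `grossberg`
#'   (length-k scaled output values), `train_distances` (per training
#'   compound, to its winning neuron), `occupancy`, `winners`, `config` and
#'   `scaling`.
#' @export
train_cpann <- function(dataset, config, scaling = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"), inherits(config, "cpann_config"))
  if (is.null(scaling)) scaling <- fit_scaling(dataset)
  sc <- scale_dataset(dataset, scaling)
  fit <- run_cpann_kernel(sc$X, sc$targets, config, supervised = TRUE)
  kohonen <- fit$kohonen
  colnames(kohonen) <- dataset$descriptor_names
  structure(
    list(kohonen = kohonen, grossberg = as.numeric(fit$grossberg),
         config = config, scaling = scaling,
         train_distances = stats::setNames(as.numeric(fit$distance), dataset$ids),
         winners = as.integer(fit$winner),
         occupancy = as.integer(fit$occupancy),
         descriptor_names = dataset$descriptor_names),
    class = "cpann_model"
  )
}

#' @export
print.cpann_model <- function(x, ...) {
  cat("CP-ANN:", x$config$map_rows, "x", x$config$map_cols, "map,",
      ncol(x$kohonen), "descriptors,", x$config$epochs, "epochs\n")
  cat("  occupied neurons:", sum(x$occupancy > 0L), "/", length(x$occupancy), "\n")
  invisible(x)
}

#' Find the winning neuron for a scaled descriptor vector
#'
#' The winner is the neuron minimizing the Euclidean distance to `x` over
#' the whole grid; exact ties go to the smallest row-major index, which
#' keeps training and prediction deterministic.
#'
#' @param kohonen a `cpann_model`, or a k x n weight matrix whose rows are
#'   neurons in row-major grid order (with attributes `map_rows` and
#'   `map_cols`, or pass `map_cols` explicitly).
#' @param x scaled descriptor vector of length n.
#' @param map_cols number of grid columns, required when `kohonen` is a
#'   bare matrix without attributes.
#' @return list with `row`, `col`, `index` (row-major) and `distance`.
#' @export
find_winner <- function(kohonen, x, map_cols = NULL) {
  if (inherits(kohonen, "cpann_model")) {
    map_cols <- kohonen$config$map_cols
    kohonen <- kohonen$kohonen
  } else if (is.null(map_cols)) {
    map_cols <- attr(kohonen, "map_cols")
    if (is.null(map_cols)) stop("map_cols is required for a bare weight matrix")
  }
  res <- cpp_find_winner(kohonen, as.numeric(x))
  coords <- neuron_index_to_coords(res$index, map_cols)
  list(row = coords$row, col = coords$col, index = res$index,
       distance = res$distance)
}

#' Neighbourhood factor between a winner and another neuron
#'
#' The grid distance is the Chebyshev distance between the two (row, col)
#' positions, with wrap-around on a toroidal map. Both shapes are zero
#' beyond the current radius: the triangular shape decays linearly inside
#' it, `1 - d / (radius + 1)` for `d <= radius`, so at radius 0 only the
#' winner itself is corrected; the rectangular shape is 1 everywhere inside.
#' Cutting the correction off at the radius (rather than letting the
#' triangle reach zero at `d = radius + 1`) is what lets each neuron's
#' output value converge to the mean target of its own compounds once the
#' radius has shrunk below the distance to its neighbours.
#'
#' @param winner,neuron integer `(row, col)` pairs.
#' @param radius current (real-valued) neighbourhood radius, `>= 0`.
#' @param map_rows,map_cols grid dimensions.
#' @param topology `"planar"` or `"toroidal"`.
#' @param shape `"triangular"` or `"rectangular"`.
#' @return a factor in \[0, 1\].
#' @export
neighborhood_factor <- function(winner, neuron, radius, map_rows, map_cols,
                                topology = c("planar", "toroidal"),
                                shape = c("triangular", "rectangular")) {
  topology <- match.arg(topology)
  shape <- match.arg(shape)
  if (radius < 0) stop("radius must be >= 0")
  dr <- abs(winner[1L] - neuron[1L])
  dc <- abs(winner[2L] - neuron[2L])
  if (topology == "toroidal") {
    dr <- min(dr, map_rows - dr)
    dc <- min(dc, map_cols - dc)
  }
  d <- max(dr, dc)
  if (shape == "rectangular") as.numeric(d <= radius)
  else if (d <= radius) 1 - d / (radius + 1) else 0
}

#' Predict with a counter-propagation network alone
#'
#' Scales `x` with the model's stored parameters, finds the winning neuron
#' and returns that neuron's Grossberg value mapped back to property units.
#' Every compound exciting the same neuron receives the same value — the
#' per-neuron lookup limitation the two-stage method removes.
#'
#' @param model a `cpann_model`.
#' @param x raw descriptor vector (length n) or matrix (one row per
#'   compound).
#' @return for a vector: list with `value` (property units), `row`, `col`,
#'   `distance`; for a matrix: data.frame with those columns.
#' @export
predict_cpann <- function(model, x) {
  stopifnot(inherits(model, "cpann_model"))
  vec <- is.null(dim(x))
  X <- scale_descriptors(if (vec) matrix(as.numeric(x), nrow = 1L) else as.matrix(x),
                         model$scaling)
  mp <- cpp_map_objects(model$kohonen, X)
  coords <- neuron_index_to_coords(mp$winner, model$config$map_cols)
  value <- inverse_scale_target(model$grossberg[mp$winner], model$scaling)
  if (vec)
    list(value = value[1L], row = coords$row[1L], col = coords$col[1L],
         distance = mp$distance[1L])
  else
    data.frame(value = value, winner_row = coords$row, winner_col = coords$col,
               distance = mp$distance)
}

#' @export
predict.cpann_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "qsar_dataset")) newdata$X else newdata
  predict_cpann(object, X)
}

#' Extract the trained neurons as a surrogate training set
#'
#' Returns one object per neuron: its Kohonen weight vector (a point in
#' scaled descriptor space) paired with its Grossberg value (scaled target
#' space). These k objects — not the original compounds — are the Stage II
#' training set. Empty neurons are included by default: neighbourhood
#' training gives them smoothed, interpolated Grossberg values, so they are
#' representative objects in their own right; set `occupied_only = TRUE`
#' to restrict to neurons that won at least one training compound.
#'
#' @param model a trained `cpann_model`.
#' @param occupied_only drop neurons with zero training occupancy.
#' @return an object of class `neuron_dataset`.
#' @export
extract_neurons <- function(model, occupied_only = FALSE) {
  stopifnot(inherits(model, "cpann_model"))
  k <- nrow(model$kohonen)
  coords <- neuron_index_to_coords(seq_len(k), model$config$map_cols)
  keep <- if (occupied_only) which(model$occupancy > 0L) else seq_len(k)
  neuron_dataset(inputs = model$kohonen[keep, , drop = FALSE],
                 targets = model$grossberg[keep],
                 coords = cbind(row = coords$row[keep], col = coords$col[keep]),
                 occupancy = model$occupancy[keep])
}

#' Construct a neuron dataset
#'
#' The container Stage II trains on: `inputs` live in scaled descriptor
#' space, `targets` in scaled target space. Normally produced by
#' [extract_neurons()]; the constructor is exported so small fixtures can
#' be built directly.
#'
#' @param inputs k x n numeric matrix.
#' @param targets length-k numeric vector in \[0, 1\].
#' @param coords optional k x 2 matrix of (row, col) grid positions.
#' @param occupancy optional integer vector of per-neuron training counts.
#' @return an object of class `neuron_dataset`.
#' @export
neuron_dataset <- function(inputs, targets, coords = NULL, occupancy = NULL) {
  inputs <- as.matrix(inputs)
  storage.mode(inputs) <- "double"
  targets <- as.numeric(targets)
  if (nrow(inputs) != length(targets))
    stop("inputs and targets must have the same number of neurons")
  if (nrow(inputs) < 1L) stop("neuron dataset is empty")
  structure(list(inputs = inputs, targets = targets, coords = coords,
                 occupancy = occupancy),
            class = "neuron_dataset")
}

#' @export
print.neuron_dataset <- function(x, ...) {
  cat("neuron dataset:", nrow(x$inputs), "neurons x", ncol(x$inputs),
      "descriptors\n")
  invisible(x)
}
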