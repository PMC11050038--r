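#' Split a dataset into train/test/validation sets on a Kohonen top-map
#'
#' Trains an unsupervised Kohonen map on the min-max scaled descriptors,
#' groups compounds by their winning neuron, and then assigns set labels so
#' that each occupied neuron contributes compounds to all three sets: the
#' neurons are visited in row-major order, compounds within a neuron in
#' ascending distance-to-neuron order, and labels are dealt along this
#' interleaved ordering so every set fills at a constant rate until its
#' quota is met. The result is a split that samples uniformly from the
#' whole top-map rather than at random.
#'
#' Quotas: TRAIN gets `floor(m * f_train)`; the remainder is divided
#' between TEST and VALIDATION in proportion to their fractions, with the
#' larger share going to TEST when the remainder is odd. For 1674 compounds
#' at 60/20/20 this yields 1004/335/335.
#'
#' The map should be small enough that several structurally similar
#' compounds excite each neuron (not enforced).
#'
#' @param dataset a [qsar_dataset()].
#' @param map_rows,map_cols dimensions of the splitting map (e.g. 20 x 20).
#' @param fractions length-3 numeric `(train, test, validation)`, positive,
#'   summing to 1.
#' @param epochs training epochs for the splitting map.
#' @param seed seed for map initialization and presentation order; the same
#'   seed always reproduces the same labels.
#' @return the dataset with `set_labels` filled in.
#' @export
som_split <- function(dataset, map_rows, map_cols,
                      fractions = c(0.6, 0.2, 0.2), epochs = 50, seed = 1L) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be three positive numbers (train, test, validation)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  m <- n_compounds(dataset)

  config <- cpann_config(map_rows, map_cols, epochs = epochs, seed = seed)
  sc <- scale_dataset(dataset, fit_scaling(dataset))
  fit <- run_cpann_kernel(sc$X, numeric(m), config, supervised = FALSE)

  # round-robin ordering: pass p takes the p-th closest compound of every
  # occupied neuron, neurons in row-major order
  by_neuron <- split(seq_len(m), fit$winner)
  by_neuron <- lapply(by_neuron, function(idx)
    idx[order(fit$distance[idx], idx)])
  by_neuron <- by_neuron[order(as.integer(names(by_neuron)))]
  max_occ <- max(lengths(by_neuron))
  ordering <- unlist(lapply(seq_len(max_occ), function(p)
    unlist(lapply(by_neuron, function(idx)
      if (length(idx) >= p) idx[p] else NULL), use.names = FALSE)),
    use.names = FALSE)
  stopifnot(length(ordering) == m)

  n_train <- floor(m * fractions[1L] + 1e-9)
  remainder <- m - n_train
  n_test <- ceiling(remainder * fractions[2L] / (fractions[2L] + fractions[3L]) - 1e-9)
  n_val <- remainder - n_test
  quotas <- c(TRAIN = n_train, TEST = n_test, VALIDATION = n_val)

  labels <- character(m)
  counts <- c(TRAIN = 0, TEST = 0, VALIDATION = 0)
  sets <- names(quotas)[quotas > 0]
  for (pos in ordering) {
    fill <- counts[sets] / quotas[sets]
    pick <- sets[which.min(fill)]   # ties resolve TRAIN > TEST > VALIDATION
    labels[pos] <- pick
    counts[pick] <- counts[pick] + 1
    if (counts[pick] >= quotas[pick]) sets <- setdiff(sets, pick)
  }
  out <- dataset
  out$set_labels <- labels
  out
}
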