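#' Reduce a descriptor pool by variance, correlation and map grouping
#'
#' Three sequential filters on the min-max scaled descriptor matrix:
#'
#' 1. drop descriptors whose scaled variance is below `var_threshold`
#'    (constant columns always fall here);
#' 2. for every remaining pair with absolute Pearson correlation above
#'    `corr_threshold`, drop the later column in file order;
#' 3. train an unsupervised Kohonen map on the *transposed* scaled matrix —
#'    descriptors as objects, compounds as features — and from each occupied
#'    neuron keep the descriptor closest to and the descriptor farthest from
#'    that neuron's weight vector (a single descriptor when the neuron has
#'    one occupant).
#'
#' The defaults (0.95 / 0.005) are the conventional cut-offs for
#' Dragon-style descriptor pools.
#'
#' @param dataset a [qsar_dataset()] with at least two descriptors.
#' @param corr_threshold absolute-correlation cut-off.
#' @param var_threshold scaled-variance cut-off.
#' @param map_rows,map_cols dimensions of the grouping map.
#' @param epochs training epochs for the grouping map.
#' @param seed map training seed.
#' @return character vector of selected descriptor names, in file order.
#' @export
reduce_descriptors <- function(dataset, corr_threshold = 0.95,
                               var_threshold = 0.005,
                               map_rows, map_cols, epochs = 100, seed = 1L) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (n_descriptors(dataset) < 2L)
    stop("descriptor reduction needs at least two descriptors")
  Xs <- scale_descriptors(dataset$X, fit_scaling(dataset))
  colnames(Xs) <- dataset$descriptor_names

  keep <- apply(Xs, 2L, stats::var) >= var_threshold
  if (!any(keep)) stop("all descriptors removed by the variance filter")
  Xs <- Xs[, keep, drop = FALSE]

  nms <- colnames(Xs)
  if (length(nms) > 1L) {
    cm <- abs(stats::cor(Xs))
    drop <- rep(FALSE, length(nms))
    for (i in seq_len(length(nms) - 1L)) {
      if (drop[i]) next
      for (j in seq(i + 1L, length(nms))) {
        if (!drop[j] && cm[i, j] > corr_threshold) drop[j] <- TRUE
      }
    }
    if (all(drop)) stop("all descriptors removed by the correlation filter")
    Xs <- Xs[, !drop, drop = FALSE]
    nms <- colnames(Xs)
  }
  if (length(nms) == 1L) return(nms)

  config <- cpann_config(map_rows, map_cols, epochs = epochs, seed = seed)
  tX <- t(Xs)  # descriptors as objects
  fit <- run_cpann_kernel(tX, numeric(nrow(tX)), config, supervised = FALSE)
  selected <- unlist(lapply(split(seq_len(nrow(tX)), fit$winner), function(idx) {
    d <- fit$distance[idx]
    unique(c(idx[which.min(d)], idx[which.max(d)]))
  }), use.names = FALSE)
  nms[sort(unique(selected))]
}
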