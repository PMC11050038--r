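#' Fit an applicability-domain threshold from training distances
#'
#' The applicability domain (AD) is defined by the distribution of the
#' training compounds' Euclidean distances (scaled descriptor space) to
#' their excited neurons: a query compound is in domain when its own
#' distance to its winning neuron does not exceed a threshold taken from
#' that distribution. `method = "max"` uses the maximum training distance
#' (the most permissive rule, and the default); `method = "percentile"`
#' uses the stated percentile with linear interpolation between order
#' statistics.
#'
#' The AD is a Stage I property: retraining Stage II never changes it.
#'
#' @param train_distances nonnegative distances of the training compounds
#'   to their winning neurons (e.g. `model$train_distances`).
#' @param method `"max"` or `"percentile"`.
#' @param percentile percentile in (0, 100], used when
#'   `method = "percentile"`.
#' @return an object of class `ad_threshold`.
#' @export
fit_ad <- function(train_distances, method = c("max", "percentile"),
                   percentile = 95) {
  method <- match.arg(method)
  train_distances <- as.numeric(train_distances)
  if (length(train_distances) == 0L) stop("no training distances supplied")
  if (any(train_distances < 0)) stop("distances must be nonnegative")
  if (method == "percentile" && !(percentile > 0 && percentile <= 100))
    stop("percentile must lie in (0, 100]")
  threshold <- if (method == "max") max(train_distances)
               else unname(stats::quantile(train_distances, percentile / 100,
                                           type = 7))
  structure(list(threshold = threshold, method = method,
                 percentile = if (method == "percentile") percentile else NA_real_),
            class = "ad_threshold")
}

#' @export
print.ad_threshold <- function(x, ...) {
  cat("applicability domain:", x$method,
      if (x$method == "percentile") paste0("(", x$percentile, "%)") else "",
      "threshold =", format(x$threshold), "\n")
  invisible(x)
}

#' Applicability-domain check for new compounds
#'
#' Scales the query descriptors, finds the winning Kohonen neuron and
#' compares the Euclidean distance to the fitted threshold. Out-of-domain
#' compounds still receive predictions elsewhere; the flag marks them
#' unreliable (extrapolation rather than interpolation).
#'
#' @param model a `cpbpe_model` (or a `cpann_model` plus `ad`).
#' @param x raw descriptor vector, or matrix with one row per compound.
#' @param ad an [fit_ad()] threshold; taken from the model when omitted.
#' @return for a vector: list with `flag` and `distance`; for a matrix:
#'   data.frame with columns `in_domain` and `distance`.
#' @export
in_domain <- function(model, x, ad = NULL) {
  cp <- if (inherits(model, "cpbpe_model")) model$cpann else model
  stopifnot(inherits(cp, "cpann_model"))
  if (is.null(ad)) ad <- model$ad
  stopifnot(inherits(ad, "ad_threshold"))
  vec <- is.null(dim(x))
  X <- scale_descriptors(if (vec) matrix(as.numeric(x), nrow = 1L) else as.matrix(x),
                         cp$scaling)
  mp <- cpp_map_objects(cp$kohonen, X)
  flag <- mp$distance <= ad$threshold
  if (vec) list(flag = flag[1L], distance = mp$distance[1L])
  else data.frame(in_domain = flag, distance = mp$distance)
}

#' Report compounds outside the applicability domain
#'
#' One row per out-of-domain compound: identifier, experimental value, the
#' Stage I (per-neuron lookup) prediction, the combined two-stage
#' prediction, and the distance to the winning neuron. An empty table means
#' every compound is in domain.
#'
#' @param model a `cpbpe_model`.
#' @param dataset a [qsar_dataset()] to screen.
#' @return data.frame with columns `id`, `observed`, `pred_cpann`,
#'   `pred_cpbpe`, `distance`.
#' @export
outlier_report <- function(model, dataset) {
  stopifnot(inherits(model, "cpbpe_model"), inherits(dataset, "qsar_dataset"))
  pred <- predict_cpbpe(model, dataset$X)
  out <- !pred$in_domain
  data.frame(id = dataset$ids[out],
             observed = dataset$targets[out],
             pred_cpann = pred$cp_value[out],
             pred_cpbpe = pred$value[out],
             distance = pred$distance[out],
             stringsAsFactors = FALSE)
}
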