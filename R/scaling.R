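#' Fit min-max scaling parameters on a training set
#'
#' Records the per-descriptor minimum and maximum and the target minimum and
#' maximum of `dataset` — and of this dataset only: scaling is always fitted
#' on the training set and reused, never refitted, on test or validation
#' compounds. Descriptors map onto \[0, 1\]; the target maps onto
#' \[`target_low`, `target_high`\] (default \[0.1, 0.9\]) so a
#' sigmoid-output network can represent every training value with headroom.
#'
#' Constant columns are flagged, not dropped (dropping would silently change
#' the descriptor count, which must equal the Stage II input-layer size);
#' they scale to 0.5.
#'
#' @param dataset a [qsar_dataset()] (normally the training set).
#' @param target_low,target_high bounds of the scaled target interval,
#'   `0 <= target_low < target_high <= 1`.
#' @return an object of class `scaling_params`.
#' @export
fit_scaling <- function(dataset, target_low = 0.1, target_high = 0.9) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (!(target_low >= 0 && target_low < target_high && target_high <= 1))
    stop("need 0 <= target_low < target_high <= 1")
  x_min <- apply(dataset$X, 2L, min)
  x_max <- apply(dataset$X, 2L, max)
  constant <- x_max == x_min
  if (any(constant))
    warning("constant descriptor column(s) scaled to 0.5: ",
            paste(names(which(constant)), collapse = ", "))
  structure(
    list(x_min = x_min, x_max = x_max, constant = constant,
         t_min = min(dataset$targets), t_max = max(dataset$targets),
         target_low = target_low, target_high = target_high),
    class = "scaling_params"
  )
}

#' Scale descriptors to the unit interval
#'
#' Linear per-column map `(x - min) / (max - min)` using the fitted range.
#' Values outside the fitted range map outside \[0, 1\] on purpose — no
#' clipping — so extrapolation stays visible to the applicability-domain
#' check.
#'
#' @param X descriptor matrix or single descriptor vector (raw units).
#' @param params a [fit_scaling()] result.
#' @return matrix (or vector) of scaled values.
#' @export
scale_descriptors <- function(X, params) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(params$x_min))
    stop("descriptor count (", ncol(X), ") does not match scaling parameters (",
         length(params$x_min), ")")
  rng <- params$x_max - params$x_min
  out <- sweep(X, 2L, params$x_min, "-")
  out <- sweep(out, 2L, ifelse(params$constant, 1, rng), "/")
  if (any(params$constant)) out[, params$constant] <- 0.5
  if (vec) out[1L, ] else out
}

#' Scale target values to the fitted interval
#' @param values numeric vector in original property units.
#' @inheritParams scale_descriptors
#' @return numeric vector in scaled units.
#' @export
scale_target <- function(values, params) {
  span <- params$t_max - params$t_min
  if (span == 0) return(rep((params$target_low + params$target_high) / 2,
                            length(values)))
  params$target_low + (values - params$t_min) / span *
    (params$target_high - params$target_low)
}

#' Map scaled target values back to original property units
#' @inheritParams scale_target
#' @export
inverse_scale_target <- function(values, params) {
  span <- params$t_max - params$t_min
  if (span == 0) return(rep(params$t_min, length(values)))
  params$t_min + (values - params$target_low) /
    (params$target_high - params$target_low) * span
}

#' Apply fitted scaling to a whole dataset
#' @param dataset a [qsar_dataset()].
#' @inheritParams scale_descriptors
#' @return a [qsar_dataset()] in scaled units.
#' @export
scale_dataset <- function(dataset, params) {
  out <- dataset
  out$X <- scale_descriptors(dataset$X, params)
  colnames(out$X) <- dataset$descriptor_names
  out$targets <- scale_target(dataset$targets, params)
  out
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("min-max scaling over", length(x$x_min), "descriptors;",
      "target [", format(x$t_min), ",", format(x$t_max), "] -> [",
      x$target_low, ",", x$target_high, "]\n")
  if (any(x$constant))
    cat("  constant columns:", paste(names(which(x$constant)), collapse = ", "), "\n")
  invisible(x)
}

#' Root-mean-square error
#'
#' @param predicted,observed numeric vectors of equal length, in the same
#'   (original) property units.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed have different lengths")
  if (length(predicted) < 1L) stop("need at least one value")
  sqrt(mean((predicted - observed)^2))
}
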