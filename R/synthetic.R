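#' Specification for a synthetic descriptor/property table
#'
#' The generator emulates a curated QSAR table: `m` compounds described by
#' `n` numeric descriptors drawn in \[0, 1\] (uniformly, or clustered
#' around `cluster_count` centers with uniform jitter), with a target that
#' is a smooth function of the first `n_informative` descriptors plus
#' Gaussian noise. The remaining descriptors are pure nuisance. Targets
#' land in a logS-like range (default -9 to 1 log mol/L) so scaling and
#' reporting resemble an aqueous-solubility study.
#'
#' Available target surfaces (`z` = mean of the informative descriptors):
#' `linear` (`z`), `quadratic` (`z^2`), `sinusoidal`
#' (`(1 - cos(2 pi z)) / 2`), and `plateau` (one constant level per
#' cluster).
#'
#' @param m,n compounds and descriptors.
#' @param n_informative how many leading descriptors carry signal.
#' @param fun target surface, see above.
#' @param noise_sd Gaussian noise standard deviation, in target units.
#' @param cluster_count 1 for uniform descriptors, larger for clustered.
#' @param jitter half-width of the uniform scatter around cluster centers.
#' @param target_range length-2 range the noiseless target spans.
#' @param seed generation seed; tables are bit-reproducible given the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m, n, n_informative = n,
                           fun = c("linear", "quadratic", "sinusoidal",
                                   "plateau"),
                           noise_sd = 0, cluster_count = 1L, jitter = 0.05,
                           target_range = c(-9, 1), seed = 1L) {
  fun <- match.arg(fun)
  m <- as.integer(m); n <- as.integer(n)
  n_informative <- as.integer(n_informative)
  cluster_count <- as.integer(cluster_count)
  if (m < 1L || n < 1L) stop("need m >= 1 and n >= 1")
  if (n_informative < 1L || n_informative > n)
    stop("n_informative must lie in 1..n")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cluster_count < 1L) stop("cluster_count must be >= 1")
  if (fun == "plateau" && cluster_count < 2L)
    stop("the plateau surface needs at least two clusters")
  structure(list(m = m, n = n, n_informative = n_informative, fun = fun,
                 noise_sd = noise_sd, cluster_count = cluster_count,
                 jitter = jitter, target_range = as.numeric(target_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor/property dataset
#'
#' Fully deterministic given the spec's seed: the descriptor matrix is
#' drawn first and the noise vector last, so regenerating with
#' `noise_sd = 0` and the same seed reproduces the identical descriptors
#' and the noiseless targets.
#'
#' @param spec a [synthetic_spec()].
#' @return a [qsar_dataset()].
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cc <- spec$cluster_count
  if (cc == 1L) {
    X <- matrix(stats::runif(spec$m * spec$n), spec$m, spec$n)
    cluster <- rep(1L, spec$m)
  } else {
    centers <- matrix(stats::runif(cc * spec$n, 0.15, 0.85), cc, spec$n)
    cluster <- rep_len(seq_len(cc), spec$m)
    X <- centers[cluster, , drop = FALSE] +
      matrix(stats::runif(spec$m * spec$n, -spec$jitter, spec$jitter),
             spec$m, spec$n)
  }
  z <- rowMeans(X[, seq_len(spec$n_informative), drop = FALSE])
  y01 <- switch(spec$fun,
                linear = z,
                quadratic = z^2,
                sinusoidal = (1 - cos(2 * pi * z)) / 2,
                plateau = (cluster - 1) / (cc - 1))
  lo <- spec$target_range[1L]
  hi <- spec$target_range[2L]
  targets <- lo + (hi - lo) * y01 +
    stats::rnorm(spec$m, 0, spec$noise_sd)
  colnames(X) <- paste0("D", seq_len(spec$n))
  qsar_dataset(sprintf("cmpd_%04d", seq_len(spec$m)), X, targets)
}

#' Tight-cluster fixture exposing the per-neuron lookup limitation
#'
#' `k_clusters` well-separated clusters of `per_cluster` compounds in two
#' descriptors; within each cluster the target varies linearly (slope 1 in
#' the first descriptor) over the jitter range, around a cluster-specific
#' logS-like base level. A small Kohonen map places each cluster on one
#' neuron, so a per-neuron lookup cannot beat the within-cluster target
#' spread (RMSE >= jitter / sqrt(12) analytically, about 0.029 for the
#' default jitter 0.1), while a smooth regressor can resolve the
#' within-cluster trend.
#'
#' @param k_clusters number of clusters (default 4, placed on the corners
#'   of the unit square; more clusters fall on a grid).
#' @param per_cluster compounds per cluster.
#' @param jitter full width of the uniform scatter (and of the target
#'   trend) within a cluster.
#' @param seed generation seed.
#' @return a [qsar_dataset()] with `k_clusters * per_cluster` compounds and
#'   2 descriptors.
#' @export
make_plateau_fixture <- function(k_clusters = 4L, per_cluster = 25L,
                                 jitter = 0.1, seed = 1L) {
  k_clusters <- as.integer(k_clusters)
  per_cluster <- as.integer(per_cluster)
  if (k_clusters < 2L || per_cluster < 1L)
    stop("need at least 2 clusters with at least 1 compound each")
  set.seed(seed)
  side <- ceiling(sqrt(k_clusters))
  gx <- ((seq_len(k_clusters) - 1L) %% side) / max(side - 1L, 1L)
  gy <- ((seq_len(k_clusters) - 1L) %/% side) / max(side - 1L, 1L)
  centers <- cbind(0.15 + 0.7 * gx, 0.15 + 0.7 * gy)
  m <- k_clusters * per_cluster
  cluster <- rep(seq_len(k_clusters), each = per_cluster)
  off <- matrix(stats::runif(m * 2L, -jitter / 2, jitter / 2), m, 2L)
  X <- centers[cluster, , drop = FALSE] + off
  colnames(X) <- c("D1", "D2")
  # logS-like base levels, within-cluster linear trend of slope 1 in D1
  bases <- seq(-8, 1, length.out = k_clusters)
  targets <- bases[cluster] + off[, 1L]
  qsar_dataset(sprintf("cmpd_%04d", seq_len(m)), X, targets)
}
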