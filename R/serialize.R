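SUPPORTED_FORMAT <- numeric_version("1.0")

#' Serialize a CP-BPE model to a JSON string
#'
#' One self-contained document holding both stages' weights, the scaling
#' parameters, all configuration, the applicability-domain threshold and a
#' format-version string. Numbers are written at full precision, so two
#' models trained with identical data, configuration and seeds serialize
#' to byte-identical strings.
#'
#' @param model a `cpbpe_model`.
#' @return a JSON character string.
#' @export
serialize_cpbpe <- function(model) {
  stopifnot(inherits(model, "cpbpe_model"))
  doc <- list(
    format_version = CPBPE_FORMAT_VERSION,
    metadata = model$metadata,
    scaling = unclass(model$scaling),
    ad = unclass(model$ad),
    cpann = list(config = unclass(model$cpann$config),
                 kohonen = unname(model$cpann$kohonen),
                 grossberg = model$cpann$grossberg,
                 train_distances = unname(model$cpann$train_distances),
                 train_ids = names(model$cpann$train_distances),
                 winners = model$cpann$winners,
                 occupancy = model$cpann$occupancy,
                 descriptor_names = model$cpann$descriptor_names),
    bpe = list(config = unclass(model$bpe$config),
               W1 = unname(model$bpe$W1), W2 = model$bpe$W2,
               P1 = unname(model$bpe$P1), P2 = model$bpe$P2,
               trace = model$bpe$trace)
  )
  as.character(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                                null = "null"))
}

#' Save / load a CP-BPE model archive
#'
#' @param model a `cpbpe_model`.
#' @param path file path of the JSON archive.
#' @return `save_cpbpe` returns `path` invisibly; `load_cpbpe` returns the
#'   restored `cpbpe_model`. Loading an archive written by a newer format
#'   than this package supports is an explicit error.
#' @export
save_cpbpe <- function(model, path) {
  writeLines(serialize_cpbpe(model), path)
  invisible(path)
}

#' @rdname save_cpbpe
#' @export
load_cpbpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  ver <- numeric_version(doc$format_version)
  if (ver > SUPPORTED_FORMAT)
    stop("model archive format ", doc$format_version,
         " is newer than the supported ", as.character(SUPPORTED_FORMAT))
  scaling <- doc$scaling
  scaling$x_min <- stats::setNames(as.numeric(scaling$x_min),
                                   doc$cpann$descriptor_names)
  scaling$x_max <- stats::setNames(as.numeric(scaling$x_max),
                                   doc$cpann$descriptor_names)
  scaling$constant <- stats::setNames(as.logical(scaling$constant),
                                      doc$cpann$descriptor_names)
  class(scaling) <- "scaling_params"
  ad <- doc$ad
  ad$percentile <- if (is.null(ad$percentile)) NA_real_ else ad$percentile
  class(ad) <- "ad_threshold"
  cp_cfg <- doc$cpann$config
  cp_cfg <- cpann_config(cp_cfg$map_rows, cp_cfg$map_cols, cp_cfg$epochs,
                         cp_cfg$eta_max, cp_cfg$eta_min, cp_cfg$topology,
                         cp_cfg$neighborhood, cp_cfg$seed)
  kohonen <- matrix(doc$cpann$kohonen, ncol = length(doc$cpann$descriptor_names))
  colnames(kohonen) <- doc$cpann$descriptor_names
  cpann <- structure(
    list(kohonen = kohonen, grossberg = as.numeric(doc$cpann$grossberg),
         config = cp_cfg, scaling = scaling,
         train_distances = stats::setNames(as.numeric(doc$cpann$train_distances),
                                           doc$cpann$train_ids),
         winners = as.integer(doc$cpann$winners),
         occupancy = as.integer(doc$cpann$occupancy),
         descriptor_names = doc$cpann$descriptor_names),
    class = "cpann_model")
  bp_cfg <- doc$bpe$config
  bp_cfg <- bpe_config(bp_cfg$hidden_neurons, bp_cfg$learning_rate,
                       bp_cfg$momentum, bp_cfg$epochs, bp_cfg$seed,
                       bp_cfg$init_range, bp_cfg$output)
  h <- bp_cfg$hidden_neurons
  W1 <- matrix(doc$bpe$W1, ncol = h)
  P1 <- matrix(doc$bpe$P1, ncol = h)
  bpe <- new_bpe_network(W1, as.numeric(doc$bpe$W2), P1,
                         as.numeric(doc$bpe$P2), bp_cfg,
                         trace = as.numeric(doc$bpe$trace))
  structure(list(cpann = cpann, bpe = bpe, scaling = scaling, ad = ad,
                 metadata = doc$metadata),
            class = "cpbpe_model")
}
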