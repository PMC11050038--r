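CPBPE_FORMAT_VERSION <- "1.0"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a combined two-stage CP-BPE model
#'
#' The two stages are trained separately and in sequence. Stage I fits
#' min-max scaling on the training set and trains the counter-propagation
#' network on the scaled compounds. Its k neurons — Kohonen weight vectors
#' paired with Grossberg values — are then extracted and become the entire
#' Stage II training set for the back-propagation network; Stage I is
#' frozen from that point on (no gradient ever reaches the Kohonen
#' weights). The applicability-domain threshold is fitted from the training
#' compounds' distances to their winning neurons.
#'
#' @param train a [qsar_dataset()] (raw units).
#' @param cp_config a [cpann_config()] for Stage I.
#' @param bpe_config a [bpe_config()] for Stage II.
#' @param target_low,target_high scaled target interval, see
#'   [fit_scaling()].
#' @param ad_method,ad_percentile applicability-domain rule, see
#'   [fit_ad()].
#' @param occupied_only train Stage II on occupied neurons only (default
#'   `FALSE`: all k neurons, empty ones carrying their smoothed Grossberg
#'   values).
#' @return an object of class `cpbpe_model` with elements `cpann`, `bpe`,
#'   `scaling`, `ad` and `metadata`.
#' @export
train_cpbpe <- function(train, cp_config, bpe_config,
                        target_low = 0.1, target_high = 0.9,
                        ad_method = "max", ad_percentile = 95,
                        occupied_only = FALSE) {
  stopifnot(inherits(train, "qsar_dataset"),
            inherits(cp_config, "cpann_config"),
            inherits(bpe_config, "bpe_config"))
  scaling <- fit_scaling(train, target_low, target_high)
  cpann <- train_cpann(train, cp_config, scaling = scaling)
  neurons <- extract_neurons(cpann, occupied_only = occupied_only)
  ad <- fit_ad(cpann$train_distances, method = ad_method,
               percentile = ad_percentile)
  bpe <- train_bpe(neurons, bpe_config)
  assemble_cpbpe(cpann, bpe, neurons, ad, n_compounds(train), occupied_only)
}

assemble_cpbpe <- function(cpann, bpe, neurons, ad, n_train, occupied_only) {
  structure(
    list(cpann = cpann, bpe = bpe, scaling = cpann$scaling, ad = ad,
         metadata = list(format_version = CPBPE_FORMAT_VERSION,
                         n_descriptors = ncol(cpann$kohonen),
                         n_train_compounds = n_train,
                         n_stage2_objects = nrow(neurons$inputs),
                         occupied_only = occupied_only)),
    class = "cpbpe_model"
  )
}

#' @export
print.cpbpe_model <- function(x, ...) {
  cat("CP-BPE model (format", x$metadata$format_version, ")\n")
  cat("  Stage I :", x$cpann$config$map_rows, "x", x$cpann$config$map_cols,
      "map on", x$metadata$n_train_compounds, "compounds,",
      x$metadata$n_descriptors, "descriptors\n")
  cat("  Stage II:", x$bpe$config$hidden_neurons, "hidden neurons trained on",
      x$metadata$n_stage2_objects, "neurons,",
      x$bpe$config$epochs, "epochs\n")
  cat("  AD      :", x$ad$method, "threshold", format(x$ad$threshold), "\n")
  invisible(x)
}

#' Predict with a combined CP-BPE model
#'
#' Scales the query descriptors, runs the Stage II forward pass and maps
#' the output back to property units (`value`). For comparison the Stage I
#' per-neuron lookup (`cp_value`), the winning neuron, the distance to it
#' and the applicability-domain flag are reported alongside — the shape of
#' a standard QSAR prediction table. Unlike `cp_value`, `value` differs for
#' every distinct input, also within one neuron.
#'
#' @param model a `cpbpe_model`.
#' @param x raw descriptor vector, or matrix / [qsar_dataset()] with one
#'   row per compound.
#' @return for a vector: a list; otherwise a data.frame with columns
#'   `value`, `cp_value`, `winner_row`, `winner_col`, `distance`,
#'   `in_domain` (and `id` for a dataset).
#' @export
predict_cpbpe <- function(model, x) {
  stopifnot(inherits(model, "cpbpe_model"))
  ids <- NULL
  if (inherits(x, "qsar_dataset")) { ids <- x$ids; x <- x$X }
  vec <- is.null(dim(x))
  X <- scale_descriptors(if (vec) matrix(as.numeric(x), nrow = 1L) else as.matrix(x),
                         model$scaling)
  mp <- cpp_map_objects(model$cpann$kohonen, X)
  coords <- neuron_index_to_coords(mp$winner, model$cpann$config$map_cols)
  value <- inverse_scale_target(predict_bpe(model$bpe, X), model$scaling)
  cp_value <- inverse_scale_target(model$cpann$grossberg[mp$winner],
                                   model$scaling)
  flag <- mp$distance <= model$ad$threshold
  if (vec)
    return(list(value = value[1L], cp_value = cp_value[1L],
                winner_row = coords$row[1L], winner_col = coords$col[1L],
                distance = mp$distance[1L], in_domain = flag[1L]))
  out <- data.frame(value = value, cp_value = cp_value,
                    winner_row = coords$row, winner_col = coords$col,
                    distance = mp$distance, in_domain = flag)
  if (!is.null(ids)) out <- cbind(data.frame(id = ids,
                                             stringsAsFactors = FALSE), out)
  out
}

#' @export
predict.cpbpe_model <- function(object, newdata, ...) {
  predict_cpbpe(object, newdata)
}

#' Grid model selection over Stage II settings
#'
#' Stage I is trained once and reused across the grid — the extracted
#' neurons do not depend on Stage II settings — then one back-propagation
#' network is trained per (hidden_neurons, epochs) cell and scored by the
#' RMSE of the combined model on the test compounds. The validation set is
#' never touched during selection. Ties resolve to fewer hidden neurons,
#' then fewer epochs.
#'
#' @param train,test labelled or plain [qsar_dataset()]s (raw units).
#' @param cp_config a [cpann_config()].
#' @param hidden_grid hidden-layer sizes to try (default 5, 10, 12).
#' @param epoch_grid epoch counts to try (default 1e3, 1e4, 1e5, 5e5,
#'   spanning the conventional 1000-500000 range).
#' @param bpe_base a [bpe_config()] providing learning rate, momentum,
#'   seed and the other settings shared across cells.
#' @param ... `target_low`, `target_high`, `ad_method`, `ad_percentile`,
#'   `occupied_only` as in [train_cpbpe()].
#' @return an object of class `selection_result`: `$grid` (one row per
#'   cell with `hidden`, `epochs`, `rmse_test`, `rmse_train_neurons`,
#'   `rmse_train_compounds`), `$chosen` (hidden, epochs), and `$model`,
#'   the winning `cpbpe_model`.
#' @export
select_model <- function(train, test, cp_config,
                         hidden_grid = c(5L, 10L, 12L),
                         epoch_grid = c(1000L, 10000L, 100000L, 500000L),
                         bpe_base = bpe_config(hidden_neurons = 5L), ...) {
  stopifnot(inherits(train, "qsar_dataset"), inherits(test, "qsar_dataset"))
  if (length(hidden_grid) == 0L || length(epoch_grid) == 0L)
    stop("hidden_grid and epoch_grid must be nonempty")
  if (n_compounds(test) == 0L) stop("empty test set")

  # Stage I once; the extracted neurons do not depend on Stage II settings
  dots <- list(...)
  scaling <- fit_scaling(train,
                         target_low = dots$target_low %||% 0.1,
                         target_high = dots$target_high %||% 0.9)
  cpann <- train_cpann(train, cp_config, scaling = scaling)
  occupied_only <- isTRUE(dots$occupied_only)
  neurons <- extract_neurons(cpann, occupied_only = occupied_only)
  ad <- fit_ad(cpann$train_distances,
               method = dots$ad_method %||% "max",
               percentile = dots$ad_percentile %||% 95)

  cells <- expand.grid(hidden = as.integer(hidden_grid),
                       epochs = as.integer(epoch_grid))
  models <- vector("list", nrow(cells))
  rmse_test <- rmse_neu <- rmse_trc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    bc <- bpe_base
    bc$hidden_neurons <- cells$hidden[i]
    bc$epochs <- cells$epochs[i]
    mod <- assemble_cpbpe(cpann, train_bpe(neurons, bc), neurons, ad,
                          n_compounds(train), occupied_only)
    models[[i]] <- mod
    rmse_test[i] <- rmse(predict_cpbpe(mod, test$X)$value, test$targets)
    rmse_neu[i] <- mod$bpe$trace[length(mod$bpe$trace)]
    rmse_trc[i] <- rmse(predict_cpbpe(mod, train$X)$value, train$targets)
  }
  grid <- cbind(cells, rmse_test = rmse_test,
                rmse_train_neurons = rmse_neu,
                rmse_train_compounds = rmse_trc)
  ord <- order(grid$rmse_test, grid$hidden, grid$epochs)
  best <- ord[1L]
  structure(list(grid = grid,
                 chosen = c(hidden = grid$hidden[best],
                            epochs = grid$epochs[best]),
                 model = models[[best]]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("model selection over", nrow(x$grid), "cells; chosen: hidden =",
      x$chosen[["hidden"]], ", epochs =", x$chosen[["epochs"]],
      "(test RMSE", format(min(x$grid$rmse_test)), ")\n")
  invisible(x)
}

#' Evaluate a CP-BPE model on labelled train/test/validation sets
#'
#' Reports, per set, the RMSE of the Stage I lookup and of the combined
#' model — overall and restricted to in-domain compounds — together with
#' the in/out-of-domain counts. An absent set is omitted with a message.
#'
#' @param model a `cpbpe_model`.
#' @param dataset a [qsar_dataset()] with set labels, or a plain dataset
#'   (evaluated as a single `"ALL"` set).
#' @return data.frame, one row per set, with columns `set`, `n`,
#'   `rmse_cpann`, `rmse_cpbpe`, `rmse_cpann_in_domain`,
#'   `rmse_cpbpe_in_domain`, `n_in_domain`, `n_out_of_domain`.
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(inherits(model, "cpbpe_model"), inherits(dataset, "qsar_dataset"))
  labels <- dataset$set_labels
  if (is.null(labels)) labels <- rep("ALL", n_compounds(dataset))
  wanted <- if (identical(unique(labels), "ALL")) "ALL"
            else c("TRAIN", "TEST", "VALIDATION")
  rows <- lapply(wanted, function(set) {
    idx <- which(labels == set)
    if (length(idx) == 0L) {
      message("no compounds in the ", set, " set; omitted from the report")
      return(NULL)
    }
    pred <- predict_cpbpe(model, dataset$X[idx, , drop = FALSE])
    obs <- dataset$targets[idx]
    ind <- pred$in_domain
    data.frame(set = set, n = length(idx),
               rmse_cpann = rmse(pred$cp_value, obs),
               rmse_cpbpe = rmse(pred$value, obs),
               rmse_cpann_in_domain =
                 if (any(ind)) rmse(pred$cp_value[ind], obs[ind]) else NA_real_,
               rmse_cpbpe_in_domain =
                 if (any(ind)) rmse(pred$value[ind], obs[ind]) else NA_real_,
               n_in_domain = sum(ind), n_out_of_domain = sum(!ind),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-k-out cross-validation of the two-stage model
#'
#' Shuffles the compounds once from `seed`, cuts the shuffled order into
#' contiguous blocks of `leave_out` compounds (the last block may be
#' smaller), retrains both stages on each complement and predicts the held
#' out block; the pooled predictions are scored by RMSE in property units.
#'
#' @param train a [qsar_dataset()].
#' @param leave_out block size, `0 < leave_out < m`.
#' @param cp_config a [cpann_config()].
#' @param bpe_config a [bpe_config()].
#' @param seed fold-assignment seed.
#' @param ... passed to [train_cpbpe()].
#' @return list with `rmse`, `folds` (per-compound fold index) and
#'   `predictions` (in input order).
#' @export
crossvalidate <- function(train, leave_out, cp_config, bpe_config,
                          seed = 1L, ...) {
  stopifnot(inherits(train, "qsar_dataset"))
  m <- n_compounds(train)
  leave_out <- as.integer(leave_out)
  if (leave_out <= 0L) stop("leave_out must be positive")
  if (leave_out >= m) stop("leave_out must be smaller than the dataset")
  set.seed(seed)
  ord <- sample.int(m)
  fold_of <- integer(m)
  fold_of[ord] <- (seq_len(m) - 1L) %/% leave_out + 1L
  preds <- numeric(m)
  for (f in seq_len(max(fold_of))) {
    hold <- which(fold_of == f)
    mod <- train_cpbpe(train[-hold], cp_config, bpe_config, ...)
    preds[hold] <- predict_cpbpe(mod, train$X[hold, , drop = FALSE])$value
  }
  list(rmse = rmse(preds, train$targets), folds = fold_of,
       predictions = preds)
}
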