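#' Construct a QSAR dataset
#'
#' A `qsar_dataset` holds one row per compound: a unique identifier, a
#' numeric descriptor matrix `X` (m compounds by n descriptors), a numeric
#' target vector `targets` (the modelled property, e.g. logS in log mol/L)
#' and, optionally, a per-compound set label in
#' `{"TRAIN", "TEST", "VALIDATION"}`.
#'
#' Missing values are rejected: the curated descriptor tables this class is
#' meant for contain none, and imputation is out of scope.
#'
#' @param ids character vector of unique compound identifiers.
#' @param X numeric matrix of descriptor values, one row per compound.
#'   Column names are the descriptor names; unnamed columns are named
#'   `D1..Dn`.
#' @param targets numeric vector of property values, one per compound.
#' @param set_labels optional character vector of set memberships
#'   (case-insensitive `train`/`test`/`validation`).
#' @return An object of class `qsar_dataset`.
#' @export
qsar_dataset <- function(ids, X, targets, set_labels = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ids <- as.character(ids)
  targets <- as.numeric(targets)
  m <- nrow(X)
  if (m < 1L || ncol(X) < 1L)
    stop("a dataset needs at least one compound and one descriptor")
  if (length(ids) != m || length(targets) != m)
    stop("ids, X and targets must describe the same number of compounds")
  if (anyNA(X) || any(!is.finite(X)))
    stop("descriptor matrix contains missing or non-finite values")
  if (anyNA(targets) || any(!is.finite(targets)))
    stop("target vector contains missing or non-finite values")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stop("descriptor names must be unique")
  if (!is.null(set_labels)) {
    set_labels <- normalize_set_labels(set_labels)
    if (length(set_labels) != m)
      stop("set_labels must have one entry per compound")
  }
  structure(
    list(ids = ids, X = X, targets = targets,
         descriptor_names = colnames(X), set_labels = set_labels),
    class = "qsar_dataset"
  )
}

normalize_set_labels <- function(labels) {
  up <- toupper(trimws(as.character(labels)))
  ok <- up %in% c("TRAIN", "TEST", "VALIDATION")
  if (!all(ok))
    stop("invalid set label(s): ", paste(unique(labels[!ok]), collapse = ", "),
         " (expected train/test/validation)")
  up
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("QSAR dataset:", n_compounds(x), "compounds x",
      n_descriptors(x), "descriptors\n")
  cat("  target range: [", format(min(x$targets)), ",",
      format(max(x$targets)), "]\n")
  if (!is.null(x$set_labels)) {
    tb <- table(factor(x$set_labels, c("TRAIN", "TEST", "VALIDATION")))
    cat("  sets:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of compounds / descriptors in a dataset
#' @param dataset a [qsar_dataset()].
#' @return integer count.
#' @export
n_compounds <- function(dataset) nrow(dataset$X)

#' @rdname n_compounds
#' @export
n_descriptors <- function(dataset) ncol(dataset$X)

#' Row subset of a dataset
#' @param x a [qsar_dataset()].
#' @param i row (compound) index.
#' @param ... unused.
#' @export
`[.qsar_dataset` <- function(x, i, ...) {
  qsar_dataset(x$ids[i], x$X[i, , drop = FALSE], x$targets[i],
               if (!is.null(x$set_labels)) x$set_labels[i])
}

#' Extract the compounds carrying a given set label
#' @param dataset a labelled [qsar_dataset()].
#' @param label one of `"TRAIN"`, `"TEST"`, `"VALIDATION"`.
#' @return a [qsar_dataset()] restricted to that set (labels dropped).
#' @export
dataset_subset <- function(dataset, label) {
  if (is.null(dataset$set_labels))
    stop("dataset has no set labels; run som_split() first")
  label <- normalize_set_labels(label)
  keep <- which(dataset$set_labels == label)
  if (length(keep) == 0L) stop("no compounds labelled ", label)
  dataset[keep]
}

#' Read a delimited descriptor/property table
#'
#' Expects a header row with an identifier column, a numeric target column,
#' any number of numeric descriptor columns, and optionally a set-membership
#' column with values `train`/`test`/`validation` (case-insensitive). Every
#' column other than `id_col`, `target_col` and `set_col` is treated as a
#' descriptor; a non-numeric or missing descriptor or target cell is an
#' error that names the offending row and column, never a silent drop.
#'
#' @param path path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param id_col,target_col,set_col column names; `set_col = NULL` (default)
#'   means no set column.
#' @param sep field separator, `","` by default.
#' @return a [qsar_dataset()].
#' @export
read_dataset <- function(path, id_col = "id", target_col = "target",
                         set_col = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (col in c(id_col, target_col, set_col)) {
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path)
  }
  desc_cols <- setdiff(names(raw), c(id_col, target_col, set_col))
  if (length(desc_cols) == 0L) stop("no descriptor columns in ", path)
  parse_numeric_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop("non-numeric or missing value in column '", col,
           "', row ", bad[1L], " (value '", raw[[col]][bad[1L]], "')")
    v
  }
  X <- vapply(desc_cols, parse_numeric_col, numeric(nrow(raw)))
  if (nrow(raw) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, desc_cols))
  colnames(X) <- desc_cols
  targets <- parse_numeric_col(target_col)
  labels <- if (!is.null(set_col)) raw[[set_col]] else NULL
  qsar_dataset(raw[[id_col]], X, targets, labels)
}

#' Write a dataset as delimited text
#'
#' Column layout mirrors [read_dataset()]: `id`, descriptors, `target`, and
#' a `set` column when labels are present.
#'
#' @param dataset a [qsar_dataset()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  df <- data.frame(id = dataset$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(dataset$X, check.names = FALSE))
  df$target <- dataset$targets
  if (!is.null(dataset$set_labels)) df$set <- tolower(dataset$set_labels)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
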