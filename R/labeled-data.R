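# Internal representation used throughout: a numeric feature matrix plus a
# label vector, split out of a data frame that carries one label column and
# any number of numeric feature columns.

#' Split a labeled feature data frame into matrix + labels
#'
#' Validates and decomposes a samples-by-features data frame (one label column,
#' all other columns numeric features) into the internal matrix form used by
#' the fitting and selection routines. Exported because oracle-style code and
#' downstream tooling benefit from the same validation.
#'
#' @param data A data frame with one label column and numeric feature columns.
#' @param label_col Name of the label column. Default `"label"`.
#' @param require_classes Minimum number of distinct classes required
#'   (default 2; set to 1 to allow degenerate label sets).
#' @return A list with `x` (numeric matrix, n x d), `y` (character vector of
#'   labels, length n), and `feature_names` (character vector, length d).
#' @examples
#' df <- tibble::tibble(f1 = rnorm(4), f2 = rnorm(4), label = c("a", "a", "b", "b"))
#' str(split_features(df))
#' @export
split_features <- function(data, label_col = "label", require_classes = 2L) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of features plus a label column.")
  }
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found in `data`.", label_col))
  }
  if (anyDuplicated(names(data))) abort("feature names must be unique.")
  y <- as.character(data[[label_col]])
  feat <- data[setdiff(names(data), label_col)]
  if (ncol(feat) < 1L) abort("`data` must contain at least one feature column.")
  non_num <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(non_num) > 0L) {
    abort(sprintf(
      "all feature columns must be numeric; offending columns: %s",
      paste(non_num, collapse = ", ")
    ))
  }
  x <- as.matrix(feat)
  if (nrow(x) < 2L) abort("need at least 2 samples.")
  if (anyNA(x) || !all(is.finite(x))) {
    abort("feature matrix contains missing or non-finite values; not imputed.")
  }
  if (anyNA(y)) abort("label column contains missing values.")
  if (length(unique(y)) < require_classes) {
    abort(sprintf("need >= %d classes; got %d.", require_classes, length(unique(y))))
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(fn)) abort("feature names must be unique.")
  list(x = x, y = y, feature_names = fn)
}

#' Read a labeled feature table from CSV/TSV
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#' @param label_col Name of the label column (default `"label"`).
#' @return A tibble with feature columns and the label column.
#' @export
read_features <- function(path, label_col = "label") {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  split_features(out, label_col = label_col, require_classes = 1L) # validate
  out
}

#' Write a labeled feature table to CSV
#'
#' @param data Data frame of features plus label column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# canonical label ordering used for deterministic tie-breaks
label_alphabet <- function(...) {
  sort(unique(unlist(lapply(list(...), as.character))))
}

# deterministic sub-seed derivation; stays below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 65536) * 31627 + offset) %% 2147483629L
}
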