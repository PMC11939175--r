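# Text frontend: cleaning, embedding backends, and feature concatenation.
# The hashing backend is the deterministic, dependency-free stand-in for
# pre-trained transformer embedders: it maps token hashes into a fixed-width
# signed-count vector (the classic hashing trick), which preserves enough
# lexical signal for the selection and voting stages to be exercised
# end-to-end.

#' Default English stopword list
#'
#' A small pinned English stopword list shipped with the package, so cleaning
#' runs are reproducible. Supply your own character vector to [clean_text()]
#' to override.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "cwinca")
  readLines(path, encoding = "UTF-8")
}

#' Clean raw text
#'
#' Applies, in order: lowercasing; removal of punctuation and all other
#' non-alphanumeric symbols (replaced by spaces); collapsing runs of three or
#' more identical characters down to two; whitespace tokenization; stopword
#' removal; rejoining with single spaces. Idempotent. Empty output is allowed
#' and flagged upstream by [embed_texts()].
#'
#' @param x Character vector of raw texts.
#' @param stopwords Character vector of stopwords to drop
#'   (default [default_stopwords()]).
#' @return Character vector of cleaned texts, same length as `x`.
#' @examples
#' clean_text("I am soooo sad!!!", stopwords = c("i", "am"))
#' @export
clean_text <- function(x, stopwords = default_stopwords()) {
  x <- tolower(as.character(x))
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("(.)\\1{2,}", "\\1\\1", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")
  vapply(toks, function(tk) {
    tk <- tk[nzchar(tk) & !(tk %in% stopwords)]
    paste(tk, collapse = " ")
  }, character(1))
}

# djb2-style rolling hash over UTF-8 bytes, kept exact in double arithmetic.
hash_token <- function(token) {
  h <- 5381
  for (b in utf8ToInt(token)) h <- (h * 33 + b) %% 2147483647
  h
}

#' Deterministic hashing embedding backend
#'
#' Maps each token to a coordinate (its hash modulo `dim`) and a sign, and
#' embeds a text as the vector of signed token counts. Fully deterministic,
#' dependency-free, and identical across calls, which is the contract the
#' selection and voting stages need from any embedder.
#'
#' @param dim Embedding width (number of feature columns).
#' @param name Backend name used as the feature-name prefix
#'   (default `"hash<dim>"`).
#' @return An `embedding_backend` object.
#' @export
hashing_backend <- function(dim = 64L, name = paste0("hash", dim)) {
  dim <- as.integer(dim)
  if (dim < 1L) abort("`dim` must be a positive integer.")
  structure(
    list(name = name, dimension = dim, kind = "hashing_test_backend"),
    class = "embedding_backend"
  )
}

#' Transformer embedding adapter (declared interface)
#'
#' Adapter slot for pre-trained transformer sentence embedders (BERT-family
#' models), pooling the final hidden layer (mean pooling by default). Model
#' weights are not bundled with the package; calling [embed_texts()] on this
#' backend errors with instructions to use [hashing_backend()] for
#' deterministic, download-free runs.
#'
#' @param model Model identifier string (e.g. `"bert-base-uncased"`).
#' @param dim Declared embedding width.
#' @param pooling `"mean"` or `"cls"` pooling over final-layer token vectors.
#' @return An `embedding_backend` object of kind `transformer_adapter`.
#' @export
transformer_backend <- function(model, dim = 768L, pooling = c("mean", "cls")) {
  pooling <- match.arg(pooling)
  structure(
    list(name = model, dimension = as.integer(dim),
         kind = "transformer_adapter", pooling = pooling),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend> %s (%s, dim %d)\n", x$name, x$kind, x$dimension))
  invisible(x)
}

#' Embed a labeled corpus into a feature matrix
#'
#' Cleans each text with [clean_text()], drops texts that clean to empty (with
#' a message reporting the count), and embeds the remainder with the backend.
#' Feature columns are named `"<backend>_0" ... "<backend>_{dim-1}"`.
#'
#' @param corpus A data frame with a text column and a label column.
#' @param backend An `embedding_backend` (see [hashing_backend()]).
#' @param text_col,label_col Column names (defaults `"text"`, `"label"`).
#' @param stopwords Stopword list passed to [clean_text()].
#' @return A tibble: `dim` numeric feature columns plus the label column.
#' @examples
#' corpus <- make_text_corpus(n = 20, classes = 2, vocab_per_class = 30,
#'                            overlap = 0, seed = 1)
#' embed_texts(corpus, hashing_backend(16))
#' @export
embed_texts <- function(corpus, backend, text_col = "text", label_col = "label",
                        stopwords = default_stopwords()) {
  if (!inherits(backend, "embedding_backend")) {
    abort("`backend` must be an embedding_backend (see hashing_backend()).")
  }
  if (!all(c(text_col, label_col) %in% names(corpus))) {
    abort(sprintf("`corpus` must contain columns '%s' and '%s'.", text_col, label_col))
  }
  if (nrow(corpus) == 0L) abort("`corpus` is empty.")
  if (backend$kind == "transformer_adapter") {
    abort(paste0(
      "transformer backend '", backend$name, "' is unavailable: no model ",
      "weights are installed. Use hashing_backend() for a deterministic, ",
      "download-free test backend."
    ))
  }
  cleaned <- clean_text(corpus[[text_col]], stopwords = stopwords)
  keep <- nzchar(cleaned)
  if (any(!keep)) {
    message(sprintf("dropped %d text(s) that cleaned to empty.", sum(!keep)))
  }
  cleaned <- cleaned[keep]
  labels <- as.character(corpus[[label_col]])[keep]
  if (length(cleaned) == 0L) abort("all texts cleaned to empty; nothing to embed.")

  toks <- strsplit(cleaned, " ", fixed = TRUE)
  vocab <- unique(unlist(toks))
  h <- vapply(vocab, hash_token, numeric(1))
  idx <- setNames(as.integer(h %% backend$dimension) + 1L, vocab)
  sgn <- setNames(1 - 2 * as.integer((h %/% backend$dimension) %% 2), vocab)

  x <- matrix(0, nrow = length(toks), ncol = backend$dimension)
  for (i in seq_along(toks)) {
    for (tk in toks[[i]]) x[i, idx[[tk]]] <- x[i, idx[[tk]]] + sgn[[tk]]
  }
  out <- as_tibble(as.data.frame(x))
  names(out) <- paste0(backend$name, "_", seq_len(backend$dimension) - 1L)
  out[[label_col]] <- labels
  out
}

#' Concatenate feature matrices column-wise
#'
#' Binds several labeled feature tables (same samples, identical label
#' vectors) into one combined table. Feature-name uniqueness is normally
#' guaranteed by backend-name prefixes; residual clashes are deduplicated
#' with [make.unique()].
#'
#' @param matrices A list of data frames sharing the label column.
#' @param label_col Name of the label column (default `"label"`).
#' @return A tibble with all feature columns and one label column.
#' @export
concat_features <- function(matrices, label_col = "label") {
  if (!is.list(matrices) || length(matrices) < 1L) {
    abort("`matrices` must be a non-empty list of data frames.")
  }
  if (length(matrices) == 1L) return(as_tibble(matrices[[1L]]))
  labels <- lapply(matrices, function(m) {
    if (!label_col %in% names(m)) abort(sprintf("label column '%s' missing.", label_col))
    as.character(m[[label_col]])
  })
  for (i in seq_along(labels)[-1L]) {
    if (!identical(labels[[i]], labels[[1L]])) {
      abort("label vectors differ across matrices; refusing to align rows silently.")
    }
  }
  feats <- lapply(matrices, function(m) m[setdiff(names(m), label_col)])
  out <- dplyr::bind_cols(feats, .name_repair = "minimal")
  names(out) <- make.unique(names(out), sep = "_")
  out[[label_col]] <- labels[[1L]]
  as_tibble(out)
}

#' Read a labeled text corpus from CSV
#'
#' @param path CSV file with columns `text` and `label` (UTF-8).
#' @return A tibble with `text` and `label` columns.
#' @export
read_corpus <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("text", "label") %in% names(out))) {
    abort("corpus CSV must have columns 'text' and 'label'.")
  }
  out
}
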