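# The shared word/document/query vector space. Word vectors are means of
# the base vectors of the documents containing the word; document vectors
# are means of the word vectors of the words they contain; query vectors
# are means of their constituents. Everything lives in one p-dimensional
# space and is directly comparable.

#' Tag a matrix as an embedding space
#'
#' @param m Numeric matrix with unique rownames (labels).
#' @param space_tag One of `"Wbase"`, `"Wwrd"`, `"Wtxt"`, `"Wlog"`, `"WQ"`.
#' @param config Optional [sweep_config] provenance.
#' @return The matrix with class `embedding_matrix`.
#' @export
embedding_matrix <- function(m, space_tag, config = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate labels in embedding matrix")
  if (!all(is.finite(m))) stop("non-finite entries in embedding matrix")
  structure(m, space_tag = space_tag, config = config,
            class = c("embedding_matrix", class(m)))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding '%s': %d rows x %d dims>\n",
              attr(x, "space_tag") %||% "?", nrow(x), ncol(x)))
  invisible(x)
}

# subsetting follows base-matrix drop semantics; matrix results keep the
# class and tags
#' @export
`[.embedding_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "space_tag") <- attr(x, "space_tag")
    attr(out, "config") <- attr(x, "config")
    class(out) <- class(x)
  }
  out
}

# document x word binary incidence over the distinct tokens of each doc
.incidence <- function(x, words) {
  toks <- .corpus_tokens(x, set = TRUE)
  ii <- integer(0); jj <- integer(0)
  for (d in seq_along(toks)) {
    m <- match(toks[[d]], words)
    m <- m[!is.na(m)]
    ii <- c(ii, rep.int(d, length(m)))
    jj <- c(jj, m)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(nrow(x), length(words)),
                       dimnames = list(x$doc_id, words))
}

#' Word vector: mean of containing documents
#'
#' The embedding of a word is the arithmetic mean of the base vectors of
#' exactly the documents whose token set contains it.
#'
#' @param word Token (uppercased internally).
#' @param x The [corpus] the base vectors were computed from.
#' @param wbase The `Wbase` [embedding_matrix] (rows = doc ids).
#' @return Numeric vector of length `ncol(wbase)`.
#' @export
word_embedding <- function(word, x, wbase) {
  word <- toupper(word)
  toks <- .corpus_tokens(x, set = TRUE)
  hit <- names(toks)[vapply(toks, function(t) word %in% t, logical(1))]
  if (!length(hit)) stop("word not found in corpus: ", word)
  colMeans(wbase[hit, , drop = FALSE])
}

#' Embed every vocabulary word (Wwrd)
#'
#' Computes the word vector of each word via the document-word incidence
#' matrix; by default over the complete word list (every corpus token),
#' optionally restricted to the relevant subset.
#'
#' @param x A [corpus].
#' @param wbase The `Wbase` [embedding_matrix].
#' @param vocab Optional [build_vocabulary()] result; `NULL` embeds every
#'   token in the corpus.
#' @param relevant_only Restrict to `vocab$is_relevant` words.
#' @return A `Wwrd` [embedding_matrix], rows = words (sorted).
#' @export
embed_words <- function(x, wbase, vocab = NULL, relevant_only = FALSE) {
  if (is.null(vocab)) vocab <- build_vocabulary(x)
  words <- if (relevant_only) vocab$word[vocab$is_relevant] else vocab$word
  words <- sort(words)
  M <- .incidence(x, words)
  df <- Matrix::colSums(M)
  if (any(df == 0)) {
    words <- words[df > 0]
    M <- M[, df > 0, drop = FALSE]
    df <- df[df > 0]
  }
  B <- unclass(wbase)[x$doc_id, , drop = FALSE]
  W <- as.matrix(Matrix::crossprod(M, B)) / df
  rownames(W) <- words
  embedding_matrix(W, "Wwrd", config = attr(wbase, "config"))
}

#' Document vector: mean of contained words (Wtxt)
#'
#' The final vector of a document is the arithmetic mean of the word
#' vectors of the distinct vocabulary words it contains. Documents
#' containing no embedded word are dropped with a warning.
#'
#' @param x A [corpus].
#' @param wwrd A `Wwrd` [embedding_matrix] (rows = words).
#' @return A `Wtxt` [embedding_matrix], rows = doc ids (corpus order).
#' @export
embed_documents <- function(x, wwrd) {
  D <- .incidence(x, rownames(wwrd))
  nw <- Matrix::rowSums(D)
  if (any(nw == 0)) {
    warning(sum(nw == 0), " document(s) contain no embedded word; dropped: ",
            paste(utils::head(x$doc_id[nw == 0], 5), collapse = ", "))
    D <- D[nw > 0, , drop = FALSE]
  }
  W <- as.matrix(D %*% unclass(wwrd)) / nw[nw > 0]
  embedding_matrix(W, "Wtxt", config = attr(wwrd, "config"))
}

#' Single-document embedding through an existing word space
#'
#' @param title,abstract Raw document fields.
#' @param wwrd A `Wwrd` [embedding_matrix].
#' @return Numeric vector (mean of the vectors of the distinct embedded
#'   words the text contains).
#' @export
document_embedding <- function(title, abstract, wwrd) {
  toks <- unique(tokenize(paste(title, abstract)))
  toks <- toks[toks %in% rownames(wwrd)]
  if (!length(toks)) stop("document contains no embedded vocabulary word")
  colMeans(wwrd[toks, , drop = FALSE])
}

#' Query vector: mean of constituent vectors
#'
#' Each item is resolved against the given spaces in order (first space
#' containing the label wins; conventionally words, then documents, then
#' logical expressions) and the query vector is the arithmetic mean of the
#' resolved vectors. A hyphen-separated string (`"NEUROLOGICAL-BRAIN-CORTEX"`)
#' is split into items.
#'
#' @param items Character vector of labels, or one hyphen-separated string.
#' @param spaces A single [embedding_matrix] or a list of them, in
#'   resolution order.
#' @return Numeric vector of the shared-space length.
#' @export
query_vector <- function(items, spaces) {
  if (inherits(spaces, "embedding_matrix")) spaces <- list(spaces)
  if (length(items) == 1L && grepl("-", items, fixed = TRUE)) {
    items <- strsplit(items, "-", fixed = TRUE)[[1]]
  }
  items <- toupper(trimws(items))
  vecs <- matrix(0, length(items), ncol(spaces[[1]]))
  for (k in seq_along(items)) {
    found <- FALSE
    for (sp in spaces) {
      if (items[k] %in% rownames(sp)) {
        vecs[k, ] <- sp[items[k], ]
        found <- TRUE
        break
      }
    }
    if (!found) stop("query item not found in any space: ", items[k])
  }
  colMeans(vecs)
}

#' Truncate an embedding space by PCA
#'
#' Replaces rows by their scores on the leading principal components
#' (fit on this matrix, centered, unscaled), ordered by descending
#' explained variance. To compare across spaces in truncated coordinates,
#' pass one fit (from a concatenated matrix) via `fit`.
#'
#' @param m An [embedding_matrix] with at least 2 rows.
#' @param n_components Number of components, `1 <= n <= ncol(m)`.
#' @param fit Optional `prcomp` object to project onto instead of fitting.
#' @return An [embedding_matrix] of scores with attribute `pca_fit`.
#' @export
pca_truncate <- function(m, n_components, fit = NULL) {
  if (n_components < 1 || n_components > ncol(m)) {
    stop("n_components must be between 1 and ", ncol(m))
  }
  if (nrow(m) < 2) stop("PCA truncation needs at least 2 rows")
  if (is.null(fit)) fit <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE)
  sc <- stats::predict(fit, unclass(m))[, seq_len(n_components), drop = FALSE]
  out <- embedding_matrix(sc, attr(m, "space_tag"), config = attr(m, "config"))
  attr(out, "pca_fit") <- fit
  out
}

# -- matrix store ------------------------------------------------------------

#' Write/read an embedding space directory
#'
#' A space directory holds `matrix.tsv` (rows = labels, tab-separated),
#' `labels.txt` and `meta.json` (space tag and vectorizer provenance).
#'
#' @param m An [embedding_matrix].
#' @param dir Directory path (created).
#' @return `read_embedding()` returns an [embedding_matrix].
#' @export
write_embedding <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(label = rownames(m), as.data.frame(unclass(m))),
                     file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(rownames(m), file.path(dir, "labels.txt"))
  cfg <- attr(m, "config")
  meta <- list(space_tag = attr(m, "space_tag"), p = ncol(m), n = nrow(m))
  if (!is.null(cfg)) {
    meta$config <- list(mask = cfg$mask$pattern, codec = cfg$codec,
                        mode = cfg$mode, p = cfg$p, seed = cfg$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(dir) {
  df <- utils::read.delim(file.path(dir, "matrix.tsv"), stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  embedding_matrix(m, meta$space_tag %||% "Wbase")
}
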