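# The fitted text-mining map: one call builds the whole shared vector
# space of a corpus (base document vectors, word vectors, final document
# vectors, optional expression vectors) and the relevance-flagged
# vocabulary, and the returned object answers semantic searches, grows
# dendrograms and feeds the HTML reports.

#' Fit the vector text-mining map of a corpus
#'
#' Runs the full pipeline: every document's normalized title + abstract is
#' codec-encoded, spaced-word indexed and projected to a base vector
#' (Wbase); each word is embedded as the mean of its containing documents
#' (Wwrd, over the complete word list); each document is re-embedded as
#' the mean of its words (Wtxt); the vocabulary is relevance-flagged
#' against `background`. All spaces share one geometry and are directly
#' comparable.
#'
#' @param x A (filtered) [corpus].
#' @param config A [sweep_config]; its `p`, mask, codec and seed fully
#'   determine the fit.
#' @param background Optional background word-frequency table (named
#'   numeric) for relevance flagging.
#' @param relevance_threshold Relevance-ratio cutoff (default 1).
#' @param basis Optional precomputed [make_basis()] result (rebuilt from
#'   the config when `NULL`).
#' @return An object of class `textmap` with components `corpus`, `config`,
#'   `vocab`, `wbase`, `wwrd`, `wtxt` and (after [textmap_logexp()])
#'   `wlog`.
#' @examples
#' fx <- generate_corpus(synthetic_spec(docs_per_topic = 5))
#' tm <- textmap(fx$corpus, sweep_config(mask = "101", codec = "dnabits", p = 8))
#' predict(tm, fx$truth$keywords[1], type = "terms", k = 5)
#' @export
textmap <- function(x, config = sweep_config(), background = NULL,
                    relevance_threshold = 1, basis = NULL) {
  stopifnot(inherits(x, "corpus"), inherits(config, "sweep_config"))
  if (nrow(x) == 0L) stop("empty corpus")
  vocab <- build_vocabulary(x, background, relevance_threshold)
  if (is.null(basis)) basis <- make_basis(config$dimension, config$p, config$seed)
  wbase <- vectorize_corpus(x, config, basis)
  wwrd <- embed_words(x, wbase, vocab)
  wtxt <- embed_documents(x, wwrd)
  structure(list(corpus = x, config = config, vocab = vocab,
                 wbase = wbase, wwrd = wwrd, wtxt = wtxt, wlog = NULL),
            class = "textmap")
}

#' Add expression vectors (Wlog) to a fitted map
#'
#' @param object A [textmap].
#' @param exprs List of `logexp` objects (or character vector of
#'   expressions).
#' @return The `textmap` with a `wlog` component.
#' @export
textmap_logexp <- function(object, exprs) {
  stopifnot(inherits(object, "textmap"))
  object$wlog <- embed_logexps(exprs, object$corpus, object$wbase)
  object
}

#' @export
print.textmap <- function(x, ...) {
  cat("Vector text-mining map\n")
  cat(sprintf("  corpus: %d documents ('%s')\n", nrow(x$corpus),
              attr(x$corpus, "label") %||% "corpus"))
  cat(sprintf("  vectorizer: mask %s, %s, p = %d, seed = %d\n",
              x$config$mask$pattern, x$config$codec, x$config$p, x$config$seed))
  cat(sprintf("  vocabulary: %d words (%d relevant)\n",
              nrow(x$vocab), sum(x$vocab$is_relevant)))
  cat(sprintf("  spaces: Wbase %d, Wwrd %d, Wtxt %d%s rows\n",
              nrow(x$wbase), nrow(x$wwrd), nrow(x$wtxt),
              if (!is.null(x$wlog)) sprintf(", Wlog %d", nrow(x$wlog)) else ""))
  invisible(x)
}

#' @export
summary.textmap <- function(object, n = 10, ...) {
  v <- object$vocab[object$vocab$is_relevant, ]
  v <- v[order(-v$doc_frequency, v$word), ]
  out <- list(n_documents = nrow(object$corpus),
              n_words = nrow(object$vocab),
              n_relevant = sum(object$vocab$is_relevant),
              p = object$config$p,
              top_words = utils::head(v[, c("word", "doc_frequency", "relevance_ratio")], n))
  class(out) <- "summary.textmap"
  out
}

#' @export
print.summary.textmap <- function(x, ...) {
  cat(sprintf("textmap: %d documents, %d words (%d relevant), p = %d\n",
              x$n_documents, x$n_words, x$n_relevant, x$p))
  cat("most widespread relevant words:\n")
  print(x$top_words, row.names = FALSE)
  invisible(x)
}

#' Semantic search in a fitted map
#'
#' `newdata` is a query: a hyphen-separated string or character vector of
#' items, each resolved as a word, then a document id, then an expression
#' label; the query vector is their mean. `type = "terms"` ranks words,
#' `"documents"` ranks documents, `"vector"` returns the query vector
#' itself.
#'
#' @param object A [textmap].
#' @param newdata Query (see above).
#' @param type `"terms"`, `"documents"` or `"vector"`.
#' @param k Number of neighbours.
#' @param metric A [metric_config] (or its name).
#' @param ... Unused.
#' @return A data frame `label`/`distance`, or a numeric vector.
#' @export
predict.textmap <- function(object, newdata, type = c("terms", "documents", "vector"),
                            k = 30, metric = metric_config("euclidean"), ...) {
  type <- match.arg(type)
  spaces <- list(object$wwrd, object$wtxt)
  if (!is.null(object$wlog)) spaces <- c(spaces, list(object$wlog))
  qv <- query_vector(newdata, spaces)
  switch(type,
         vector = qv,
         terms = knn_search(qv, object$wwrd, k = k, metric = metric),
         documents = knn_search(qv, object$wtxt, k = k, metric = metric))
}

#' Dendrogram of the most widespread relevant words
#'
#' Builds the Neighbor-Joining tree of the top `n` relevant words (by
#' document frequency) in word space and plots it.
#'
#' @param x A [textmap].
#' @param n Number of words (default 30).
#' @param metric Tree metric (default Euclidean).
#' @param root Optional word to root at.
#' @param ... Passed to `ape::plot.phylo`.
#' @return The `phylo` tree, invisibly.
#' @export
plot.textmap <- function(x, n = 30, metric = metric_config("euclidean"),
                         root = NULL, ...) {
  v <- x$vocab[x$vocab$is_relevant & x$vocab$word %in% rownames(x$wwrd), ]
  v <- v[order(-v$doc_frequency, v$word), ]
  words <- utils::head(v$word, n)
  if (length(words) < 2) stop("need at least 2 relevant embedded words")
  tr <- embedding_tree(x$wwrd[words, , drop = FALSE], metric, root = root)
  ape::plot.phylo(tr, ...)
  invisible(tr)
}
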