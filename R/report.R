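# Static HTML navigation reports: WORDS.html (one entry per relevant
# word: best hits, a dendrogram of the top related terms, the nearest
# documents, and a year-usage index) and TEXTS.html (one entry per
# document: its nearest documents). The two files cross-link through
# stable document numbers; output is dependency-free static HTML so the
# reports work offline, and regeneration is byte-identical.

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.html_head <- function(title) {
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    paste0("<title>", .html_escape(title), "</title>"),
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:60em}",
    "h2{border-bottom:1px solid #999;margin-top:2em}",
    ".hits{color:#225}.tree{font-family:monospace;font-size:85%;",
    "white-space:pre-wrap;background:#f5f5f5;padding:0.5em}",
    "table{border-collapse:collapse}td{padding:0.1em 0.6em}",
    ".years{color:#555;font-size:90%}",
    "</style></head><body>",
    paste0("<h1>", .html_escape(title), "</h1>"))
}

.year_bar <- function(counts) {
  if (!length(counts)) return("")
  paste(vapply(seq_along(counts), function(i) {
    sprintf("%s:%s", names(counts)[i], strrep("#", counts[i]))
  }, ""), collapse = " ")
}

#' Build the HTML-TM navigation files
#'
#' Writes `WORDS.html` (one anchored entry per relevant vocabulary word:
#' its `n_hits` best word hits, a Neighbor-Joining dendrogram over its
#' `n_terms` top related terms rendered as embedded Newick, its `n_docs`
#' nearest documents, and the word's year-usage index) and `TEXTS.html`
#' (one anchored entry per document with its `n_docs` nearest documents
#' and distances), plus `entries.json` with the same content for
#' programmatic use. Word trees use the fractional Lk-norm (k = 0.3);
#' hit and document rankings use `metric` (Euclidean by default). A word's
#' own entry is excluded from its hit list. Document numbering is the
#' corpus row order and is consistent across both files.
#'
#' @param x A [corpus].
#' @param vocab A [build_vocabulary()] result; entries with
#'   `is_relevant = TRUE` get a word entry.
#' @param wwrd A `Wwrd` [embedding_matrix] over (at least) the relevant
#'   words.
#' @param wtxt A `Wtxt` [embedding_matrix] over the corpus documents.
#' @param out_dir Output directory (created).
#' @param metric Ranking metric for hits and nearest documents.
#' @param tree_metric Metric for the per-word term dendrograms.
#' @param n_hits,n_terms,n_docs Entry sizes (defaults 7/30/30); trimmed to
#'   what the corpus provides.
#' @return Invisible character vector of the files written.
#' @export
build_html_tm <- function(x, vocab, wwrd, wtxt, out_dir,
                          metric = metric_config("euclidean"),
                          tree_metric = metric_config("lk_norm", 0.3),
                          n_hits = 7, n_terms = 30, n_docs = 30) {
  if (nrow(x) == 0L) stop("empty corpus")
  words <- intersect(vocab$word[vocab$is_relevant], rownames(wwrd))
  if (!length(words)) stop("no relevant vocabulary word is embedded")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  doc_ids <- rownames(wtxt)
  doc_no <- setNames(match(doc_ids, x$doc_id), doc_ids)
  doc_title <- setNames(x$title, x$doc_id)

  words_path <- file.path(out_dir, "WORDS.html")
  texts_path <- file.path(out_dir, "TEXTS.html")
  entries <- list(words = list(), texts = list())

  w_lines <- .html_head("WORDS - text-mining word index")
  w_lines <- c(w_lines, "<p>Each entry: best hits among words, the related-term dendrogram (Newick), nearest documents, and the year-usage index.</p>")
  for (w in words) {
    qv <- wwrd[w, ]
    hits <- knn_search(qv, wwrd, k = n_hits, metric = metric, exclude = w)
    terms <- knn_search(qv, wwrd, k = n_terms, metric = metric, exclude = w)
    docs <- knn_search(qv, wtxt, k = n_docs, metric = metric)
    nwk <- ""
    if (nrow(terms) >= 2) {
      sub <- wwrd[terms$label, , drop = FALSE]
      nwk <- write_newick(neighbor_joining(distance_matrix(sub, tree_metric)))
    }
    yu <- tryCatch(year_usage_index(w, x), error = function(e) NULL)
    anchor <- paste0("word-", w)
    w_lines <- c(w_lines,
      sprintf("<h2 id=\"%s\">%s</h2>", anchor, .html_escape(w)),
      "<p class=\"hits\"><b>Best hits:</b> ",
      paste(ifelse(hits$label %in% words,
                   sprintf("<a href=\"#word-%s\">%s</a>", hits$label,
                           .html_escape(hits$label)),
                   .html_escape(hits$label)), collapse = ", "),
      "</p>",
      if (nzchar(nwk)) c("<div class=\"tree\">", .html_escape(nwk), "</div>") else NULL,
      if (!is.null(yu)) {
        sprintf("<p class=\"years\">mean year %.1f | %s</p>",
                yu$mean_year, .html_escape(.year_bar(yu$per_year_counts)))
      } else NULL,
      "<table>",
      vapply(seq_len(nrow(docs)), function(i) {
        id <- docs$label[i]
        sprintf("<tr><td><a href=\"TEXTS.html#doc-%d\">[%d]</a></td><td>%s</td><td>%.4g</td></tr>",
                doc_no[[id]], doc_no[[id]], .html_escape(doc_title[[id]]), docs$distance[i])
      }, ""),
      "</table>")
    entries$words[[w]] <- list(
      word = w, best_hits = hits$label,
      related_terms_newick = nwk, related_terms = terms$label,
      nearest_docs = data.frame(doc_no = unname(doc_no[docs$label]),
                                doc_id = docs$label,
                                distance = docs$distance),
      year_usage = if (is.null(yu)) NULL else
        list(mean_year = yu$mean_year,
             per_year_counts = as.list(yu$per_year_counts))
    )
  }
  w_lines <- c(w_lines, "</body></html>")
  writeLines(w_lines, words_path, useBytes = TRUE)

  t_lines <- .html_head("TEXTS - similar-article index")
  for (id in doc_ids) {
    near <- knn_search(wtxt[id, ], wtxt, k = n_docs, metric = metric, exclude = id)
    anchor <- sprintf("doc-%d", doc_no[[id]])
    t_lines <- c(t_lines,
      sprintf("<h2 id=\"%s\">[%d] %s</h2>", anchor, doc_no[[id]],
              .html_escape(doc_title[[id]])),
      "<table>",
      vapply(seq_len(nrow(near)), function(i) {
        nid <- near$label[i]
        sprintf("<tr><td><a href=\"#doc-%d\">[%d]</a></td><td>%s</td><td>%.4g</td></tr>",
                doc_no[[nid]], doc_no[[nid]], .html_escape(doc_title[[nid]]),
                near$distance[i])
      }, ""),
      "</table>")
    entries$texts[[id]] <- list(
      doc_id = id, doc_no = unname(doc_no[[id]]), title = unname(doc_title[[id]]),
      nearest_docs = data.frame(doc_no = unname(doc_no[near$label]),
                                doc_id = near$label,
                                distance = near$distance)
    )
  }
  t_lines <- c(t_lines, "</body></html>")
  writeLines(t_lines, texts_path, useBytes = TRUE)

  json_path <- file.path(out_dir, "entries.json")
  jsonlite::write_json(entries, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(words_path, texts_path, json_path))
}
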