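# LOGEXP: the boolean substring query language. Operators: '|' (or),
# '&' (and), '~' (not), '(' ')' and '{' '}' (grouping), '_' (explicit
# space inside a pattern). Literals are exact substring patterns matched
# case-insensitively against normalized text padded with one leading and
# trailing space (so word-initial patterns like '_CARDI' can match at the
# start of the text). Precedence: NOT > AND > OR, left-associative.

.lx_ops <- c("&", "|", "~", "(", ")", "{", "}")

.lx_tokenize <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list()
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 %in% .lx_ops) {
      toks[[length(toks) + 1L]] <- list(type = c0, pos = i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(ch[j] %in% .lx_ops)) j <- j + 1L
      lit <- paste0(ch[i:(j - 1L)], collapse = "")
      if (nzchar(trimws(lit))) {
        toks[[length(toks) + 1L]] <- list(type = "LIT", value = trimws(lit), pos = i)
      }
      i <- j
    }
  }
  toks
}

#' Parse a logical substring expression
#'
#' @param text Expression string, e.g. `"{CHRONIC | ACUTE} & CONDITIONS"`.
#' @param label Identifier carried through matching and vectorization.
#' @return An object of class `logexp` with fields `ast`, `source`,
#'   `label`. Parse failures report the character offset.
#' @examples
#' parse_logexp("_CARDI & VASCUL")
#' @export
parse_logexp <- function(text, label = text) {
  if (!nzchar(trimws(text))) stop("empty expression")
  toks <- .lx_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg, at) {
    stop("parse error at offset ", at, " in '", text, "': ", msg, call. = FALSE)
  }
  parse_or <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek()$type == "|") {
      op <- advance()
      left <- list(type = "or", left = left, right = parse_and())
    }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (!is.null(peek()) && peek()$type == "&") {
      op <- advance()
      left <- list(type = "and", left = left, right = parse_not())
    }
    left
  }
  parse_not <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "~") {
      advance()
      return(list(type = "not", child = parse_not()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of expression", nchar(text))
    if (t$type == "LIT") {
      advance()
      return(list(type = "literal", pattern = t$value))
    }
    if (t$type %in% c("(", "{")) {
      open <- advance()
      inner <- parse_or()
      t2 <- peek()
      closer <- if (open$type == "(") ")" else "}"
      if (is.null(t2) || t2$type != closer) {
        fail(paste0("unbalanced group opened with '", open$type, "'"),
             if (is.null(t2)) nchar(text) else t2$pos)
      }
      advance()
      return(inner)
    }
    fail(paste0("expected a pattern or group, found '", t$type, "'"), t$pos)
  }
  ast <- parse_or()
  t <- peek()
  if (!is.null(t)) fail(paste0("unexpected '", t$type, "'"), t$pos)
  structure(list(ast = ast, source = text, label = label), class = "logexp")
}

.lx_prec <- function(node) switch(node$type, or = 1L, and = 2L, not = 3L, literal = 4L)

.lx_deparse <- function(node, need = 1L) {
  p <- .lx_prec(node)
  s <- switch(node$type,
    literal = node$pattern,
    not = paste0("~", .lx_deparse(node$child, 3L)),
    and = paste0(.lx_deparse(node$left, 2L), " & ", .lx_deparse(node$right, 3L)),
    or  = paste0(.lx_deparse(node$left, 1L), " | ", .lx_deparse(node$right, 2L))
  )
  if (p < need) paste0("{", s, "}") else s
}

#' @export
format.logexp <- function(x, ...) .lx_deparse(x$ast)

#' @export
print.logexp <- function(x, ...) {
  cat(sprintf("<logexp %s: %s>\n", x$label, format(x)))
  invisible(x)
}

.lx_eval <- function(node, padded) {
  switch(node$type,
    literal = {
      pat <- gsub("_", " ", toupper(node$pattern), fixed = TRUE)
      grepl(pat, padded, fixed = TRUE)
    },
    not = !.lx_eval(node$child, padded),
    and = .lx_eval(node$left, padded) & .lx_eval(node$right, padded),
    or  = .lx_eval(node$left, padded) | .lx_eval(node$right, padded)
  )
}

#' Evaluate an expression against text
#'
#' A literal is true iff its pattern (with `_` read as a space) occurs as a
#' substring of the normalized text padded with one leading and trailing
#' space; AND/OR/NOT have the usual boolean semantics.
#'
#' @param expr A [parse_logexp()] result (or expression string).
#' @param text Character vector of texts (normalized internally).
#' @return Logical vector, one value per text.
#' @export
evaluate_logexp <- function(expr, text) {
  if (is.character(expr)) expr <- parse_logexp(expr)
  padded <- paste0(" ", normalize_text(text), " ")
  .lx_eval(expr$ast, padded)
}

#' Match an expression against a corpus
#'
#' Evaluates the expression on the full text (title + abstract) and on the
#' title field of every document; `n_docs` counts full-text matches and
#' `n_titles` title matches. `matched_doc_ids` holds the ids for the
#' requested `field`.
#'
#' @param expr A `logexp` (or string).
#' @param x A [corpus].
#' @param field Which match set to return ids for: `"text"` or `"title"`.
#' @return A list of class `logexp_match`: `label`, `matched_doc_ids`,
#'   `n_docs`, `n_titles`.
#' @export
match_corpus <- function(expr, x, field = c("text", "title")) {
  field <- match.arg(field)
  if (is.character(expr)) expr <- parse_logexp(expr)
  hit_text <- evaluate_logexp(expr, corpus_text(x))
  hit_title <- evaluate_logexp(expr, normalize_text(x$title))
  ids <- x$doc_id[if (field == "text") hit_text else hit_title]
  structure(list(label = expr$label, matched_doc_ids = ids,
                 n_docs = sum(hit_text), n_titles = sum(hit_title)),
            class = "logexp_match")
}

#' @export
print.logexp_match <- function(x, ...) {
  cat(sprintf("<logexp %s: %d documents, %d titles>\n", x$label, x$n_docs, x$n_titles))
  invisible(x)
}

#' Vectorize an expression in the document base space (Wlog row)
#'
#' Same averaging rule as for words, with the match set replacing the
#' containing-document set: the arithmetic mean of the base vectors of the
#' documents whose full text satisfies the expression.
#'
#' @param expr A `logexp` (or string).
#' @param x A [corpus].
#' @param wbase The `Wbase` [embedding_matrix].
#' @return Numeric vector of length `ncol(wbase)`; error on zero matches.
#' @export
vectorize_logexp <- function(expr, x, wbase) {
  if (is.character(expr)) expr <- parse_logexp(expr)
  m <- match_corpus(expr, x, field = "text")
  if (!length(m$matched_doc_ids)) {
    stop("expression matches no document: ", expr$label)
  }
  colMeans(wbase[m$matched_doc_ids, , drop = FALSE])
}

#' Embed a list of expressions (Wlog)
#'
#' @param exprs List of `logexp` objects (or character vector).
#' @inheritParams vectorize_logexp
#' @return A `Wlog` [embedding_matrix], rows labelled by expression label.
#' @export
embed_logexps <- function(exprs, x, wbase) {
  if (is.character(exprs)) exprs <- lapply(exprs, parse_logexp)
  W <- t(vapply(exprs, vectorize_logexp, numeric(ncol(wbase)), x = x, wbase = wbase))
  rownames(W) <- vapply(exprs, function(e) e$label, "")
  embedding_matrix(W, "Wlog", config = attr(wbase, "config"))
}

#' Union coverage of an expression set
#'
#' Fraction of the corpus recovered by the union of all full-text matches,
#' and of titles recovered by the union of all title matches, in percent.
#'
#' @param exprs List of `logexp` objects (or character vector).
#' @param x A [corpus] (non-empty).
#' @return List with `doc_recall` and `title_recall` (percent), and the
#'   underlying counts `n_docs_matched`, `n_titles_matched`, `n_corpus`.
#' @export
coverage_report <- function(exprs, x) {
  if (nrow(x) == 0L) stop("empty corpus")
  if (is.character(exprs)) exprs <- lapply(exprs, parse_logexp)
  if (!length(exprs)) stop("need at least one expression")
  texts <- paste0(" ", corpus_text(x), " ")
  titles <- paste0(" ", normalize_text(x$title), " ")
  hit_text <- rep(FALSE, nrow(x))
  hit_title <- rep(FALSE, nrow(x))
  for (e in exprs) {
    hit_text <- hit_text | .lx_eval(e$ast, texts)
    hit_title <- hit_title | .lx_eval(e$ast, titles)
  }
  list(doc_recall = 100 * sum(hit_text) / nrow(x),
       title_recall = 100 * sum(hit_title) / nrow(x),
       n_docs_matched = sum(hit_text),
       n_titles_matched = sum(hit_title),
       n_corpus = nrow(x))
}

#' Read/write an expression file
#'
#' Tab-separated, two columns (label, expression), one expression per line,
#' with header.
#'
#' @param path File path.
#' @return `read_logexp()` returns a list of `logexp` objects.
#' @export
read_logexp <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  mapply(function(lab, ex) parse_logexp(ex, label = lab),
         as.character(df[[1]]), as.character(df[[2]]),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_logexp
#' @param exprs List of `logexp` objects.
#' @export
write_logexp <- function(exprs, path) {
  utils::write.table(
    data.frame(label = vapply(exprs, function(e) e$label, ""),
               expression = vapply(exprs, function(e) e$source, "")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
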