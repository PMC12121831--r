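# Corpus construction: PubMed-style record ingestion, the title/abstract
# filter funnel, tokenization, and the relevance-filtered vocabulary.

#' Construct a corpus
#'
#' A corpus is a data frame with columns `doc_id`, `year`, `title`,
#' `abstract` (one document per row, insertion order preserved) and a
#' `label` attribute naming the collection.
#'
#' @param doc_id Character vector of unique document ids.
#' @param title,abstract Character vectors.
#' @param year Integer vector of publication years (NA allowed).
#' @param label Collection label, e.g. `"TextDoc"`.
#' @return An object of class `corpus`.
#' @export
corpus <- function(doc_id, title, abstract, year = NA_integer_, label = "corpus") {
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) stop("duplicate doc_id in corpus")
  x <- data.frame(
    doc_id = doc_id,
    year = suppressWarnings(as.integer(year)),
    title = as.character(title),
    abstract = as.character(abstract),
    stringsAsFactors = FALSE
  )
  structure(x, class = c("corpus", "data.frame"), label = label)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus '%s': %d documents>\n", attr(x, "label") %||% "corpus", nrow(x)))
  if (nrow(x)) {
    yy <- x$year[!is.na(x$year)]
    if (length(yy)) cat(sprintf("  years %d-%d; ", min(yy), max(yy)))
    cat(sprintf("median text length %d characters\n",
                as.integer(stats::median(nchar(corpus_text(x))))))
    print(utils::head(data.frame(doc_id = x$doc_id, year = x$year,
                                 title = substr(x$title, 1, 50)), 5))
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Normalized full text of each document
#'
#' The working text of a document is its title concatenated with its
#' abstract (single space between), normalized.
#'
#' @param x A `corpus`.
#' @return Character vector, one normalized text per document.
#' @export
corpus_text <- function(x) {
  normalize_text(paste(x$title, x$abstract))
}

# -- readers -----------------------------------------------------------------

.parse_medline <- function(lines) {
  # MEDLINE flat format: "TAG - value", continuation lines indented;
  # blank line separates records.
  recs <- list()
  cur <- list()
  tag <- NULL
  flush <- function(cur) if (length(cur)) recs[[length(recs) + 1L]] <<- cur
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      flush(cur); cur <- list(); tag <- NULL
      next
    }
    if (grepl("^[A-Z]{1,4} *- ", ln)) {
      tag <- trimws(sub(" *-.*$", "", ln))
      val <- sub("^[A-Z]{1,4} *- ", "", ln)
      cur[[tag]] <- c(cur[[tag]], val)
    } else if (grepl("^ +", ln) && !is.null(tag)) {
      n <- length(cur[[tag]])
      cur[[tag]][n] <- paste(cur[[tag]][n], trimws(ln))
    }
  }
  recs
}

.year_from_date <- function(x) {
  vapply(x, function(s) {
    m <- regmatches(s, regexpr("(19|20)[0-9]{2}", s))
    if (length(m)) as.integer(m) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Read PubMed-style records into a corpus
#'
#' Supported formats: `"medline"` (flat PMID/TI/AB/DP tagged records with
#' continuation lines), `"csv"` (columns pmid, title, abstract, year), and
#' `"tsv"` (the corpus serialization written by [write_corpus()]:
#' doc_id, year, title, abstract). `col_map` renames columns of a csv/tsv
#' with a different header (e.g. a deposited document table) to the
#' expected names: a named character vector `c(pmid = "...", title = "...",
#' abstract = "...", year = "...")`.
#'
#' Records lacking an id are assigned synthetic ids; a missing or
#' unparseable date yields `NA` year.
#'
#' @param path Input file.
#' @param format `"medline"`, `"csv"` or `"tsv"`.
#' @param col_map Optional column mapping for csv/tsv input.
#' @param label Corpus label.
#' @return A [corpus].
#' @export
read_corpus <- function(path, format = c("medline", "csv", "tsv"),
                        col_map = NULL, label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  if (format == "medline") {
    recs <- .parse_medline(readLines(path, encoding = "UTF-8", warn = FALSE))
    if (!length(recs)) {
      return(corpus(character(0), character(0), character(0), integer(0), label))
    }
    get1 <- function(r, tag) if (is.null(r[[tag]])) "" else paste(r[[tag]], collapse = " ")
    ids <- vapply(recs, get1, "", "PMID")
    miss <- !nzchar(ids)
    ids[miss] <- sprintf("DOC%05d", which(miss))
    dp <- vapply(recs, get1, "", "DP")
    yr <- ifelse(nzchar(dp), .year_from_date(dp), NA_integer_)
    return(corpus(ids,
                  vapply(recs, get1, "", "TI"),
                  vapply(recs, get1, "", "AB"),
                  yr, label))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        stop("col_map column not present in file: ", col_map[[std]])
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  names(df) <- tolower(names(df))
  if ("doc_id" %in% names(df) && !"pmid" %in% names(df)) names(df)[names(df) == "doc_id"] <- "pmid"
  need <- c("title", "abstract")
  if (!all(need %in% names(df))) {
    stop("corpus file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  n <- nrow(df)
  ids <- if ("pmid" %in% names(df)) as.character(df$pmid) else character(n)
  if (!length(ids)) ids <- rep("", n)
  miss <- is.na(ids) | !nzchar(ids)
  ids[miss] <- sprintf("DOC%05d", which(miss))
  yr <- if ("year" %in% names(df)) suppressWarnings(as.integer(df$year)) else rep(NA_integer_, n)
  corpus(ids, df$title, df$abstract, yr, label)
}

#' Write a corpus as TSV
#'
#' Fixed column order: doc_id, year, title, abstract.
#'
#' @param x A [corpus].
#' @param path Output file.
#' @export
write_corpus <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("doc_id", "year", "title", "abstract")],
                     path, sep = "\t", quote = TRUE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# -- filtering ---------------------------------------------------------------

#' Filter a corpus by the title/abstract funnel
#'
#' Applies, in order: removal of documents with an empty title or abstract;
#' removal of documents whose normalized title-plus-abstract is shorter than
#' `min_chars` characters; removal of later duplicates of an identical
#' normalized title (first occurrence kept); and, when `title_only = TRUE`,
#' removal of documents whose normalized title does not contain
#' `focus_term` as a substring (case-insensitive).
#'
#' @param x A [corpus].
#' @param focus_term Non-empty focus term (e.g. `"YOGA"`); used when
#'   `title_only = TRUE`.
#' @param title_only Keep only documents with the focus term in the title.
#' @param min_chars Minimum character count of the normalized
#'   title + space + abstract (default 300).
#' @param label Label for the filtered corpus.
#' @return A list with elements `corpus` (the filtered [corpus]) and
#'   `report` (a `filter_report` accounting for every removal).
#' @export
filter_corpus <- function(x, focus_term, title_only = FALSE, min_chars = 300,
                          label = if (title_only) "TextDoc" else "TextDocAll") {
  if (missing(focus_term) || !nzchar(focus_term)) stop("focus_term must be non-empty")
  n_in <- nrow(x)
  keep <- rep(TRUE, n_in)
  norm_title <- normalize_text(x$title)
  norm_text <- corpus_text(x)

  empty <- !nzchar(trimws(x$title)) | !nzchar(trimws(x$abstract))
  n_empty <- sum(empty & keep)
  keep <- keep & !empty

  short <- nchar(norm_text) < min_chars
  n_short <- sum(short & keep)
  keep <- keep & !short

  dup <- duplicated(norm_title) & keep
  # only count duplicates among surviving docs: first surviving occurrence kept
  surv_idx <- which(keep)
  dup_surv <- surv_idx[duplicated(norm_title[surv_idx])]
  n_dup <- length(dup_surv)
  keep[dup_surv] <- FALSE

  n_focus <- 0L
  if (title_only) {
    has_term <- grepl(normalize_text(focus_term), norm_title, fixed = TRUE)
    n_focus <- sum(keep & !has_term)
    keep <- keep & has_term
  }

  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("corpus", "data.frame")
  report <- structure(list(
    n_input = n_in,
    removed_empty_fields = n_empty,
    removed_short = n_short,
    removed_duplicate_title = n_dup,
    removed_no_focus_in_title = n_focus,
    n_output = nrow(out),
    min_chars = min_chars,
    focus_term = focus_term,
    title_only = title_only
  ), class = "filter_report")
  stopifnot(report$n_input == report$n_output + n_empty + n_short + n_dup + n_focus)
  list(corpus = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Corpus filter funnel\n")
  cat(sprintf("  input records              %6d\n", x$n_input))
  cat(sprintf("  - empty title/abstract     %6d\n", x$removed_empty_fields))
  cat(sprintf("  - shorter than %d chars   %6d\n", x$min_chars, x$removed_short))
  cat(sprintf("  - duplicate title          %6d\n", x$removed_duplicate_title))
  if (x$title_only) {
    cat(sprintf("  - '%s' not in title      %6d\n", x$focus_term, x$removed_no_focus_in_title))
  }
  cat(sprintf("  surviving documents        %6d\n", x$n_output))
  invisible(x)
}

# -- tokenization and vocabulary --------------------------------------------

#' Tokenize text
#'
#' Tokens are the maximal alphabetic runs of the normalized text,
#' uppercased, of length >= `min_len`; order and duplicates preserved.
#' No stemming and no stop list: downstream relevance filtering against a
#' background frequency table demotes function words.
#'
#' @param text A single character string (raw; normalized internally).
#' @param min_len Minimum token length (default 3).
#' @return Character vector of tokens.
#' @examples
#' tokenize("Yoga-based practice!")  # "YOGA" "BASED" "PRACTICE"
#' @export
tokenize <- function(text, min_len = 3L) {
  stopifnot(length(text) == 1L)
  s <- normalize_text(text)
  if (!nzchar(s)) return(character(0))
  toks <- regmatches(s, gregexpr("[A-Z]+", s))[[1]]
  toks[nchar(toks) >= min_len]
}

# tokens of every document; set = TRUE drops within-document duplicates
.corpus_tokens <- function(x, set = FALSE, min_len = 3L) {
  txt <- corpus_text(x)
  out <- lapply(txt, function(s) {
    toks <- regmatches(s, gregexpr("[A-Z]+", s))[[1]]
    toks <- toks[nchar(toks) >= min_len]
    if (set) unique(toks) else toks
  })
  names(out) <- x$doc_id
  out
}

#' Build the corpus vocabulary with relevance flags
#'
#' One entry per distinct token across the corpus, with its document
#' frequency, corpus relative frequency (token occurrences over all token
#' occurrences), background relative frequency from `background`, and the
#' relevance ratio corpus/background. Words whose ratio is at least
#' `relevance_threshold` form the relevant-word set (WRD). Words absent
#' from the background table are assigned the minimum background frequency
#' present, which makes rare domain terms maximally relevant.
#'
#' @param x A [corpus] (non-empty).
#' @param background Named numeric vector mapping words to frequencies
#'   (counts or relative; normalized internally). `NULL` marks every word
#'   relevant.
#' @param relevance_threshold Ratio cutoff (default 1: more frequent in the
#'   corpus than in general usage).
#' @return A data frame of class `vocabulary`, sorted by word, with columns
#'   word, doc_frequency, corpus_rel_freq, background_rel_freq,
#'   relevance_ratio, is_relevant.
#' @export
build_vocabulary <- function(x, background = NULL, relevance_threshold = 1) {
  if (nrow(x) == 0L) stop("empty corpus")
  if (!is.null(background) && length(background) == 0L) {
    stop("background table is empty")
  }
  toks <- .corpus_tokens(x, set = FALSE)
  all_tok <- unlist(toks, use.names = FALSE)
  tf <- table(all_tok)
  df_count <- table(unlist(lapply(toks, unique), use.names = FALSE))
  words <- sort(names(tf))
  n_tok <- length(all_tok)
  corpus_rel <- as.numeric(tf[words]) / n_tok
  if (is.null(background)) {
    bg <- rep(NA_real_, length(words))
    ratio <- rep(NA_real_, length(words))
    rel <- rep(TRUE, length(words))
  } else {
    names(background) <- toupper(names(background))
    background <- background / sum(background)
    bg <- unname(background[words])
    bg[is.na(bg)] <- min(background)
    ratio <- corpus_rel / bg
    rel <- ratio >= relevance_threshold
  }
  structure(data.frame(
    word = words,
    doc_frequency = as.integer(df_count[words]),
    corpus_rel_freq = corpus_rel,
    background_rel_freq = bg,
    relevance_ratio = ratio,
    is_relevant = rel,
    stringsAsFactors = FALSE,
    row.names = NULL
  ), class = c("vocabulary", "data.frame"))
}

#' Read/write a background word-frequency table
#'
#' Two-column TSV (word, frequency), header included.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_background_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), toupper(as.character(df[[1]])))
}

#' @rdname read_background_table
#' @param background Named numeric vector.
#' @export
write_background_table <- function(background, path) {
  utils::write.table(data.frame(word = names(background), frequency = unname(background)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Year-usage index of a word
#'
#' Mean publication year over the documents containing the word, plus the
#' per-year document counts. Documents without a parsed year are excluded;
#' it is an error if the word occurs only in year-less documents or not at
#' all.
#'
#' @param word Token (uppercased internally).
#' @param x A [corpus].
#' @return List with `mean_year` (numeric) and `per_year_counts` (named
#'   integer vector, names are years).
#' @export
year_usage_index <- function(word, x) {
  word <- toupper(word)
  toks <- .corpus_tokens(x, set = TRUE)
  hit <- vapply(toks, function(t) word %in% t, logical(1))
  if (!any(hit)) stop("word not found in corpus: ", word)
  yrs <- x$year[hit]
  yrs <- yrs[!is.na(yrs)]
  if (!length(yrs)) stop("word occurs only in documents without a year: ", word)
  counts <- table(yrs)
  list(mean_year = mean(yrs),
       per_year_counts = setNames(as.integer(counts), names(counts)))
}
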