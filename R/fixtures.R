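# Synthetic corpora with planted topic structure. Each document draws its
# tokens from a topic-specific vocabulary (with probability `topic_mix`)
# or from a shared pool of background words and stop words; every title
# carries the shared focus term plus its topic's keyword, so corpus
# filtering, relevance ranking, embedding, expression matching and
# reporting can all be exercised end to end without any download.

.fixture_stopwords <- c("THE", "AND", "WITH", "FROM", "THIS", "THAT", "WERE",
                        "HAVE", "STUDY", "RESULTS", "AMONG", "AFTER")

# pronounceable pseudo-words (alternating consonant/vowel), lengths 4-10;
# exercises the codecs' full alphabetic path
.make_tokens <- function(n, avoid = character(0)) {
  cons <- strsplit("BCDFGHJKLMNPRSTVZ", "")[[1]]
  vow <- strsplit("AEIOU", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    len <- sample(4:10, 1)
    ch <- character(len)
    for (i in seq_len(len)) {
      ch[i] <- if (i %% 2 == 1) sample(cons, 1) else sample(vow, 1)
    }
    w <- paste0(ch, collapse = "")
    if (!(w %in% out) && !(w %in% avoid)) out <- c(out, w)
  }
  out
}

#' Specification of a synthetic corpus
#'
#' @param n_topics Number of planted topics.
#' @param docs_per_topic Documents per topic.
#' @param topic_vocab_size Topic-specific vocabulary size per topic.
#' @param shared_vocab_size Size of the shared (cross-topic) vocabulary.
#' @param doc_length_mean,doc_length_sd Abstract length distribution, in
#'   tokens.
#' @param topic_mix Probability that an abstract token is drawn from the
#'   document's topic vocabulary rather than the shared pool.
#' @param years Candidate publication years (uniform).
#' @param focus_term Term planted in every title (plays the role the
#'   search term plays in a literature corpus).
#' @param seed Integer seed; generation is fully determined by it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_topics = 3, docs_per_topic = 30,
                           topic_vocab_size = 40, shared_vocab_size = 60,
                           doc_length_mean = 60, doc_length_sd = 10,
                           topic_mix = 0.8, years = 1970:2022,
                           focus_term = "YOGA", seed = 1) {
  stopifnot(n_topics >= 1, docs_per_topic >= 1, topic_vocab_size >= 1,
            shared_vocab_size >= 1, topic_mix >= 0, topic_mix <= 1,
            doc_length_mean >= 1)
  structure(list(n_topics = n_topics, docs_per_topic = docs_per_topic,
                 topic_vocab_size = topic_vocab_size,
                 shared_vocab_size = shared_vocab_size,
                 doc_length_mean = doc_length_mean,
                 doc_length_sd = doc_length_sd,
                 topic_mix = topic_mix, years = years,
                 focus_term = toupper(focus_term), seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic corpus with planted topics
#'
#' Returns the corpus, the ground truth (document-to-topic assignment,
#' per-topic title keywords and defining vocabularies), and a co-generated
#' background word-frequency table in which the stop words are frequent
#' and all planted vocabulary is rare, so relevance filtering can be
#' tested without an external frequency list. Abstracts are padded with
#' additional sampled tokens until the title-plus-abstract passes the
#' 300-character filter.
#'
#' @param spec A [synthetic_spec].
#' @return List with elements `corpus` (a [corpus]), `truth` (list:
#'   `topics` data frame doc_id/topic, `keywords`, `topic_vocab`), and
#'   `background` (named numeric vector).
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    keywords <- .make_tokens(spec$n_topics, avoid = c(.fixture_stopwords, spec$focus_term))
    shared <- .make_tokens(spec$shared_vocab_size,
                           avoid = c(keywords, .fixture_stopwords, spec$focus_term))
    topic_vocab <- list()
    used <- c(keywords, shared, .fixture_stopwords, spec$focus_term)
    for (t in seq_len(spec$n_topics)) {
      topic_vocab[[t]] <- .make_tokens(spec$topic_vocab_size, avoid = used)
      used <- c(used, topic_vocab[[t]])
    }
    names(topic_vocab) <- keywords
    shared_pool <- c(shared, .fixture_stopwords)

    n <- spec$n_topics * spec$docs_per_topic
    if (length(shared_pool) < 5 || spec$topic_vocab_size < 2) {
      stop("vocabulary too small for the requested document lengths")
    }
    doc_id <- sprintf("SYN%05d", seq_len(n))
    topic <- rep(seq_len(spec$n_topics), each = spec$docs_per_topic)
    title <- character(n)
    abstract <- character(n)
    year <- sample(spec$years, n, replace = TRUE)
    for (i in seq_len(n)) {
      tv <- topic_vocab[[topic[i]]]
      title[i] <- paste(spec$focus_term, keywords[topic[i]],
                        paste(sample(tv, 2), collapse = " "))
      len <- max(30L, round(rnorm(1, spec$doc_length_mean, spec$doc_length_sd)))
      draw <- function(m) {
        from_topic <- runif(m) < spec$topic_mix
        ifelse(from_topic, sample(tv, m, replace = TRUE),
               sample(shared_pool, m, replace = TRUE))
      }
      toks <- draw(len)
      # pad until the normalized title + abstract clears the length filter
      while (nchar(title[i]) + 1 + nchar(paste(toks, collapse = " ")) < 320) {
        toks <- c(toks, draw(10))
      }
      # sentence-ish punctuation every ~12 tokens
      brk <- seq(12, length(toks), by = 12)
      toks[brk] <- paste0(toks[brk], ".")
      abstract[i] <- paste(toks, collapse = " ")
    }
    background <- c(
      setNames(runif(length(.fixture_stopwords), 0.005, 0.05), .fixture_stopwords),
      setNames(rep(1e-6, length(shared)), shared),
      setNames(rep(1e-7, length(unlist(topic_vocab)) + length(keywords) + 1),
               c(unlist(topic_vocab, use.names = FALSE), keywords, spec$focus_term))
    )
    list(
      corpus = corpus(doc_id, title, abstract, year, label = "synthetic"),
      truth = list(
        topics = data.frame(doc_id = doc_id, topic = topic, stringsAsFactors = FALSE),
        keywords = keywords,
        topic_vocab = topic_vocab
      ),
      background = background
    )
  })
}
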