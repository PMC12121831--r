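# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (explicit loops, substring scans) so they share no
# code path with the implementation they check.

# a tiny handcrafted corpus
tiny_corpus <- function() {
  corpus(
    doc_id = c("D1", "D2", "D3"),
    title = c("Yoga and health outcomes",
              "Breathing practice in asthma",
              "Yoga for chronic pain"),
    abstract = c("Health benefits of yoga practice in adults.",
                 "Breathing exercises improve asthma symptoms and health.",
                 "Chronic pain patients practice yoga for relief."),
    year = c(2010L, 2015L, 2020L),
    label = "tiny"
  )
}

# one small fitted map, shared (and memoized) across test files
.cache <- new.env(parent = emptyenv())
fixture_fit <- function() {
  if (is.null(.cache$fit)) {
    fx <- generate_corpus(synthetic_spec(n_topics = 3, docs_per_topic = 10,
                                         doc_length_mean = 40, seed = 7))
    cfg <- sweep_config(mask = "101", codec = "dnabits", p = 12, seed = 3)
    .cache$fit <- list(fx = fx,
                       tm = textmap(fx$corpus, cfg, background = fx$background))
  }
  .cache$fit
}

# naive O(n * span) spaced-word indexer returning a word -> count map
oracle_spaced_words <- function(seq, pattern, alphabet, binary = FALSE) {
  bits <- as.integer(strsplit(pattern, "")[[1]])
  span <- length(bits)
  care <- which(bits == 1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  if (length(ch) >= span) {
    for (s in seq_len(length(ch) - span + 1L)) {
      w <- paste0(ch[s + care - 1L], collapse = "")
      out[[w]] <- if (binary) 1 else (out[[w]] %||% 0) + 1
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# hd_vector -> named count vector, for comparison with the oracle
hd_as_map <- function(v) setNames(as.list(v$x), hd_words(v))

# loop-based Eq. 1 oracle: mean base vector over containing documents
oracle_word_embedding <- function(word, x, wbase) {
  acc <- numeric(ncol(wbase))
  n <- 0L
  for (i in seq_len(nrow(x))) {
    toks <- tokenize(paste(x$title[i], x$abstract[i]))
    if (word %in% toks) {
      acc <- acc + wbase[x$doc_id[i], ]
      n <- n + 1L
    }
  }
  stopifnot(n > 0L)
  acc / n
}

# loop-based Eq. 2 oracle: mean word vector over distinct contained words
oracle_document_embedding <- function(i, x, wwrd) {
  toks <- unique(tokenize(paste(x$title[i], x$abstract[i])))
  toks <- toks[toks %in% rownames(wwrd)]
  stopifnot(length(toks) > 0L)
  acc <- numeric(ncol(wwrd))
  for (w in toks) acc <- acc + wwrd[w, ]
  acc / length(toks)
}

# truth-table oracle for expression evaluation: computes each literal's
# truth by direct substring scan, then folds the tree bottom-up
oracle_eval <- function(node, text) {
  padded <- paste0(" ", normalize_text(text), " ")
  lit_true <- function(pat) {
    pat <- gsub("_", " ", toupper(pat), fixed = TRUE)
    n <- nchar(pat)
    any(vapply(seq_len(max(0L, nchar(padded) - n + 1L)),
               function(s) substr(padded, s, s + n - 1L) == pat, logical(1)))
  }
  fold <- function(nd) {
    switch(nd$type,
           literal = lit_true(nd$pattern),
           not = !fold(nd$child),
           and = fold(nd$left) && fold(nd$right),
           or = fold(nd$left) || fold(nd$right))
  }
  fold(node)
}

# random expression AST over a word alphabet (for property tests)
random_ast <- function(depth, words) {
  if (depth == 0L || runif(1) < 0.35) {
    return(list(type = "literal", pattern = sample(words, 1)))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") {
    list(type = "not", child = random_ast(depth - 1L, words))
  } else {
    list(type = op, left = random_ast(depth - 1L, words),
         right = random_ast(depth - 1L, words))
  }
}
as_logexp <- function(ast) structure(list(ast = ast, source = "", label = "R"),
                                     class = "logexp")

# brute-force full-sort k-NN oracle
oracle_knn <- function(query, m, k, metric = metric_config("euclidean")) {
  d <- vapply(seq_len(nrow(m)), function(i) {
    pairwise_distance(query, m[i, ], metric)
  }, numeric(1))
  ord <- order(d, rownames(m))
  head(data.frame(label = rownames(m)[ord], distance = d[ord],
                  stringsAsFactors = FALSE), k)
}

# random normalized string over the full character inventory
random_normalized <- function(len) {
  inv <- text_inventory()
  normalize_text(paste0(sample(inv, len, replace = TRUE), collapse = ""))
}

# the worked-example passage for boolean expression semantics
example_passage <- paste(
  "yoga as a therapeutic intervention for adults with acute and chronic",
  "health conditions. Objectives: overview of the quality, direction, and",
  "characteristics of yoga interventions for the treatment of acute and",
  "chronic health conditions in adult populations.")
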