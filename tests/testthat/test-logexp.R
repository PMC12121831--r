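# Parsing, evaluation, matching, vectorization and coverage of the
# boolean substring query language.

test_that("parsing builds the expected trees", {
  e <- parse_logexp("_CARDI & VASCUL")
  expect_equal(e$ast$type, "and")
  expect_equal(e$ast$left, list(type = "literal", pattern = "_CARDI"))
  expect_equal(e$ast$right, list(type = "literal", pattern = "VASCUL"))

  e2 <- parse_logexp("{CHRONIC | ACUTE} & CONDITIONS")
  expect_equal(e2$ast$type, "and")
  expect_equal(e2$ast$left$type, "or")
  expect_equal(e2$ast$left$left$pattern, "CHRONIC")
  expect_equal(e2$ast$right$pattern, "CONDITIONS")

  # precedence: NOT > AND > OR, left-associative chains nest left
  e3 <- parse_logexp("A | B & ~C | D")
  expect_equal(e3$ast$type, "or")
  expect_equal(e3$ast$left$type, "or")
  expect_equal(e3$ast$left$right$type, "and")
  expect_equal(e3$ast$left$right$right$type, "not")
})

test_that("malformed expressions fail with a character offset", {
  expect_error(parse_logexp("A & & B"), "offset 5")
  expect_error(parse_logexp("{A | B"), "unbalanced")
  expect_error(parse_logexp("(A | B}"), "unbalanced")
  expect_error(parse_logexp("A |"), "unexpected end")
  expect_error(parse_logexp("   "), "empty")
  expect_error(parse_logexp("~"), "unexpected end")
})

test_that("serialization round-trips the tree", {
  set.seed(51)
  words <- c("ALPHA", "BETA", "GAMMA", "DELTA", "KAPPA")
  for (i in 1:200) {
    ast <- random_ast(sample(0:4, 1), words)
    s <- format(as_logexp(ast))
    expect_equal(parse_logexp(s)$ast, ast, label = s)
  }
})

test_that("the worked boolean examples on the therapy passage all reproduce", {
  txt <- example_passage
  expect_true(evaluate_logexp("YOGA & HEALTH", txt))
  expect_false(evaluate_logexp("YOGA & INJURY", txt))
  expect_true(evaluate_logexp("INJURY | CHRONIC", txt))
  expect_true(evaluate_logexp("TREATMENT | CHRONIC", txt))
  expect_false(evaluate_logexp("INJURY | COLD", txt))
  expect_true(evaluate_logexp("~INJURY", txt))
  expect_false(evaluate_logexp("~YOGA", txt))
  expect_true(evaluate_logexp("{CHRONIC | ACUTE} & CONDITIONS", txt))
})

test_that("'_' demands a literal space; padding lets word-initial patterns match edges", {
  expect_true(evaluate_logexp("_CARDI & VASCUL", "cardiac and vascular outcomes"))
  expect_false(evaluate_logexp("_CARDI", "myocardial infarction"))
  expect_true(evaluate_logexp("_CARDI", "cardi at text start"))
  expect_true(evaluate_logexp("END_", "words end here"))  # trailing space at pad
})

test_that("evaluation agrees with a truth-table oracle on random expressions", {
  set.seed(52)
  words <- c("AAA", "BBB", "CCC", "DDD", "EEE")
  for (i in 1:1000) {
    ast <- random_ast(sample(1:4, 1), words)
    txt <- paste(sample(c(words, "XXX", "YYY"), sample(1:8, 1), replace = TRUE),
                 collapse = " ")
    e <- as_logexp(ast)
    expect_equal(evaluate_logexp(e, txt), oracle_eval(ast, txt),
                 label = paste(format(e), "on", txt))
  }
})

test_that("De Morgan duals evaluate identically", {
  set.seed(53)
  words <- c("AAA", "BBB", "CCC")
  for (i in 1:100) {
    a <- sample(words, 1); b <- sample(words, 1)
    txt <- paste(sample(words, sample(0:3, 1)), collapse = " ")
    expect_equal(evaluate_logexp(sprintf("~{%s | %s}", a, b), txt),
                 evaluate_logexp(sprintf("~%s & ~%s", a, b), txt))
    expect_equal(evaluate_logexp(sprintf("~{%s & %s}", a, b), txt),
                 evaluate_logexp(sprintf("~%s | ~%s", a, b), txt))
  }
})

test_that("matching counts documents and titles, monotonically in the expression", {
  fit <- fixture_fit()
  x <- fit$fx$corpus
  kw <- fit$fx$truth$keywords
  # the focus term heads every title: a universal match in both fields
  m_all <- match_corpus("YOGA", x)
  expect_equal(m_all$n_docs, nrow(x))
  expect_equal(m_all$n_titles, nrow(x))
  expect_equal(sort(m_all$matched_doc_ids), sort(x$doc_id))
  # adding an OR-term never shrinks, adding an AND-term never grows
  m1 <- match_corpus(kw[1], x)
  m_or <- match_corpus(paste(kw[1], "|", kw[2]), x)
  m_and <- match_corpus(paste(kw[1], "&", kw[2]), x)
  expect_gte(m_or$n_docs, m1$n_docs)
  expect_lte(m_and$n_docs, m1$n_docs)
  # titles are a subfield of the text: title hits never exceed text hits
  for (e in c(kw, "YOGA")) {
    m <- match_corpus(e, x)
    expect_lte(m$n_titles, m$n_docs)
  }
})

test_that("expression vectors average the matched documents' base vectors", {
  fit <- fixture_fit()
  x <- fit$fx$corpus
  wbase <- fit$tm$wbase
  kw <- fit$fx$truth$keywords
  # single-document match: exactly that document's base row
  one_id <- x$doc_id[1]
  uniq_tok <- setdiff(tokenize(x$abstract[1]),
                      unlist(lapply(2:nrow(x), function(i) tokenize(x$abstract[i]))))
  if (length(uniq_tok)) {
    pat <- paste0("_", uniq_tok[1], "_")
    m <- match_corpus(pat, x)
    if (m$n_docs == 1) {
      expect_equal(vectorize_logexp(pat, x, wbase), unname(colMeans(wbase[m$matched_doc_ids, , drop = FALSE])))
    }
  }
  # keyword expressions partition the corpus: their union mean is the global mean
  big <- paste(sprintf("_%s_", kw), collapse = " | ")
  expect_equal(vectorize_logexp(big, x, wbase), unname(colMeans(unclass(wbase))),
               tolerance = 1e-12)
  # brute-force oracle for an arbitrary expression
  e <- sprintf("%s | %s", kw[1], kw[2])
  m <- match_corpus(e, x)
  acc <- numeric(ncol(wbase)); n <- 0
  for (id in m$matched_doc_ids) { acc <- acc + wbase[id, ]; n <- n + 1 }
  expect_equal(vectorize_logexp(e, x, wbase), unname(acc / n), tolerance = 1e-12)
  expect_error(vectorize_logexp("QQQQZZZZ", x, wbase), "matches no document")
})

test_that("coverage reports the union recall of an expression set", {
  fit <- fixture_fit()
  x <- fit$fx$corpus
  kw <- fit$fx$truth$keywords
  cov_all <- coverage_report(list(parse_logexp("YOGA")), x)
  expect_equal(cov_all$doc_recall, 100)
  expect_equal(cov_all$title_recall, 100)
  # per-topic keywords partition the corpus: union covers all documents
  cov_kw <- coverage_report(sprintf("_%s_", kw), x)
  expect_equal(cov_kw$doc_recall, 100)
  expect_error(coverage_report(list(), x), "at least one")
  expect_error(coverage_report("YOGA", x[0, ]), "empty corpus")
})

test_that("expression files round-trip and embed as a labelled Wlog space", {
  fit <- fixture_fit()
  kw <- fit$fx$truth$keywords
  exprs <- mapply(parse_logexp,
                  sprintf("_%s_", kw), paste0("LOGEXP ", seq_along(kw)),
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_logexp(exprs, f)
  back <- read_logexp(f)
  expect_equal(vapply(back, function(e) e$label, ""), paste0("LOGEXP ", seq_along(kw)))
  expect_equal(lapply(back, function(e) e$ast), lapply(exprs, function(e) e$ast))
  wlog <- embed_logexps(back, fit$fx$corpus, fit$tm$wbase)
  expect_equal(nrow(wlog), length(kw))
  expect_equal(attr(wlog, "space_tag"), "Wlog")
  expect_equal(rownames(wlog), paste0("LOGEXP ", seq_along(kw)))
})
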