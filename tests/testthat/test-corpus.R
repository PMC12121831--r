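# Record ingestion, the filter funnel, tokenization, vocabulary and the
# year-usage index.

medline_fixture <- function(path) {
  writeLines(c(
    "PMID- 101",
    "TI  - Yoga and health outcomes",
    "AB  - Health benefits of yoga practice",
    "      in adults.",
    "DP  - 2010 Jan 15",
    "",
    "PMID- 102",
    "TI  - Breathing practice in asthma",
    "AB  - Breathing exercises improve asthma symptoms and health.",
    "DP  - 2015",
    "",
    "TI  - Yoga for chronic pain",
    "AB  - Chronic pain patients practice yoga for relief.",
    "DP  - 2020 Dec",
    ""
  ), path)
  path
}

test_that("MEDLINE records parse field by field, with continuation lines and synthetic ids", {
  f <- medline_fixture(withr::local_tempfile(fileext = ".txt"))
  x <- read_corpus(f, "medline")
  expect_s3_class(x, "corpus")
  expect_equal(nrow(x), 3L)
  expect_equal(x$doc_id[1:2], c("101", "102"))
  expect_match(x$doc_id[3], "^DOC")      # record without PMID gets a synthetic id
  expect_equal(x$year, c(2010L, 2015L, 2020L))
  expect_equal(x$title[1], "Yoga and health outcomes")
  expect_equal(x$abstract[1], "Health benefits of yoga practice in adults.")
})

test_that("an empty file yields an empty corpus and CSV input matches MEDLINE input", {
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_equal(nrow(read_corpus(empty, "medline")), 0L)

  f <- medline_fixture(withr::local_tempfile(fileext = ".txt"))
  med <- read_corpus(f, "medline")
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(pmid = med$doc_id, title = med$title,
                              abstract = med$abstract, year = med$year),
                   csv, row.names = FALSE)
  via_csv <- read_corpus(csv, "csv")
  expect_equal(as.data.frame(via_csv), as.data.frame(med), ignore_attr = TRUE)
})

test_that("corpus TSV serialization round-trips, including a column-mapped header", {
  x <- tiny_corpus()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(x, f)
  y <- read_corpus(f, "tsv")
  expect_equal(as.data.frame(y), as.data.frame(x), ignore_attr = TRUE)

  # deposited-table shape: different column names, mapped via col_map
  df <- utils::read.delim(f)
  names(df) <- c("PMID", "Year", "Title", "Abstract")
  g <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, g, sep = "\t", row.names = FALSE)
  z <- read_corpus(g, "tsv", col_map = c(pmid = "PMID", year = "Year",
                                         title = "Title", abstract = "Abstract"))
  expect_equal(z$doc_id, x$doc_id)
  expect_equal(z$title, x$title)
})

test_that("the filter funnel applies length, duplicate-title and focus rules in order", {
  long_pad <- strrep("background text ", 20)  # 320 chars
  x <- corpus(
    doc_id = paste0("D", 1:7),
    title = c("Yoga one", "No abstract", "Short doc", "Yoga one",
              "Yoga two", "Running study", "Yoga three"),
    abstract = c(long_pad, "", strrep("a", 250), long_pad,
                 long_pad, long_pad, long_pad),
    year = 2000:2006
  )
  fl <- filter_corpus(x, focus_term = "yoga", title_only = TRUE)
  r <- fl$report
  expect_equal(r$removed_empty_fields, 1L)       # D2
  expect_equal(r$removed_short, 1L)              # D3
  expect_equal(r$removed_duplicate_title, 1L)    # D4 (later duplicate of D1)
  expect_equal(r$removed_no_focus_in_title, 1L)  # D6
  expect_equal(fl$corpus$doc_id, c("D1", "D5", "D7"))  # first duplicate kept
  expect_equal(r$n_input, r$n_output + r$removed_empty_fields + r$removed_short +
                 r$removed_duplicate_title + r$removed_no_focus_in_title)
})

test_that("min_chars is a strict boundary on the normalized title+abstract", {
  # title (5) + space + abstract (293) = 299 normalized characters
  ttl <- "Yoga1"
  ab <- paste0(strrep("abcde ", 48), "abcde")  # 293 chars
  x <- corpus("A", ttl, ab, 2000)
  expect_equal(nchar(corpus_text(x)), 299L)
  expect_equal(filter_corpus(x, "YOGA")$corpus |> nrow(), 0L)
  x2 <- corpus("A", paste0(ttl, "x"), ab, 2000)  # 300 characters
  expect_equal(nrow(filter_corpus(x2, "YOGA")$corpus), 1L)
})

test_that("filtering is idempotent and conserves counts on random corpora", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    x <- corpus(
      doc_id = paste0("R", seq_len(n)),
      title = replicate(n, paste(if (runif(1) < 0.5) "yoga" else "other",
                                 paste0(sample(letters, 6), collapse = ""))),
      abstract = replicate(n, strrep(paste0(sample(letters, 8), collapse = ""),
                                     sample(c(5, 60), 1))),
      year = sample(1990:2020, n, replace = TRUE)
    )
    # plant one duplicate title
    if (n > 3) x$title[n] <- x$title[1]
    f1 <- filter_corpus(x, "yoga", title_only = TRUE)
    expect_equal(f1$report$n_input,
                 f1$report$n_output + f1$report$removed_empty_fields +
                   f1$report$removed_short + f1$report$removed_duplicate_title +
                   f1$report$removed_no_focus_in_title)
    f2 <- filter_corpus(f1$corpus, "yoga", title_only = TRUE)
    expect_equal(as.data.frame(f2$corpus), as.data.frame(f1$corpus))
    expect_equal(f2$report$n_input, f2$report$n_output)
  }
})

test_that("tokenize extracts uppercase alphabetic runs of length >= 3, case-invariantly", {
  expect_equal(tokenize("Yoga-based practice!"), c("YOGA", "BASED", "PRACTICE"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("a an I"), character(0))
  expect_equal(tokenize("Café 123 x7y"), "CAFE")
  set.seed(1)
  for (i in 1:20) {
    s <- paste0(sample(c(letters, LETTERS, " ", ".", "3"), 40, replace = TRUE),
                collapse = "")
    expect_equal(tokenize(s), tokenize(tolower(s)))
  }
})

test_that("vocabulary frequencies, relevance ratios and flags are correct", {
  x <- tiny_corpus()
  bg <- c(HEALTH = 0.5, YOGA = 1e-6, THE = 0.9)
  v <- build_vocabulary(x, background = bg, relevance_threshold = 1)
  expect_true(all(diff(rank(v$word)) > 0))  # sorted by word
  # doc_frequency equals a brute-force recount
  for (w in v$word) {
    bf <- sum(vapply(seq_len(nrow(x)), function(i) {
      w %in% tokenize(paste(x$title[i], x$abstract[i]))
    }, logical(1)))
    expect_equal(v$doc_frequency[v$word == w], bf)
  }
  # a ubiquitous domain word with tiny background frequency is relevant
  expect_true(v$is_relevant[v$word == "YOGA"])
  # a word with large background frequency is not (ratio < 1)
  expect_false(v$is_relevant[v$word == "HEALTH"])
  # words absent from the background table take its minimum frequency
  expect_equal(v$background_rel_freq[v$word == "CHRONIC"],
               min(bg / sum(bg)))
  expect_error(build_vocabulary(x, background = numeric(0)), "empty")
})

test_that("a single-word corpus yields a one-entry vocabulary", {
  x <- corpus(c("A", "B"), c("alpha", "alpha"), c("alpha alpha", "alpha"), c(2000, 2001))
  v <- build_vocabulary(x)
  expect_equal(nrow(v), 1L)
  expect_equal(v$word, "ALPHA")
  expect_equal(v$doc_frequency, 2L)
})

test_that("year usage averages the publication years of containing documents", {
  x <- corpus(c("A", "B", "C"),
              title = c("word one", "word two", "other"),
              abstract = c("shared token here", "shared token here", "different text"),
              year = c(2010L, 2020L, NA))
  yu <- year_usage_index("SHARED", x)
  expect_equal(yu$mean_year, 2015)
  expect_equal(yu$per_year_counts, c("2010" = 1L, "2020" = 1L))
  expect_error(year_usage_index("ABSENT", x), "not found")
})

test_that("a word occurring only in year-less documents is an error", {
  x <- corpus(c("A", "B"), c("one", "two"), c("unique text", "other words"),
              c(NA, 2000L))
  expect_error(year_usage_index("UNIQUE", x), "without a year")
  expect_equal(year_usage_index("OTHER", x)$mean_year, 2000)
})
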