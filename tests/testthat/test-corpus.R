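test_that("tokenization lowercases, strips punctuation and is deterministic", {
  expect_identical(tokenize(""), character())
  expect_identical(tokenize(NA_character_), character())
  expect_identical(tokenize("BRCA1 and BRCA1."), c("brca1", "and", "brca1"))
  txt <- "p53-mediated Apoptosis, in 12 cell-lines!"
  expect_identical(tokenize(txt), tokenize(txt))
  expect_identical(tokenize(txt),
                   c("p53", "mediated", "apoptosis", "in", "12", "cell", "lines"))
  cfg <- tokenizer_config(stopwords = c("and", "in"))
  expect_identical(tokenize("BRCA1 and BRCA1.", cfg), c("brca1", "brca1"))
  stem <- tokenizer_config(stem = TRUE)
  expect_identical(tokenize("genes binding mutated bodies", stem),
                   c("gene", "bind", "mutat", "bodi"))
})

test_that("passage extraction returns maximal inter-break segments", {
  txt100 <- paste(rep("a", 100), collapse = "")
  p <- extract_passages(document("d", txt100))
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 0L)
  expect_equal(p$length, 100L)

  p <- extract_passages(document("d", "aaaabbb", paragraph_breaks = 4L))
  expect_equal(p$start, c(0L, 4L))
  expect_equal(p$length, c(4L, 3L))
  expect_equal(p$text, c("aaaa", "bbb"))

  # boundary breaks are vacuous
  p0 <- extract_passages(document("d", "aaaabbb"))
  pb <- extract_passages(document("d", "aaaabbb", paragraph_breaks = c(0L, 7L)))
  expect_equal(pb[c("start", "length", "text")], p0[c("start", "length", "text")])

  # whitespace-only segments are dropped, surrounding whitespace trimmed
  p <- extract_passages(document("d", "ab   cd", paragraph_breaks = c(2L, 5L)))
  expect_equal(p$text, c("ab", "cd"))
  expect_equal(p$start, c(0L, 5L))
})

test_that("passage spans tile the document over random break sets", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(5:60, 1)
      txt <- paste(sample(letters, n, replace = TRUE), collapse = "")
      breaks <- sort(sample(0:n, sample(0:4, 1)))
      p <- extract_passages(document("d", txt, breaks))
      covered <- unlist(mapply(function(s, l) seq.int(s, s + l - 1L),
                               p$start, p$length, SIMPLIFY = FALSE))
      expect_identical(sort(covered), 0:(n - 1L))
    }
  })
})

test_that("invalid paragraph breaks are rejected", {
  expect_error(document("d", "abc", c(2L, 1L)), "strictly increasing")
  expect_error(document("d", "abc", 5L), "strictly increasing")
})

test_that("HTML preprocessor turns <p> tags into breaks and strips others", {
  doc <- html_to_document("d", "<p>one <b>bold</b></p><p>two</p>")
  expect_equal(doc$text, "one boldtwo")
  expect_equal(doc$paragraph_breaks, 8L)
  p <- extract_passages(doc)
  expect_equal(p$text, c("one bold", "two"))
})

test_that("index postings and stats match a hand count and reject duplicates", {
  passages <- tokenize_passages(data.frame(
    passage_id = c("x", "y"), doc_id = "d", start = c(0L, 4L),
    length = c(3L, 3L), text = c("a b", "b b"), stringsAsFactors = FALSE))
  idx <- build_index(passages)
  expect_equal(unname(idx$stats$doc_freq["b"]), 2L)
  expect_equal(unname(idx$stats$coll_freq["b"]), 3L)
  expect_equal(idx$stats$avg_passage_len, 2)
  expect_equal(idx$stats$total_tokens, 4L)
  expect_equal(idx$postings[["b"]]$tf, c(1L, 2L))

  empty <- build_index(tokenize_passages(data.frame(
    passage_id = character(), doc_id = character(), start = integer(),
    length = integer(), text = character(), stringsAsFactors = FALSE)))
  expect_equal(empty$stats$num_passages, 0L)
  expect_length(empty$postings, 0L)

  passages$passage_id <- c("x", "x")
  expect_error(build_index(passages), "duplicate passage_id")
})

test_that("index stats equal a brute-force recount on a random corpus", {
  withr::with_seed(21, {
    n <- 50
    texts <- vapply(seq_len(n), function(i)
      paste(sample(letters[1:8], sample(3:12, 1), replace = TRUE),
            collapse = " "), character(1))
    passages <- tokenize_passages(data.frame(
      passage_id = sprintf("p%02d", seq_len(n)), doc_id = "d",
      start = 0L, length = nchar(texts), text = texts,
      stringsAsFactors = FALSE))
    idx <- build_index(passages)
    oracle <- recount_stats(passages$tokens)
    expect_equal(idx$stats$num_passages, oracle$num_passages)
    expect_equal(idx$stats$avg_passage_len, oracle$avg_passage_len)
    expect_equal(idx$stats$total_tokens, oracle$total_tokens)
    expect_equal(idx$stats$doc_freq[names(oracle$doc_freq)],
                 stats::setNames(as.integer(oracle$doc_freq), names(oracle$doc_freq)))
    expect_equal(idx$stats$coll_freq[names(oracle$coll_freq)],
                 stats::setNames(as.integer(oracle$coll_freq), names(oracle$coll_freq)))
    expect_true(all(idx$stats$doc_freq <= idx$stats$num_passages))
    expect_true(all(idx$stats$coll_freq >= idx$stats$doc_freq))
  })
})

test_that("relevance transfers by character overlap with max-grade/union-aspect", {
  passages <- data.frame(passage_id = "p", doc_id = "d", start = 10L,
                         length = 20L, stringsAsFactors = FALSE)
  qr <- function(start, length, grade, aspects) {
    data.frame(query_id = "q", doc_id = "d", start = start, length = length,
               grade = grade, aspects = I(list(aspects)), stringsAsFactors = FALSE)
  }
  # 5-char overlap
  lab <- transfer_relevance(passages, qr(25L, 15L, 1, "a"), "q")
  expect_equal(lab$grade, 1)
  expect_equal(lab$aspects[[1]], "a")
  # half-open intervals: touching spans do not overlap
  lab <- transfer_relevance(passages, qr(30L, 10L, 1, "a"), "q")
  expect_equal(lab$grade, 0)
  expect_equal(lab$aspects[[1]], character())
  # two overlapping spans: max grade, union of aspects
  qr2 <- rbind(qr(5L, 10L, 1, "a"), qr(25L, 10L, 2, "b"))
  lab <- transfer_relevance(passages, qr2, "q")
  expect_equal(lab$grade, 2)
  expect_equal(lab$aspects[[1]], c("a", "b"))
  # unknown doc_id: warning, span skipped
  qr3 <- qr(12L, 5L, 1, "a"); qr3$doc_id <- "nope"
  expect_warning(lab <- transfer_relevance(passages, qr3, "q"), "unknown doc_id")
  expect_equal(lab$grade, 0)
})

test_that("adding a gold span never lowers a grade or shrinks an aspect set", {
  withr::with_seed(31, {
    passages <- data.frame(passage_id = sprintf("p%d", 1:6), doc_id = "d",
                           start = seq(0L, 100L, by = 20L), length = 20L,
                           stringsAsFactors = FALSE)
    spans <- lapply(1:8, function(i)
      data.frame(query_id = "q", doc_id = "d",
                 start = sample(0:110, 1), length = sample(1:30, 1),
                 grade = sample(0:2, 1),
                 aspects = I(list(sample(letters[1:4], sample(0:2, 1)))),
                 stringsAsFactors = FALSE))
    prev <- transfer_relevance(passages, spans[[1]], "q")
    acc <- spans[[1]]
    for (i in 2:8) {
      acc <- rbind(acc, spans[[i]])
      cur <- transfer_relevance(passages, acc, "q")
      expect_true(all(cur$grade >= prev$grade))
      for (j in seq_len(nrow(passages)))
        expect_true(all(prev$aspects[[j]] %in% cur$aspects[[j]]))
      prev <- cur
    }
  })
})

test_that("JSON-lines corpus round-trips", {
  docs <- list(document("d1", "alpha beta", 5L),
               document("d2", "gamma"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(docs, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back, docs)
})
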