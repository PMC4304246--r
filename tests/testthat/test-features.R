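# Hand-worked values on the 3-passage micro-corpus:
#   p1 = "brca1 gene mutation brca1" (len 4), p2 = "gene expression profile"
#   (len 3), p3 = "the cell cycle gene" (len 4); query = {brca1, gene}.
#   N = 3, total tokens = 11, avgdl = 11/3; tf(brca1,p1) = 2, tf(gene,p1) = 1;
#   df(brca1) = 1, df(gene) = 3; cf(brca1) = 2, cf(gene) = 3.

test_that("TF-IDF matches manual arithmetic and its smoothing boundary", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  # brca1: 2 * log(4/2); gene occurs in every passage: log(4/4) = 0
  expect_equal(score_tfidf(q, "p1", idx), 2 * log(2))
  # term absent from the passage contributes nothing
  expect_equal(score_tfidf("mutation", "p2", idx), 0)
  expect_equal(score_tfidf(c("zzz"), "p1", idx), 0)
})

test_that("BM25 matches manual arithmetic; equal tf/length gives equal scores", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  k1 <- 1.2; b <- 0.75; avgdl <- 11 / 3
  K <- k1 * (1 - b + b * 4 / avgdl)
  manual <- log(2.5 / 1.5) * 2 * (k1 + 1) / (2 + K) +
    log(0.5 / 3.5) * 1 * (k1 + 1) / (1 + K)
  expect_equal(score_bm25(q, "p1", idx), manual)
  expect_equal(score_bm25("zzz", "p1", idx), 0)
  # p1 and p3 both have length 4 and tf(gene) = 1
  expect_equal(score_bm25("gene", "p1", idx), score_bm25("gene", "p3", idx))
})

test_that("DFR variants match manual arithmetic; DLH13 rejects a parameter", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  avgdl <- 11 / 3
  tfn <- function(tf) tf * log2(1 + avgdl / 4)
  manual_inl2 <- tfn(2) / (tfn(2) + 1) * log2(4 / 1.5) +
    tfn(1) / (tfn(1) + 1) * log2(4 / 3.5)
  expect_equal(score_dfr("InL2", q, "p1", idx, c = 1), manual_inl2)
  k1 <- 1.2
  manual_dfrbm25 <- (k1 + 1) * tfn(2) / (k1 + tfn(2)) * log2(2.5 / 1.5) +
    (k1 + 1) * tfn(1) / (k1 + tfn(1)) * log2(0.5 / 3.5)
  expect_equal(score_dfr("DFR_BM25", q, "p1", idx), manual_dfrbm25)
  manual_dlh13 <-
    (2 * log2((2 * avgdl / 4) * (3 / 2)) + 0.5 * log2(2 * pi * 2 * 0.5)) / 2.5 +
    (1 * log2((1 * avgdl / 4) * (3 / 3)) + 0.5 * log2(2 * pi * 1 * 0.75)) / 1.5
  expect_equal(score_dfr("DLH13", q, "p1", idx), manual_dlh13)
  for (v in c("DFR_BM25", "InL2", "DLH13"))
    expect_equal(score_dfr(v, "zzz", "p1", idx), 0)
  expect_error(score_dfr("DLH13", q, "p1", idx, c = 2), "parameter-free")
  expect_error(score_dfr("whatever", q, "p1", idx), "arg")
})

test_that("Dirichlet query likelihood matches manual arithmetic", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  mu <- 2000
  manual <- log((2 + mu * 2 / 11) / (4 + mu)) + log((1 + mu * 3 / 11) / (4 + mu))
  expect_equal(score_dirkl(q, "p1", idx), manual)
  # permutation invariance (bag-of-words symmetry)
  expect_equal(score_dirkl(c("gene", "brca1"), "p1", idx),
               score_dirkl(c("brca1", "gene"), "p1", idx))
  # OOV floor keeps the score finite
  expect_true(is.finite(score_dirkl("zzz", "p1", idx)))
  # when the passage is the whole collection, mu -> 0 recovers the query's
  # maximum-likelihood log probability under that text
  solo <- build_index(tokenize_passages(data.frame(
    passage_id = "only", doc_id = "d", start = 0L, length = 11L,
    text = "a a b c", stringsAsFactors = FALSE)))
  ml <- log(2 / 4) + log(1 / 4)
  expect_equal(score_dirkl(c("a", "b"), "only", solo, feature_params(mu = 1e-9)),
               ml, tolerance = 1e-6)
})

test_that("Hiemstra LM matches manual arithmetic and vanishes as lam -> 0", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  lam <- 0.15
  manual <- log(1 + lam * 2 * 11 / ((1 - lam) * 2 * 4)) +
    log(1 + lam * 1 * 11 / ((1 - lam) * 3 * 4))
  expect_equal(score_hiemstra_lm(q, "p1", idx), manual)
  expect_equal(score_hiemstra_lm("zzz", "p1", idx), 0)
  tiny <- score_hiemstra_lm(q, "p1", idx, feature_params(lam = 1e-9))
  expect_lt(tiny, 1e-7)
})

test_that("proximity feature matches an exhaustive pair-distance oracle", {
  passages <- tokenize_passages(data.frame(
    passage_id = c("s1", "s2", "s3"), doc_id = "d", start = c(0L, 10L, 30L),
    length = c(3L, 7L, 7L),
    text = c("a b", "a x x b", "a x b c"), stringsAsFactors = FALSE))
  idx <- build_index(passages)
  # single-term query is always 0
  expect_equal(score_proxqt("a", "s1", idx), 0)
  # closer pairs score strictly higher
  expect_gt(score_proxqt(c("a", "b"), "s1", idx), score_proxqt(c("a", "b"), "s2", idx))
  # brute force over all ordered pairs and occurrence distances
  brute <- function(q, toks, window = Inf) {
    total <- 0
    for (t1 in q) for (t2 in q) {
      if (t1 >= t2) next
      p1 <- which(toks == t1); p2 <- which(toks == t2)
      if (!length(p1) || !length(p2)) next
      d <- min(abs(outer(p1, p2, "-")))
      if (d <= window) total <- total + 2 / d^2
    }
    total
  }
  expect_equal(score_proxqt(c("a", "b", "c"), "s3", idx),
               brute(c("a", "b", "c"), c("a", "x", "b", "c")))
  # window cuts distant pairs
  expect_equal(score_proxqt(c("a", "b"), "s2", idx, feature_params(window = 2)), 0)
  expect_equal(score_proxqt(c("a", "b"), "s2", idx),
               brute(c("a", "b"), c("a", "x", "x", "b")))
})

test_that("feature matrix equals the individual scorers and is permutation-safe", {
  idx <- micro_corpus()
  q <- c("brca1", "gene")
  mat <- extract_general_features(q, c("p1", "p2", "p3"), idx)
  expect_identical(colnames(mat), general_feature_names())
  expect_equal(mat["p1", "TFIDF"], score_tfidf(q, "p1", idx))
  expect_equal(mat["p2", "BM25"], score_bm25(q, "p2", idx))
  expect_equal(mat["p3", "DirKL"], score_dirkl(q, "p3", idx))
  expect_equal(mat["p1", "DLH13"], score_dfr("DLH13", q, "p1", idx))
  # all eight features invariant under query-token permutation
  expect_equal(extract_general_features(rev(q), c("p1", "p2"), idx),
               mat[c("p1", "p2"), ])
  # a candidate sharing no terms with the query: lexical features 0
  m0 <- extract_general_features(c("zzz", "qqq"), "p1", idx)
  expect_equal(unname(m0[1, c("TFIDF", "BM25", "DFR_BM25", "InL2", "DLH13",
                              "HiemstraLM", "ProxQT")]),
               rep(0, 7))
})

test_that("duplicate passages receive identical feature vectors", {
  passages <- tokenize_passages(data.frame(
    passage_id = c("u", "v", "w"), doc_id = "d", start = c(0L, 20L, 40L),
    length = c(11L, 11L, 7L),
    text = c("gene a b c", "gene a b c", "other x"), stringsAsFactors = FALSE))
  idx <- build_index(passages)
  mat <- extract_general_features(c("gene", "b"), c("u", "v"), idx)
  expect_equal(unname(mat["u", ]), unname(mat["v", ]))
})

test_that("lexical scores are non-decreasing in matched-term tf, all else fixed", {
  # BM25's classical idf goes negative once df > N/2, where tf-monotonicity
  # genuinely fails; the property is asserted in the ordinary df <= N/2 regime
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- 6
      texts <- vapply(seq_len(n), function(i)
        paste(sample(letters[1:5], sample(4:9, 1), replace = TRUE),
              collapse = " "), character(1))
      with_t <- sample.int(n, 3)
      texts[with_t] <- paste(texts[with_t], "t")
      idx <- build_index(tokenize_passages(data.frame(
        passage_id = sprintf("p%d", seq_len(n)), doc_id = "d", start = 0L,
        length = nchar(texts), text = texts, stringsAsFactors = FALSE)))
      pid <- sprintf("p%d", sample.int(n, 1))
      # bump tf of the query term in one passage, holding everything else fixed
      idx2 <- idx
      old <- idx2$tf[[pid]]["t"]
      idx2$tf[[pid]]["t"] <- if (is.na(old)) 1L else old + 1L
      for (f in list(score_tfidf, score_bm25, score_dirkl, score_hiemstra_lm))
        expect_gte(f("t", pid, idx2), f("t", pid, idx))
    }
  })
})
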