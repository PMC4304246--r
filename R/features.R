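#' Feature schema
#'
#' The fixed, versioned ordering of the feature columns: eight content-based
#' general features, optionally extended by seven diversity features computed
#' from an initial ranking.
#'
#' @return Character vector of feature names in canonical order.
#' @export
general_feature_names <- function() {
  c("TFIDF", "BM25", "DFR_BM25", "InL2", "DLH13", "DirKL", "HiemstraLM", "ProxQT")
}

#' @rdname general_feature_names
#' @export
diversity_feature_names <- function() {
  c("RelAsp", "NonRelAsp", "NewRelAsp", "OldRelAsp",
    "NewAspPsg", "PctRelAsp", "PctUniqRelAsp")
}

#' Scoring hyperparameters
#'
#' Field-standard defaults for the general features; all configurable.
#'
#' @param k1,b Okapi BM25 term-saturation and length-normalization parameters
#'   (`k1 >= 0`, `0 <= b <= 1`); `k1` is also used by the DFR version of BM25.
#' @param c Length-normalization parameter of DFR normalization 2 (InL2 and
#'   DFR BM25); must be positive.
#' @param mu Dirichlet smoothing mass in tokens (`mu > 0`).
#' @param lam Hiemstra language-model mixing weight in (0, 1).
#' @param window Maximum token distance at which a query-term pair contributes
#'   to the proximity feature; `Inf` (default) means unlimited.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(k1 = 1.2, b = 0.75, c = 1.0, mu = 2000,
                           lam = 0.15, window = Inf) {
  stopifnot(k1 >= 0, b >= 0, b <= 1, c > 0, mu > 0, lam > 0, lam < 1, window >= 1)
  structure(list(k1 = k1, b = b, c = c, mu = mu, lam = lam, window = window),
            class = "feature_params")
}

# Resolve a query argument to its token vector.
query_tokens <- function(q) {
  if (is.list(q) && !is.null(q$tokens)) q <- q$tokens
  stopifnot(is.character(q))
  if (!length(q)) stop("query must have at least one token")
  q
}

# Per-passage term statistics needed by every lexical feature: query-term
# multiplicities, tf in the passage, df/cf in the collection.
term_stats <- function(index, passage_id, q) {
  qt <- table(query_tokens(q))
  terms <- names(qt)
  tfv <- index$tf[[passage_id]]
  if (is.null(tfv)) stop("unknown passage_id: ", passage_id)
  s <- index$stats
  list(terms = terms,
       qtf = as.numeric(qt),
       tf = ifelse(terms %in% names(tfv), tfv[terms], 0),
       df = ifelse(terms %in% names(s$doc_freq), s$doc_freq[terms], 0),
       cf = ifelse(terms %in% names(s$coll_freq), s$coll_freq[terms], 0),
       len = unname(index$passage_len[[passage_id]]),
       N = s$num_passages,
       avgdl = s$avg_passage_len,
       total = s$total_tokens)
}

#' Content-based feature scores
#'
#' The eight scoring functions of the general ranking model, each summing a
#' per-term weight over the query's terms (counted with multiplicity). The
#' exact formulations are pinned here for reproducibility:
#'
#' * `score_tfidf()`: `sum qtf * tf * log((N + 1) / (df + 1))`.
#' * `score_bm25()`: Okapi BM25,
#'   `sum qtf * log((N - df + 0.5) / (df + 0.5)) * tf (k1 + 1) / (tf + k1 (1 - b + b len/avgdl))`.
#' * `score_dfr()`: divergence-from-randomness models. `InL2` and `DFR_BM25`
#'   use normalization 2, `tfn = tf * log2(1 + c * avgdl / len)`; the per-term
#'   weights are `tfn/(tfn + 1) * log2((N + 1)/(df + 0.5))` for InL2 and
#'   `(k1 + 1) tfn / (k1 + tfn) * log2((N - df + 0.5)/(df + 0.5))` for the DFR
#'   version of BM25. `DLH13` is the parameter-free hypergeometric model
#'   `(tf * log2((tf * avgdl / len) * (N / cf)) + 0.5 * log2(2 pi tf (1 - tf/len))) / (tf + 0.5)`.
#' * `score_dirkl()`: Dirichlet-smoothed query log-likelihood
#'   `sum qtf * log((tf + mu P(t|C)) / (len + mu))` with `P(t|C) = cf/total`;
#'   out-of-vocabulary terms use the floor `P(t|C) = 1/(2 total)` so the score
#'   stays finite while preserving ordering.
#' * `score_hiemstra_lm()`:
#'   `sum qtf * log(1 + lam tf total / ((1 - lam) cf len))`; terms with
#'   `cf = 0` or `tf = 0` contribute nothing.
#' * `score_proxqt()`: sum over ordered pairs of distinct matched query terms
#'   of `1 / mindist^2`, where `mindist` is the minimum token distance between
#'   occurrences of the two terms; pairs farther apart than `window` are
#'   ignored, and fewer than two distinct matched terms give 0.
#'
#' @param q Query: a token vector or a list with a `tokens` element.
#' @param passage_id Passage identifier, resolved in `index`.
#' @param index A [build_index()] result over the passage's corpus.
#' @param params A [feature_params()].
#' @param variant For `score_dfr()`: one of `"DFR_BM25"`, `"InL2"`, `"DLH13"`.
#' @return A single numeric score; 0 when no query term matches.
#' @name general_features
NULL

#' @rdname general_features
#' @export
score_tfidf <- function(q, passage_id, index, params = feature_params()) {
  ts <- term_stats(index, passage_id, q)
  sum(ts$qtf * ts$tf * log((ts$N + 1) / (ts$df + 1)))
}

#' @rdname general_features
#' @export
score_bm25 <- function(q, passage_id, index, params = feature_params()) {
  ts <- term_stats(index, passage_id, q)
  m <- ts$tf > 0
  if (!any(m)) return(0)
  K <- params$k1 * (1 - params$b + params$b * ts$len / ts$avgdl)
  idf <- log((ts$N - ts$df[m] + 0.5) / (ts$df[m] + 0.5))
  sum(ts$qtf[m] * idf * ts$tf[m] * (params$k1 + 1) / (ts$tf[m] + K))
}

#' @rdname general_features
#' @param c Optional override of the normalization-2 parameter for the InL2
#'   and DFR BM25 variants. DLH13 is parameter-free: passing `c` with
#'   `variant = "DLH13"` is an error.
#' @export
score_dfr <- function(variant, q, passage_id, index, params = feature_params(),
                      c = NULL) {
  variant <- match.arg(variant, c("DFR_BM25", "InL2", "DLH13"))
  if (!is.null(c)) {
    if (variant == "DLH13") stop("DLH13 is parameter-free: no tuning parameter accepted")
    stopifnot(c > 0)
    params$c <- c
  }
  ts <- term_stats(index, passage_id, q)
  m <- ts$tf > 0
  if (!any(m)) return(0)
  tf <- ts$tf[m]; df <- ts$df[m]; cf <- ts$cf[m]; qtf <- ts$qtf[m]
  if (variant == "DLH13") {
    f <- tf / ts$len
    # guard the degenerate tf == len case (log2 of 0)
    onemf <- pmax(1 - f, 1e-10)
    w <- (tf * log2((tf * ts$avgdl / ts$len) * (ts$N / cf)) +
            0.5 * log2(2 * pi * tf * onemf)) / (tf + 0.5)
    return(sum(qtf * w))
  }
  tfn <- tf * log2(1 + params$c * ts$avgdl / ts$len)
  if (variant == "InL2") {
    w <- tfn / (tfn + 1) * log2((ts$N + 1) / (df + 0.5))
  } else {
    w <- (params$k1 + 1) * tfn / (params$k1 + tfn) *
      log2((ts$N - df + 0.5) / (df + 0.5))
  }
  sum(qtf * w)
}

#' @rdname general_features
#' @export
score_dlh13 <- function(q, passage_id, index) {
  score_dfr("DLH13", q, passage_id, index)
}

#' @rdname general_features
#' @export
score_dirkl <- function(q, passage_id, index, params = feature_params()) {
  ts <- term_stats(index, passage_id, q)
  p_c <- ifelse(ts$cf > 0, ts$cf / ts$total, 1 / (2 * ts$total))
  sum(ts$qtf * log((ts$tf + params$mu * p_c) / (ts$len + params$mu)))
}

#' @rdname general_features
#' @export
score_hiemstra_lm <- function(q, passage_id, index, params = feature_params()) {
  ts <- term_stats(index, passage_id, q)
  m <- ts$tf > 0 & ts$cf > 0
  if (!any(m)) return(0)
  lam <- params$lam
  sum(ts$qtf[m] * log(1 + lam * ts$tf[m] * ts$total /
                        ((1 - lam) * ts$cf[m] * ts$len)))
}

#' @rdname general_features
#' @export
score_proxqt <- function(q, passage_id, index, params = feature_params()) {
  qterms <- unique(query_tokens(q))
  toks <- index$tokens[[passage_id]]
  if (is.null(toks)) stop("unknown passage_id: ", passage_id)
  pos <- lapply(qterms, function(t) which(toks == t))
  present <- which(lengths(pos) > 0L)
  if (length(present) < 2L) return(0)
  total <- 0
  for (a in seq_along(present)) {
    for (b in seq_along(present)) {
      if (a >= b) next
      d <- min(abs(outer(pos[[present[a]]], pos[[present[b]]], "-")))
      if (d <= params$window) total <- total + 2 / d^2  # both ordered pairs
    }
  }
  total
}

#' Assemble the general feature matrix
#'
#' Computes the eight general features for every candidate passage of one
#' query, in the fixed [general_feature_names()] order.
#'
#' @param q Query (token vector or list with `tokens`).
#' @param candidates Character vector of passage ids.
#' @param index A [build_index()] result.
#' @param params A [feature_params()].
#' @return Numeric matrix, one row per candidate (rownames = passage ids),
#'   columns [general_feature_names()].
#' @export
extract_general_features <- function(q, candidates, index,
                                     params = feature_params()) {
  candidates <- as.character(candidates)
  mat <- matrix(0, nrow = length(candidates), ncol = 8L,
                dimnames = list(candidates, general_feature_names()))
  for (pid in candidates) {
    mat[pid, ] <- c(
      score_tfidf(q, pid, index, params),
      score_bm25(q, pid, index, params),
      score_dfr("DFR_BM25", q, pid, index, params),
      score_dfr("InL2", q, pid, index, params),
      score_dfr("DLH13", q, pid, index, params),
      score_dirkl(q, pid, index, params),
      score_hiemstra_lm(q, pid, index, params),
      score_proxqt(q, pid, index, params))
  }
  if (any(!is.finite(mat))) stop("non-finite feature value computed")
  mat
}
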