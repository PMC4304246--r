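# Shared fixtures and independent oracles, built in code.

# Three-passage micro-corpus used by the hand-worked feature checks.
micro_corpus <- function() {
  passages <- data.frame(
    passage_id = c("p1", "p2", "p3"),
    doc_id = c("d1", "d1", "d2"),
    start = c(0L, 30L, 0L),
    length = c(25L, 23L, 19L),
    text = c("brca1 gene mutation brca1",
             "gene expression profile",
             "the cell cycle gene"),
    stringsAsFactors = FALSE)
  build_index(tokenize_passages(passages))
}

# Brute-force recount of collection statistics straight from raw token lists.
recount_stats <- function(token_lists) {
  all_tokens <- unlist(token_lists, use.names = FALSE)
  terms <- sort(unique(all_tokens))
  list(num_passages = length(token_lists),
       avg_passage_len = mean(lengths(token_lists)),
       doc_freq = vapply(terms, function(t)
         sum(vapply(token_lists, function(x) t %in% x, logical(1))), numeric(1)),
       coll_freq = vapply(terms, function(t) sum(all_tokens == t), numeric(1)),
       total_tokens = length(all_tokens))
}

# Textbook average precision: mean of precision at each relevant rank.
textbook_ap <- function(rel, total_rel = sum(rel)) {
  if (total_rel == 0) return(0)
  prec_at <- cumsum(rel) / seq_along(rel)
  sum(prec_at[rel]) / total_rel
}

# Exhaustive search over every grid^k weight combination (excluding the
# all-zero vector), the oracle for the coordinate-ascent objective.
exhaustive_grid_search <- function(train_data, metric, grid) {
  k <- ncol(train_data[[1]]$features)
  combos <- do.call(expand.grid, rep(list(grid), k))
  objective <- divrank:::prepare_objective(train_data, metric)
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    w <- as.numeric(combos[i, ])
    if (all(w == 0)) next
    val <- objective(w)
    if (val > best) best <- val
  }
  best
}

# Random ranking + annotation instance for diversity-feature property tests.
random_aspect_instance <- function(n = 10, n_aspects = 6, n_rel = 3) {
  universe <- sprintf("a%d", seq_len(n_aspects))
  pids <- sprintf("p%02d", seq_len(n))
  ann <- lapply(seq_len(n), function(i)
    sample(universe, rpois(1, 1.5) %% (n_aspects + 1)))
  names(ann) <- pids
  list(pids = pids, ann = ann, a_rel = sample(universe, n_rel))
}

# Small labeled feature set for learner tests: k features, grades random.
random_train_data <- function(n_queries = 3, n_passages = 8, k = 2,
                              feature_names = paste0("f", seq_len(k))) {
  out <- lapply(seq_len(n_queries), function(qi) {
    feats <- matrix(stats::rnorm(n_passages * k), nrow = n_passages,
                    dimnames = list(sprintf("q%d_p%02d", qi, seq_len(n_passages)),
                                    feature_names))
    grades <- as.numeric(stats::runif(n_passages) < 0.4)
    if (!any(grades > 0)) grades[1] <- 1
    list(features = feats, grades = grades)
  })
  names(out) <- sprintf("q%d", seq_len(n_queries))
  out
}
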