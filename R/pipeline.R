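#' Fit the combined diversity-biased ranking framework on a set of queries
#'
#' Trains the general model (gLTR) on the eight content features by
#' coordinate ascent, ranks the training queries with it, derives the seven
#' diversity features from that initial ranking ("once for all"), and trains
#' the diversity-biased model (dLTR) on the 15-feature extension.
#'
#' During training the relevant aspect set `A_rel` of a query defaults to its
#' gold aspects; `aspect_provider` (a `function(query_id, dataset)` returning
#' a character vector) overrides this.
#'
#' @param dataset An [ltr_dataset()] with `annotations` (and `query_aspects`
#'   unless a provider is given).
#' @param qids Query ids to train on (default: all).
#' @param cfg A [train_config()].
#' @param aspect_provider Optional `A_rel` provider used during training.
#' @param diversity_metric Metric maximized when training the
#'   diversity-biased model; defaults to `"aspect_map"`, the metric the
#'   diversity features exist to improve (the general model keeps
#'   `cfg$metric`).
#' @return A list of class `combined_model` with elements `general` and
#'   `diversity` ([linear_model()]s).
#' @export
train_combined <- function(dataset, qids = names(dataset$queries), cfg,
                           aspect_provider = NULL,
                           diversity_metric = "aspect_map") {
  stopifnot(inherits(dataset, "ltr_dataset"))
  if (is.null(dataset$annotations))
    stop("dataset has no aspect annotations; cannot train the diversity model")
  train_q <- dataset$queries[qids]
  general <- train_coordinate_ascent(train_q, cfg)
  ext <- lapply(qids, function(qid) {
    q <- dataset$queries[[qid]]
    ranked <- rank_passages(general, q$features)
    a_rel <- if (!is.null(aspect_provider)) aspect_provider(qid, dataset)
             else dataset$query_aspects[[qid]]
    div <- extract_diversity_features(ranked, dataset$annotations, a_rel)
    feats <- build_diversity_training_set(q$features, div)
    list(features = feats, grades = q$grades, aspects = q$aspects,
         meta = q$meta)
  })
  names(ext) <- qids
  dcfg <- cfg
  dcfg$metric <- diversity_metric
  diversity <- train_coordinate_ascent(ext, dcfg)
  structure(list(general = general, diversity = diversity),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model>\n$general\n"); print(x$general)
  cat("$diversity\n"); print(x$diversity)
  invisible(x)
}

#' Rank queries with the combined model
#'
#' For each query: rank with the general model, compute the diversity
#' features from that initial ranking, score with the diversity-biased model,
#' and mix the per-query min-max-normalized scores with `alpha`. At inference
#' `A_rel` comes from `aspect_provider`; with no provider every observed
#' aspect is treated as relevant.
#'
#' @param model A [train_combined()] result.
#' @param dataset An [ltr_dataset()].
#' @param qids Query ids to rank.
#' @param alpha Mixing weight(s) in `[0, 1]`; may be a vector, in which case
#'   a list of ranking sets (one per alpha) is returned.
#' @param aspect_provider Optional `A_rel` provider for inference.
#' @param simplify Drop the outer per-alpha layer when `alpha` has length 1.
#' @return For scalar `alpha` (with `simplify = TRUE`): named list of
#'   `ranked_list`s. Otherwise a named list (by alpha value) of such lists.
#' @export
predict_combined <- function(model, dataset, qids = names(dataset$queries),
                             alpha = 0.7, aspect_provider = NULL,
                             simplify = TRUE) {
  stopifnot(inherits(model, "combined_model"))
  per_query <- lapply(qids, function(qid) {
    q <- dataset$queries[[qid]]
    g_ranked <- rank_passages(model$general, q$features)
    a_rel <- if (!is.null(aspect_provider)) aspect_provider(qid, dataset) else NULL
    div <- extract_diversity_features(g_ranked, dataset$annotations, a_rel)
    ext <- build_diversity_training_set(q$features, div)
    d_ranked <- rank_passages(model$diversity, ext)
    list(g = g_ranked, d = d_ranked)
  })
  names(per_query) <- qids
  one_alpha <- function(a) {
    out <- lapply(per_query, function(p) combine_rankings(p$g, p$d, a))
    names(out) <- qids
    out
  }
  if (length(alpha) == 1L && isTRUE(simplify)) return(one_alpha(alpha))
  out <- lapply(alpha, one_alpha)
  names(out) <- as.character(alpha)
  out
}

#' Sweep the combination weight alpha
#'
#' For each alpha on the grid, runs the full combined pipeline under 2-fold
#' cross-validation (seeded random half/half topic split): on each training
#' half gLTR and dLTR are fitted with [train_combined()], the complementary
#' half is ranked at each alpha, and the four MAP metrics are averaged over
#' the two test halves. Deterministic for a fixed config seed.
#'
#' @param dataset An [ltr_dataset()] with annotations and gold query aspects.
#' @param grid Numeric vector of alpha values (default the 0.1..0.9 sweep).
#' @param cfg A [train_config()].
#' @param aspect_provider Optional inference-time `A_rel` provider.
#' @return A data.frame with one row per alpha and columns `alpha`,
#'   `aspect_map`, `passage_map`, `passage2_map`, `document_map`.
#' @export
sweep_alpha <- function(dataset, grid = seq(0.1, 0.9, by = 0.1), cfg,
                        aspect_provider = NULL) {
  if (!length(grid)) stop("empty alpha grid")
  stopifnot(all(grid >= 0 & grid <= 1))
  qids <- names(dataset$queries)
  sp <- split_queries(qids, cfg$seed)
  folds <- list(list(train = sp$a, test = sp$b),
                list(train = sp$b, test = sp$a))
  fold_metrics <- lapply(folds, function(f) {
    model <- train_combined(dataset, f$train, cfg,
                            aspect_provider = aspect_provider)
    by_alpha <- predict_combined(model, dataset, f$test, alpha = grid,
                                 aspect_provider = aspect_provider,
                                 simplify = FALSE)
    do.call(rbind, lapply(by_alpha, evaluate_rankings, dataset = dataset))
  })
  avg <- (fold_metrics[[1L]] + fold_metrics[[2L]]) / 2
  data.frame(alpha = grid, avg, row.names = NULL)
}

#' Cross-validated comparison of gLTR and the combined model
#'
#' The end-to-end harness behind the package's synthetic benchmark: under a
#' seeded 2-fold topic split it fits gLTR and dLTR on each training half,
#' tunes alpha on the training half (by Document MAP, the same metric used
#' for model selection) over `alpha_grid`, and evaluates both gLTR and the
#' tuned combined model on the complementary half with all four metrics.
#'
#' @param dataset An [ltr_dataset()].
#' @param cfg A [train_config()].
#' @param alpha_grid Alphas to tune over (default 0.1..0.9).
#' @param tune_metric Metric used to pick alpha on the training half.
#' @param aspect_provider Optional inference-time `A_rel` provider (applied
#'   on both halves' predictions).
#' @return List with `gltr` and `ltr` (named metric vectors averaged over the
#'   two test halves) and `alpha` (the tuned value per fold).
#' @export
compare_gltr_ltr <- function(dataset, cfg, alpha_grid = seq(0.1, 0.9, by = 0.1),
                             tune_metric = "document_map",
                             aspect_provider = NULL) {
  qids <- names(dataset$queries)
  sp <- split_queries(qids, cfg$seed)
  folds <- list(list(train = sp$a, test = sp$b),
                list(train = sp$b, test = sp$a))
  out <- lapply(folds, function(f) {
    model <- train_combined(dataset, f$train, cfg,
                            aspect_provider = aspect_provider)
    # gLTR on the test half
    g_rank <- lapply(dataset$queries[f$test], function(q)
      rank_passages(model$general, q$features))
    names(g_rank) <- f$test
    g_metrics <- evaluate_rankings(g_rank, dataset)
    # tune alpha on the training half, then apply to the test half
    tr_by_alpha <- predict_combined(model, dataset, f$train, alpha = alpha_grid,
                                    aspect_provider = aspect_provider,
                                    simplify = FALSE)
    metric_fun <- switch(tune_metric, aspect_map = aspect_map,
                         passage_map = passage_map, passage2_map = passage2_map,
                         document_map = document_map,
                         stop("unknown tune_metric: ", tune_metric))
    qr_train <- dataset$qrels[dataset$qrels$query_id %in% f$train, , drop = FALSE]
    tr_scores <- vapply(tr_by_alpha, function(r)
      metric_fun(run_from_rankings(r, dataset), qr_train)$mean, numeric(1L))
    best_alpha <- alpha_grid[which.max(tr_scores)]
    c_rank <- predict_combined(model, dataset, f$test, alpha = best_alpha,
                               aspect_provider = aspect_provider)
    list(gltr = g_metrics, ltr = evaluate_rankings(c_rank, dataset),
         alpha = best_alpha)
  })
  list(gltr = (out[[1L]]$gltr + out[[2L]]$gltr) / 2,
       ltr = (out[[1L]]$ltr + out[[2L]]$ltr) / 2,
       alpha = vapply(out, `[[`, numeric(1L), "alpha"))
}

#' Gold-aspect relevance provider
#'
#' An `A_rel` provider that returns the query's gold aspect set — the
#' "topics detected on the query" convention, usable at training and
#' inference time alike so the diversity features keep one distribution.
#'
#' @return A `function(query_id, dataset)` for the `aspect_provider`
#'   arguments of [train_combined()], [predict_combined()],
#'   [compare_gltr_ltr()] and [sweep_alpha()].
#' @export
gold_aspect_provider <- function() {
  function(query_id, dataset) dataset$query_aspects[[query_id]]
}

#' Redundancy-heavy synthetic benchmark
#'
#' Generates an aspect-redundant synthetic collection per seed, builds the
#' feature dataset, and runs [compare_gltr_ltr()]; reports per-seed and mean
#' metrics for gLTR and the tuned combined model.
#'
#' @param seeds Integer vector of seeds (one benchmark replicate each).
#' @param synth A [synth_config()]; defaults to the redundancy-heavy study
#'   conditions (`redundancy = 0.6`, 20 queries).
#' @param alpha_grid Alphas to tune over.
#' @return List with `per_seed` (data.frame) and `mean` (list of mean metric
#'   vectors for `gltr` and `ltr`).
#' @export
diversity_benchmark <- function(seeds,
                                synth = synth_config(redundancy = 0.6, seed = 1L),
                                alpha_grid = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(seeds, function(s) {
    sc <- synth
    sc$seed <- as.integer(s)
    corpus <- generate_corpus(sc)
    dataset <- build_ltr_dataset(corpus)
    cfg <- train_config(seed = as.integer(s))
    res <- compare_gltr_ltr(dataset, cfg, alpha_grid = alpha_grid)
    data.frame(seed = s,
               gltr_aspect_map = res$gltr[["aspect_map"]],
               ltr_aspect_map = res$ltr[["aspect_map"]],
               gltr_document_map = res$gltr[["document_map"]],
               ltr_document_map = res$ltr[["document_map"]],
               gltr_passage_map = res$gltr[["passage_map"]],
               ltr_passage_map = res$ltr[["passage_map"]],
               gltr_passage2_map = res$gltr[["passage2_map"]],
               ltr_passage2_map = res$ltr[["passage2_map"]],
               alpha_fold1 = res$alpha[1L], alpha_fold2 = res$alpha[2L])
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean = colMeans(per_seed[, setdiff(names(per_seed), "seed")]))
}
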