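#' Linear ranking model
#'
#' A named weight vector defining the scoring function `S(p) = w . fv(p)`.
#' Weights are L1-normalized after training (scaling does not change the
#' induced ranking).
#'
#' @param weights Named numeric vector.
#' @param metric Name of the retrieval metric the model was trained to
#'   maximize (or `NA` for a hand-built model).
#' @param iterations,restarts,seed,objective Training metadata.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(weights, metric = NA_character_, iterations = NA_integer_,
                         restarts = NA_integer_, seed = NA_integer_,
                         objective = NA_real_) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(nzchar(names(weights))), all(is.finite(weights)))
  structure(list(weights = weights, metric = metric, iterations = iterations,
                 restarts = restarts, seed = seed, objective = objective),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model: %d features%s>\n", length(x$weights),
              if (!is.na(x$metric)) sprintf(", trained on %s (objective %.4f)",
                                            x$metric, x$objective) else ""))
  w <- sort(abs(x$weights), decreasing = TRUE)
  print(round(x$weights[names(w)], 4))
  invisible(x)
}

#' Write / read a model as JSON
#' @param model A [linear_model()].
#' @param path File path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(feature_names = names(model$weights),
                            weights = unname(model$weights),
                            metric = model$metric, seed = model$seed,
                            iterations = model$iterations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  linear_model(stats::setNames(as.numeric(x$weights), x$feature_names),
               metric = x$metric, seed = x$seed, iterations = x$iterations)
}

#' Score feature vectors with a linear model
#'
#' @param model A [linear_model()].
#' @param fv Named numeric vector, or a matrix whose columns include every
#'   model feature. Missing features are an error.
#' @return Numeric score(s), the dot product with the model weights.
#' @export
score_linear <- function(model, fv) {
  w <- model$weights
  if (is.matrix(fv)) {
    missing <- setdiff(names(w), colnames(fv))
    if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
    return(drop(fv[, names(w), drop = FALSE] %*% w))
  }
  missing <- setdiff(names(w), names(fv))
  if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
  sum(w * fv[names(w)])
}

#' Rank one query's candidates
#'
#' Sorts candidates by model score, descending; ties are broken by ascending
#' passage id (a stable, documented rule so rankings are reproducible).
#'
#' @param model A [linear_model()].
#' @param features Feature matrix for one query, rownames = passage ids.
#' @return A `ranked_list` data.frame with `passage_id`, `score`, `rank`
#'   (1-based, consecutive).
#' @export
rank_passages <- function(model, features) {
  stopifnot(is.matrix(features), nrow(features) >= 1L,
            !is.null(rownames(features)))
  s <- score_linear(model, features)
  ranked_list(rownames(features), s)
}

ranked_list <- function(passage_id, score) {
  o <- order(-score, passage_id)
  structure(data.frame(passage_id = passage_id[o], score = score[o],
                       rank = seq_along(o), stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Training configuration
#'
#' @param metric Retrieval metric the trainer maximizes: `"map"` (average
#'   precision over passages with positive grade), `"document_map"` (average
#'   precision over first document occurrences; requires per-passage document
#'   metadata) or `"aspect_map"` (aspect-coverage AP; requires per-passage
#'   gold aspect sets). Model selection in the cross-validation harness uses
#'   Document MAP.
#' @param grid Numeric vector of candidate weight values for the per-coordinate
#'   line search: a signed geometric grid plus 0 by default.
#' @param max_iter Maximum coordinate-ascent sweeps per restart.
#' @param tol Relative objective improvement below which a restart stops.
#' @param restarts Number of starts: the first from the best single-feature
#'   model, the rest random (seeded).
#' @param seed Mandatory integer seed; the metric surface is non-smooth and
#'   restarts are random.
#' @param folds Fold count for [cross_validate()] (2, as in the experimental
#'   protocol).
#' @param refine Logical; after convergence, one off-grid refinement pass that
#'   rescales each coordinate by small factors. Off by default so that the
#'   searched weight space stays exactly on `grid` (see the methods vignette).
#' @return A list of class `train_config`.
#' @export
train_config <- function(metric = "document_map", grid = default_weight_grid(),
                         max_iter = 25L, tol = 1e-4, restarts = 3L, seed,
                         folds = 2L, refine = FALSE) {
  if (missing(seed)) stop("seed is mandatory in train_config()")
  stopifnot(tol > 0, folds >= 2L, max_iter >= 1L, restarts >= 1L,
            is.numeric(grid), length(grid) >= 2L)
  structure(list(metric = metric, grid = sort(unique(grid)), max_iter = as.integer(max_iter),
                 tol = tol, restarts = as.integer(restarts),
                 seed = as.integer(seed), folds = as.integer(folds),
                 refine = isTRUE(refine)),
            class = "train_config")
}

#' @rdname train_config
#' @export
default_weight_grid <- function() {
  g <- c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 4)
  sort(c(-g, 0, g))
}

# ---- objective machinery -------------------------------------------------

# Precompute per-query structures so an objective evaluation is a handful of
# vector operations: score, order with the passage-id tie rule, metric kernel.
prepare_objective <- function(train_data, metric) {
  queries <- lapply(train_data, function(q) {
    X <- q$features
    stopifnot(is.matrix(X), !is.null(rownames(X)))
    tie <- rank(rownames(X), ties.method = "first")
    prep <- list(X = X, grades = q$grades, tie = tie)
    if (metric == "document_map") {
      if (is.null(q$meta) || is.null(q$meta$doc_id))
        stop("metric 'document_map' needs per-passage doc_id metadata")
      doc <- q$meta$doc_id[match(rownames(X), q$meta$passage_id)]
      prep$doc_idx <- as.integer(factor(doc))
      prep$rel_docs <- unique(prep$doc_idx[q$grades > 0])
    }
    if (metric == "aspect_map") {
      if (is.null(q$aspects))
        stop("metric 'aspect_map' needs per-passage gold aspect sets")
      prep$aspects <- q$aspects
      prep$n_gold_aspects <- length(unique(unlist(q$aspects)))
    }
    prep
  })
  if (!any(vapply(queries, function(q) any(q$grades > 0), logical(1L))))
    stop("no relevant labels anywhere: metric undefined")
  kernel <- switch(metric,
    map = function(q, ord) ap_binary(q$grades[ord] > 0),
    document_map = function(q, ord) {
      d <- q$doc_idx[ord]
      first <- !duplicated(d)
      if (!length(q$rel_docs)) return(NA_real_)
      ap_binary(d[first] %in% q$rel_docs, total_rel = length(q$rel_docs))
    },
    aspect_map = function(q, ord) {
      if (q$n_gold_aspects == 0L) return(NA_real_)
      aspect_ap_kernel(q$aspects[ord], q$n_gold_aspects)
    },
    stop("unknown training metric: ", metric))
  function(w) {
    vals <- vapply(queries, function(q) {
      s <- drop(q$X %*% w)
      ord <- order(-s, q$tie)
      kernel(q, ord)
    }, numeric(1L))
    mean(vals, na.rm = TRUE)
  }
}

# Textbook binary average precision over a relevance indicator in rank order.
ap_binary <- function(rel, total_rel = sum(rel)) {
  if (total_rel == 0) return(0)
  hits <- which(rel)
  if (!length(hits)) return(0)
  sum(seq_along(hits) / hits) / total_rel
}

# Aspect-level AP over a rank-ordered list of gold aspect sets: a passage is
# an aspect-hit iff it introduces an unseen gold aspect; k new aspects give k
# credits at precision (#aspect-hit passages so far)/rank; normalized by the
# gold aspect count.
aspect_ap_kernel <- function(aspect_sets, n_gold) {
  seen <- character()
  hit_passages <- 0L
  ap_sum <- 0
  for (i in seq_along(aspect_sets)) {
    a <- aspect_sets[[i]]
    if (!length(a)) next
    new_asp <- setdiff(a, seen)
    if (length(new_asp)) {
      hit_passages <- hit_passages + 1L
      ap_sum <- ap_sum + length(new_asp) * (hit_passages / i)
      seen <- c(seen, new_asp)
    }
  }
  ap_sum / n_gold
}

# ---- coordinate ascent ---------------------------------------------------

#' Train a linear model by metric-maximizing coordinate ascent
#'
#' Directly maximizes a rank-based retrieval metric over the weight space of
#' a linear scoring function: one coordinate at a time is replaced by each
#' value of a fixed line-search grid, the best strictly-improving replacement
#' is kept, and sweeps repeat until the relative improvement falls below
#' `tol` or `max_iter` is reached. Several restarts (best single-feature
#' start, then random starts) guard against local optima of the piecewise-
#' constant objective; the best weight vector visited anywhere is returned,
#' L1-normalized. Fully reproducible given the config seed.
#'
#' @param train_data Named list, one entry per query:
#'   `list(features = matrix, grades = numeric, meta = data.frame)` (meta with
#'   `passage_id`, `doc_id` is only needed for the document-level metric).
#' @param cfg A [train_config()].
#' @param features Optional character vector restricting training to a subset
#'   of feature columns.
#' @return A [linear_model()] with training metadata; `$objective` is the
#'   training-set value of the maximized metric.
#' @export
train_coordinate_ascent <- function(train_data, cfg, features = NULL) {
  stopifnot(inherits(cfg, "train_config"), length(train_data) >= 1L)
  feat_names <- colnames(train_data[[1L]]$features)
  if (!is.null(features)) {
    stopifnot(all(features %in% feat_names))
    train_data <- lapply(train_data, function(q) {
      q$features <- q$features[, features, drop = FALSE]; q
    })
    feat_names <- features
  }
  k <- length(feat_names)
  objective <- prepare_objective(train_data, cfg$metric)
  grid <- cfg$grid

  eval_w <- function(w) if (all(w == 0)) -Inf else objective(w)

  # start 1: best single-feature direction (sign included)
  one_hots <- list()
  for (j in seq_len(k)) for (s in c(1, -1)) {
    w <- numeric(k); w[j] <- s * max(abs(grid))
    one_hots[[length(one_hots) + 1L]] <- w
  }
  oh_obj <- vapply(one_hots, eval_w, numeric(1L))
  starts <- list(one_hots[[which.max(oh_obj)]])
  gmax <- max(abs(grid))
  extra <- withr::with_seed(cfg$seed, {
    lapply(seq_len(max(0L, cfg$restarts - 1L)), function(i) {
      w <- stats::runif(k, -gmax, gmax)
      # snap random starts onto the grid so the searched space stays on it
      vapply(w, function(v) grid[which.min(abs(grid - v))], numeric(1L))
    })
  })
  starts <- c(starts, extra)

  best_w <- starts[[1L]]
  best_obj <- -Inf
  total_iter <- 0L
  trace <- list()  # accepted objective values per restart (ascent audit)
  for (w in starts) {
    obj <- eval_w(w)
    if (obj > best_obj) { best_obj <- obj; best_w <- w }
    restart_trace <- obj
    for (iter in seq_len(cfg$max_iter)) {
      sweep_start <- obj
      for (j in seq_len(k)) {
        cand_obj <- obj
        cand_v <- w[j]
        for (v in grid) {
          if (v == w[j]) next
          w2 <- w; w2[j] <- v
          o2 <- eval_w(w2)
          if (o2 > cand_obj + 1e-12) { cand_obj <- o2; cand_v <- v }
        }
        if (cand_v != w[j]) {
          w[j] <- cand_v
          obj <- cand_obj
          restart_trace <- c(restart_trace, obj)
          if (obj > best_obj) { best_obj <- obj; best_w <- w }
        }
      }
      total_iter <- total_iter + 1L
      if ((obj - sweep_start) <= cfg$tol * max(abs(sweep_start), 1e-12)) break
    }
    trace[[length(trace) + 1L]] <- restart_trace
    if (cfg$refine) {
      for (j in seq_len(k)) {
        if (w[j] == 0) next
        for (f in c(0.5, 0.8, 1.25, 2)) {
          w2 <- w; w2[j] <- w[j] * f
          o2 <- eval_w(w2)
          if (o2 > obj + 1e-12) {
            w <- w2; obj <- o2
            if (obj > best_obj) { best_obj <- obj; best_w <- w }
          }
        }
      }
    }
  }
  wn <- best_w / sum(abs(best_w))
  model <- linear_model(stats::setNames(wn, feat_names), metric = cfg$metric,
                        iterations = total_iter, restarts = cfg$restarts,
                        seed = cfg$seed, objective = best_obj)
  model$trace <- trace
  model
}

#' Greedy feature introduction ("greedy boosting")
#'
#' Features are introduced one at a time: each round, every unused feature is
#' tried by running coordinate ascent on the augmented subset, and the best
#' addition is kept only if it improves the training objective. Stops when no
#' addition helps. This is the model-building procedure used with 2-fold
#' cross-validated model selection in the experimental protocol; plain
#' [train_coordinate_ascent()] over all features reaches the same training
#' objective on our benchmarks at lower cost and is the default elsewhere.
#'
#' @inheritParams train_coordinate_ascent
#' @return A [linear_model()] over the full feature set (unused features get
#'   weight 0).
#' @export
train_greedy <- function(train_data, cfg) {
  feat_names <- colnames(train_data[[1L]]$features)
  chosen <- character()
  best_model <- NULL
  best_obj <- -Inf
  repeat {
    remaining <- setdiff(feat_names, chosen)
    if (!length(remaining)) break
    round_best <- NULL
    round_obj <- best_obj
    round_feat <- NULL
    for (f in remaining) {
      m <- train_coordinate_ascent(train_data, cfg, features = c(chosen, f))
      if (m$objective > round_obj + 1e-12) {
        round_obj <- m$objective; round_best <- m; round_feat <- f
      }
    }
    if (is.null(round_best)) break
    chosen <- c(chosen, round_feat)
    best_model <- round_best
    best_obj <- round_obj
  }
  if (is.null(best_model))
    best_model <- train_coordinate_ascent(train_data, cfg,
                                          features = feat_names[1L])
  w <- stats::setNames(numeric(length(feat_names)), feat_names)
  w[names(best_model$weights)] <- best_model$weights
  linear_model(w, metric = cfg$metric, iterations = best_model$iterations,
               restarts = cfg$restarts, seed = cfg$seed,
               objective = best_model$objective)
}

# ---- cross-validation ----------------------------------------------------

#' Bundle queries, judgments and annotations into a dataset
#'
#' @param queries Named list, one entry per query id:
#'   `list(query = tokens, features = matrix, grades = numeric,
#'   meta = data.frame(passage_id, doc_id, start, length))`.
#' @param qrels Judgment data.frame ([read_qrels()] layout).
#' @param annotations Named list `passage_id -> character vector` of aspect
#'   ids (may be `NULL` when no diversity modeling is wanted).
#' @param query_aspects Named list `query_id -> character vector` of gold
#'   aspect ids.
#' @return A list of class `ltr_dataset`.
#' @export
ltr_dataset <- function(queries, qrels, annotations = NULL, query_aspects = NULL) {
  stopifnot(is.list(queries), length(names(queries)) == length(queries),
            is.data.frame(qrels))
  structure(list(queries = queries, qrels = qrels, annotations = annotations,
                 query_aspects = query_aspects),
            class = "ltr_dataset")
}

#' @export
print.ltr_dataset <- function(x, ...) {
  cat(sprintf("<ltr_dataset: %d queries, %d judged spans%s>\n",
              length(x$queries), nrow(x$qrels),
              if (!is.null(x$annotations)) sprintf(", %d annotated passages",
                                                   length(x$annotations)) else ""))
  invisible(x)
}

split_queries <- function(qids, seed) {
  stopifnot(length(qids) >= 2L)
  withr::with_seed(seed, {
    half <- sample(qids, floor(length(qids) / 2))
  })
  list(a = sort(half), b = sort(setdiff(qids, half)))
}

run_from_rankings <- function(rankings, dataset, tag = "divrank") {
  rows <- lapply(names(rankings), function(qid) {
    r <- rankings[[qid]]
    meta <- dataset$queries[[qid]]$meta
    m <- meta[match(r$passage_id, meta$passage_id), , drop = FALSE]
    data.frame(query_id = qid, doc_id = m$doc_id, start = m$start,
               length = m$length, rank = r$rank, score = r$score, tag = tag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

evaluate_rankings <- function(rankings, dataset) {
  run <- run_from_rankings(rankings, dataset)
  qr <- dataset$qrels[dataset$qrels$query_id %in% names(rankings), , drop = FALSE]
  c(aspect_map = aspect_map(run, qr)$mean,
    passage_map = passage_map(run, qr)$mean,
    passage2_map = passage2_map(run, qr)$mean,
    document_map = document_map(run, qr)$mean)
}

#' Two-fold cross-validation of the general ranking model
#'
#' Topics are split randomly in half (seeded); a model is trained on each
#' half by coordinate ascent (selection metric from `cfg`, Document MAP by
#' default) and evaluated on the complementary half with all four MAP
#' metrics; the report averages the two test halves.
#'
#' @param dataset An [ltr_dataset()].
#' @param cfg A [train_config()].
#' @return List with `split`, per-fold `models` and `metrics`, and the
#'   averaged `metrics`.
#' @export
cross_validate <- function(dataset, cfg) {
  stopifnot(inherits(dataset, "ltr_dataset"))
  qids <- names(dataset$queries)
  if (length(qids) < cfg$folds) stop("fewer queries than folds")
  sp <- split_queries(qids, cfg$seed)
  folds <- list(list(train = sp$a, test = sp$b),
                list(train = sp$b, test = sp$a))
  fold_out <- lapply(folds, function(f) {
    model <- train_coordinate_ascent(dataset$queries[f$train], cfg)
    rankings <- lapply(dataset$queries[f$test], function(q)
      rank_passages(model, q$features))
    names(rankings) <- f$test
    list(model = model, metrics = evaluate_rankings(rankings, dataset),
         test = f$test)
  })
  metrics <- colMeans(do.call(rbind, lapply(fold_out, `[[`, "metrics")))
  list(split = sp, folds = fold_out, metrics = metrics)
}
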