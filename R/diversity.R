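#' Extract diversity features from an initial ranking
#'
#' The seven ranking-list-derived aspect features, computed once from the
#' initial ranking produced by the general model ("once for all" strategy).
#' Walking ranks `i = 1..n` with `Seen(i)` the union of aspects of ranks
#' `< i`:
#'
#' * `RelAsp` = number of the passage's aspects that are relevant
#'   (`|A(p) intersect A_rel|`), `NonRelAsp` the rest;
#' * `NewRelAsp` = relevant aspects of the passage not in `Seen(i)`,
#'   `OldRelAsp = RelAsp - NewRelAsp`;
#' * `NewAspPsg` = fraction of prior-ranked passages that introduced at
#'   least one unseen aspect (of any kind) at their own rank; 0 at rank 1;
#' * `PctRelAsp` = relevant-aspect occurrences among all aspect occurrences
#'   before the current rank (with multiplicity), 0 when nothing precedes;
#' * `PctUniqRelAsp` = `|Seen(i) intersect A_rel| / |Seen(i)|`, 0 when
#'   `Seen(i)` is empty.
#'
#' @param ranked A `ranked_list` (see [rank_passages()]) or a character
#'   vector of passage ids in rank order.
#' @param annotations Named list `passage_id -> character vector` of aspect
#'   ids; every ranked passage must be present (an empty set is fine).
#' @param a_rel Character vector of aspects considered relevant for the
#'   query. Defaults to all aspects observed among the ranked passages (the
#'   no-provider inference convention).
#' @return Numeric matrix, one row per passage in rank order (rownames =
#'   passage ids), columns [diversity_feature_names()].
#' @export
extract_diversity_features <- function(ranked, annotations, a_rel = NULL) {
  pids <- if (is.data.frame(ranked)) as.character(ranked$passage_id)
          else as.character(ranked)
  missing <- pids[!(pids %in% names(annotations))]
  if (length(missing))
    stop("unannotated passage(s): ", paste(missing, collapse = ", "))
  asp <- annotations[pids]
  if (is.null(a_rel)) a_rel <- unique(unlist(asp))
  n <- length(pids)
  mat <- matrix(0, nrow = n, ncol = 7L,
                dimnames = list(pids, diversity_feature_names()))
  seen <- character()
  new_asp_count <- 0L      # prior passages that introduced an unseen aspect
  rel_occ <- 0L            # relevant-aspect occurrences before current rank
  all_occ <- 0L            # all aspect occurrences before current rank
  for (i in seq_len(n)) {
    a <- unique(asp[[i]])
    rel <- intersect(a, a_rel)
    new_rel <- setdiff(rel, seen)
    mat[i, "RelAsp"] <- length(rel)
    mat[i, "NonRelAsp"] <- length(a) - length(rel)
    mat[i, "NewRelAsp"] <- length(new_rel)
    mat[i, "OldRelAsp"] <- length(rel) - length(new_rel)
    mat[i, "NewAspPsg"] <- if (i == 1L) 0 else new_asp_count / (i - 1L)
    mat[i, "PctRelAsp"] <- if (all_occ == 0L) 0 else rel_occ / all_occ
    mat[i, "PctUniqRelAsp"] <- if (!length(seen)) 0 else
      length(intersect(seen, a_rel)) / length(seen)
    if (length(setdiff(a, seen))) new_asp_count <- new_asp_count + 1L
    seen <- union(seen, a)
    rel_occ <- rel_occ + length(rel)
    all_occ <- all_occ + length(a)
  }
  mat
}

#' Build the extended (15-feature) training matrix
#'
#' Concatenates the eight general features with the seven diversity features
#' for the same (query, passage) keys, in the documented column order
#' (columns 1-8 general, 9-15 diversity).
#'
#' @param general Numeric matrix of general features (rownames = passage ids).
#' @param diversity Numeric matrix of diversity features for the same
#'   passages (any row order; keys must match exactly).
#' @return Numeric matrix with 15 columns, rows in the order of `general`.
#' @export
build_diversity_training_set <- function(general, diversity) {
  stopifnot(is.matrix(general), is.matrix(diversity),
            !is.null(rownames(general)), !is.null(rownames(diversity)))
  if (!setequal(rownames(general), rownames(diversity)))
    stop("general and diversity features cover different (query, passage) keys")
  out <- cbind(general[, general_feature_names(), drop = FALSE],
               diversity[rownames(general), diversity_feature_names(),
                         drop = FALSE])
  out
}

#' Combination configuration
#'
#' @param alpha Weight of the general model in `[0, 1]`; the diversity-biased
#'   model gets `beta = 1 - alpha` exactly. The empirical setting suggested
#'   when no training data is available is `alpha = 0.7` (the 0.6-0.8 band).
#' @return A list of class `combine_config` with `alpha` and `beta`.
#' @export
combine_config <- function(alpha = 0.7) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  structure(list(alpha = alpha, beta = 1 - alpha), class = "combine_config")
}

#' Combine general and diversity-biased scores
#'
#' The combined model score `alpha * g + (1 - alpha) * d`. In the ranking
#' pipeline this is applied to per-query min-max-normalized scores of each
#' model (see [combine_rankings()]); `combine_scores()` itself is the plain
#' arithmetic combination.
#'
#' @param g,d Numeric score vectors of equal length.
#' @param cfg A [combine_config()] (or a bare alpha value).
#' @return Numeric vector of combined scores.
#' @export
combine_scores <- function(g, d, cfg) {
  if (!inherits(cfg, "combine_config")) cfg <- combine_config(cfg)
  stopifnot(length(g) == length(d))
  cfg$alpha * g + cfg$beta * d
}

#' Min-max normalize scores to [0, 1]
#'
#' Per-query normalization applied to each model's scores before combining;
#' a constant score vector maps to 0.5 everywhere (any constant preserves
#' the tie).
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1L]) / diff(rng)
}

#' Combine two rankings of the same candidates
#'
#' Min-max normalizes each model's scores per query, mixes them with
#' `alpha`/`1 - alpha`, and re-ranks (ties by ascending passage id, the same
#' rule as [rank_passages()]). At `alpha = 1` this reproduces the general
#' model's ranking item for item, at `alpha = 0` the diversity-biased one.
#'
#' @param g_ranked,d_ranked `ranked_list`s over the same passage ids.
#' @param cfg A [combine_config()] (or a bare alpha value).
#' @return A `ranked_list` of the combined model.
#' @export
combine_rankings <- function(g_ranked, d_ranked, cfg) {
  if (!inherits(cfg, "combine_config")) cfg <- combine_config(cfg)
  if (!setequal(g_ranked$passage_id, d_ranked$passage_id))
    stop("rankings cover different passages")
  pids <- g_ranked$passage_id
  g <- minmax_normalize(g_ranked$score)
  d <- minmax_normalize(d_ranked$score[match(pids, d_ranked$passage_id)])
  ranked_list(pids, combine_scores(g, d, cfg))
}
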