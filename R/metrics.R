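#' TREC-Genomics-style retrieval metrics
#'
#' Four levels of mean average precision over a run and gold judgments, all
#' macro-averaged over queries and all in `[0, 1]`. Character spans are
#' 0-based half-open; a retrieved passage is relevant iff it overlaps (by at
#' least one character) a gold span with positive grade in the same document;
#' unjudged material is non-relevant.
#'
#' * `document_map()`: the run is collapsed to the first occurrence of each
#'   document; standard average precision over documents, a document being
#'   relevant iff it carries any positively graded gold span.
#' * `passage_map()`: passage-granularity character-overlap AP. Walking the
#'   ranked passages, a passage is a hit iff it contributes at least one gold
#'   character not yet retrieved; precision at a hit is (cumulative gold
#'   characters retrieved) / (cumulative characters retrieved), and
#'   AP = sum(new gold chars at hit * precision) / total gold characters.
#' * `passage2_map()`: character-granularity AP. Retrieved passages are
#'   exploded into their characters in rank order; a character is a hit iff it
#'   lies in a gold span of its document and was not previously retrieved;
#'   AP over this character sequence with total relevant = total gold
#'   characters.
#' * `aspect_map()`: a ranked passage is an aspect-hit at rank i iff it is
#'   relevant and contributes at least one gold aspect unseen at earlier
#'   ranks; a passage introducing k new aspects contributes k credits at its
#'   rank, each at precision (number of aspect-hit passages at ranks <= i)/i,
#'   normalized by the size of the query's gold aspect set. Queries whose
#'   gold aspect set is empty are skipped with a warning.
#'
#' @param run Run data.frame ([read_run()] layout).
#' @param qrels Judgment data.frame ([read_qrels()] layout).
#' @return List with `per_query` (named numeric) and `mean` (macro average).
#'   Queries judged but absent from the run score 0 with a warning.
#' @name retrieval_metrics
NULL

metric_queries <- function(run, qrels, need_aspects = FALSE) {
  qids <- unique(qrels$query_id)
  if (need_aspects) {
    has_asp <- vapply(qids, function(q) {
      g <- qrels[qrels$query_id == q & qrels$grade > 0, , drop = FALSE]
      length(unlist(g$aspects)) > 0
    }, logical(1L))
    if (any(!has_asp))
      warning("queries with empty gold aspect set skipped: ",
              paste(qids[!has_asp], collapse = ", "))
    qids <- qids[has_asp]
  }
  absent <- setdiff(qids, unique(run$query_id))
  if (length(absent))
    warning("queries judged but absent from run score 0: ",
            paste(absent, collapse = ", "))
  qids
}

macro <- function(per_query) {
  list(per_query = per_query,
       mean = if (length(per_query)) mean(per_query) else NA_real_)
}

#' @rdname retrieval_metrics
#' @export
document_map <- function(run, qrels) {
  qids <- metric_queries(run, qrels)
  ap <- vapply(qids, function(q) {
    gold <- qrels[qrels$query_id == q, , drop = FALSE]
    rel_docs <- unique(gold$doc_id[gold$grade > 0])
    if (!length(rel_docs)) return(NA_real_)
    r <- run[run$query_id == q, , drop = FALSE]
    if (!nrow(r)) return(0)
    docs <- r$doc_id[order(r$rank)]
    docs <- docs[!duplicated(docs)]
    ap_binary(docs %in% rel_docs, total_rel = length(rel_docs))
  }, numeric(1L))
  macro(ap[!is.na(ap)])
}

# Per-document logical character masks: gold coverage (positively graded
# spans, merged) sized to cover every span the run or the judgments mention.
gold_masks <- function(gold, r) {
  docs <- unique(c(gold$doc_id, r$doc_id))
  ends <- vapply(docs, function(d)
    max(0L, gold$start[gold$doc_id == d] + gold$length[gold$doc_id == d],
        r$start[r$doc_id == d] + r$length[r$doc_id == d]), numeric(1L))
  masks <- lapply(ends, function(n) logical(n))
  names(masks) <- docs
  pos <- gold[gold$grade > 0 & gold$length > 0, , drop = FALSE]
  for (i in seq_len(nrow(pos))) {
    d <- pos$doc_id[i]
    masks[[d]][seq.int(pos$start[i] + 1L, pos$start[i] + pos$length[i])] <- TRUE
  }
  masks
}

#' @rdname retrieval_metrics
#' @export
passage_map <- function(run, qrels) {
  qids <- metric_queries(run, qrels)
  ap <- vapply(qids, function(q) {
    gold <- qrels[qrels$query_id == q, , drop = FALSE]
    r <- run[run$query_id == q, , drop = FALSE]
    gold_cov <- gold_masks(gold, r)
    total_gold <- sum(vapply(gold_cov, sum, numeric(1L)))
    if (total_gold == 0) return(NA_real_)
    if (!nrow(r)) return(0)
    r <- r[order(r$rank), , drop = FALSE]
    seen <- lapply(gold_cov, function(m) logical(length(m)))
    cum_chars <- 0; cum_gold <- 0; ap_sum <- 0
    for (i in seq_len(nrow(r))) {
      d <- r$doc_id[i]
      idx <- seq.int(r$start[i] + 1L, r$start[i] + r$length[i])
      new_gold <- sum(gold_cov[[d]][idx] & !seen[[d]][idx])
      cum_chars <- cum_chars + r$length[i]
      cum_gold <- cum_gold + new_gold
      if (new_gold > 0) ap_sum <- ap_sum + new_gold * (cum_gold / cum_chars)
      seen[[d]][idx] <- TRUE
    }
    ap_sum / total_gold
  }, numeric(1L))
  macro(ap[!is.na(ap)])
}

#' @rdname retrieval_metrics
#' @export
passage2_map <- function(run, qrels) {
  qids <- metric_queries(run, qrels)
  ap <- vapply(qids, function(q) {
    gold <- qrels[qrels$query_id == q, , drop = FALSE]
    r <- run[run$query_id == q, , drop = FALSE]
    gold_cov <- gold_masks(gold, r)
    total_gold <- sum(vapply(gold_cov, sum, numeric(1L)))
    if (total_gold == 0) return(NA_real_)
    if (!nrow(r)) return(0)
    r <- r[order(r$rank), , drop = FALSE]
    seen <- lapply(gold_cov, function(m) logical(length(m)))
    pos <- 0L; hits <- 0L; ap_sum <- 0
    for (i in seq_len(nrow(r))) {
      d <- r$doc_id[i]
      idx <- seq.int(r$start[i] + 1L, r$start[i] + r$length[i])
      is_hit <- gold_cov[[d]][idx] & !seen[[d]][idx]
      if (any(is_hit)) {
        hit_pos <- pos + which(is_hit)
        ap_sum <- ap_sum + sum((hits + seq_along(hit_pos)) / hit_pos)
        hits <- hits + length(hit_pos)
      }
      pos <- pos + length(idx)
      seen[[d]][idx] <- TRUE
    }
    ap_sum / total_gold
  }, numeric(1L))
  macro(ap[!is.na(ap)])
}

#' @rdname retrieval_metrics
#' @export
aspect_map <- function(run, qrels) {
  qids <- metric_queries(run, qrels, need_aspects = TRUE)
  ap <- vapply(qids, function(q) {
    gold <- qrels[qrels$query_id == q, , drop = FALSE]
    gold_pos <- gold[gold$grade > 0, , drop = FALSE]
    gold_aspects <- sort(unique(unlist(gold_pos$aspects)))
    r <- run[run$query_id == q, , drop = FALSE]
    if (!nrow(r)) return(0)
    r <- r[order(r$rank), , drop = FALSE]
    g_end <- gold_pos$start + gold_pos$length
    seen <- character()
    hit_passages <- 0L
    ap_sum <- 0
    for (i in seq_len(nrow(r))) {
      ov <- gold_pos$doc_id == r$doc_id[i] &
        gold_pos$start < r$start[i] + r$length[i] & g_end > r$start[i]
      if (!any(ov)) next
      asp <- unique(unlist(gold_pos$aspects[ov]))
      new_asp <- setdiff(asp, seen)
      if (length(new_asp)) {
        hit_passages <- hit_passages + 1L
        ap_sum <- ap_sum + length(new_asp) * (hit_passages / i)
        seen <- c(seen, new_asp)
      }
    }
    ap_sum / length(gold_aspects)
  }, numeric(1L))
  macro(ap)
}

#' Evaluate a run on all four metrics
#'
#' @inheritParams retrieval_metrics
#' @return Named numeric vector with the macro-averaged `aspect_map`,
#'   `passage_map`, `passage2_map`, `document_map`.
#' @export
evaluate_run <- function(run, qrels) {
  c(aspect_map = aspect_map(run, qrels)$mean,
    passage_map = passage_map(run, qrels)$mean,
    passage2_map = passage2_map(run, qrels)$mean,
    document_map = document_map(run, qrels)$mean)
}
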