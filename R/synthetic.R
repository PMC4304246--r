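#' Synthetic collection configuration
#'
#' Conditions for the seeded generator of aspect-labeled synthetic passage
#' collections. Defaults emulate a small TREC-Genomics-style workload: 20
#' topics, 4 gold aspects each, 30 candidate passages per topic of ~40 tokens,
#' ~30% of candidates relevant, moderate background noise. `redundancy` is
#' the probability that a relevant passage repeats an already-used gold
#' aspect instead of introducing a new one (0 = every relevant passage brings
#' a new aspect until the gold set is exhausted; 1 = a single aspect is
#' repeated throughout).
#'
#' @param num_queries Number of topics.
#' @param num_aspects_per_query Gold aspects per topic.
#' @param passages_per_query Candidate passages generated per topic.
#' @param vocab_size Total vocabulary size; each gold aspect owns a disjoint
#'   5-term cluster carved out of it and the remainder is shared background.
#' @param passage_len Tokens per passage.
#' @param redundancy Probability in `[0, 1]` of repeating a used aspect.
#' @param relevance_rate Fraction of a topic's passages that are relevant.
#' @param noise_rate Fraction of a relevant passage's tokens drawn from the
#'   background vocabulary rather than its aspect clusters.
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(num_queries = 20L, num_aspects_per_query = 4L,
                         passages_per_query = 30L, vocab_size = 600L,
                         passage_len = 30L, redundancy = 0.5,
                         relevance_rate = 0.3, noise_rate = 0.6, seed) {
  if (missing(seed)) stop("seed is mandatory in synth_config()")
  stopifnot(num_queries >= 1L, num_aspects_per_query >= 1L,
            passages_per_query >= 2L, passage_len >= 2L,
            redundancy >= 0, redundancy <= 1,
            relevance_rate > 0, relevance_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(num_queries = as.integer(num_queries),
                 num_aspects_per_query = as.integer(num_aspects_per_query),
                 passages_per_query = as.integer(passages_per_query),
                 vocab_size = as.integer(vocab_size),
                 passage_len = as.integer(passage_len),
                 redundancy = redundancy, relevance_rate = relevance_rate,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synth_config")
}

CLUSTER_SIZE <- 5L
NOISE_ASPECTS_PER_QUERY <- 3L

pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a synthetic aspect-labeled passage collection
#'
#' Each topic gets a gold aspect set; each gold aspect owns a disjoint
#' cluster of `r CLUSTER_SIZE` vocabulary terms. The topic's query samples
#' two terms from every gold cluster. Relevant passages are assigned one or
#' two gold aspects (aspect reuse governed by `redundancy`) and draw their
#' tokens from a mixture of the assigned clusters and background; every
#' passage also carries detected-topic annotations: relevant passages their
#' gold aspects (occasionally plus a per-topic noise aspect), non-relevant
#' passages one or two noise aspects. Passages are grouped five to a
#' document with paragraph breaks between them, so the corpus exercises the
#' extraction and overlap-transfer machinery end to end. Deterministic per
#' seed.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_corpus`: `documents` (list of
#'   [document()]), `passages` (data.frame with tokens), `queries` (named
#'   list of token vectors), `candidates` (named list query -> passage ids),
#'   `qrels`, `annotations`, `query_aspects`, and the generating `config`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_clusters <- cfg$num_queries * cfg$num_aspects_per_query
  need <- n_clusters * CLUSTER_SIZE + 10L
  if (cfg$vocab_size < need)
    stop(sprintf("vocab_size %d too small for %d aspect clusters (need >= %d)",
                 cfg$vocab_size, n_clusters, need))
  vocab <- sprintf("w%04d", seq_len(cfg$vocab_size))
  cluster_terms <- split(vocab[seq_len(n_clusters * CLUSTER_SIZE)],
                         rep(seq_len(n_clusters), each = CLUSTER_SIZE))
  background <- vocab[(n_clusters * CLUSTER_SIZE + 1L):cfg$vocab_size]

  withr::with_seed(cfg$seed, {
    queries <- list(); query_aspects <- list(); candidates <- list()
    qrels_rows <- list(); annotations <- list()
    passage_rows <- list(); documents <- list()
    cluster_idx <- 0L
    n_rel <- max(1L, round(cfg$relevance_rate * cfg$passages_per_query))

    for (qi in seq_len(cfg$num_queries)) {
      qid <- sprintf("q%03d", qi)
      aspects <- sprintf("%s_a%d", qid, seq_len(cfg$num_aspects_per_query))
      clusters <- stats::setNames(
        cluster_terms[cluster_idx + seq_along(aspects)], aspects)
      cluster_idx <- cluster_idx + length(aspects)
      noise_aspects <- sprintf("%s_x%d", qid, seq_len(NOISE_ASPECTS_PER_QUERY))
      queries[[qid]] <- unlist(lapply(clusters, function(cl) sample(cl, 2L)),
                               use.names = FALSE)
      query_aspects[[qid]] <- aspects

      is_rel <- c(rep(TRUE, n_rel),
                  rep(FALSE, cfg$passages_per_query - n_rel))
      used <- character()
      pass_tokens <- list(); pass_rel <- logical(); pass_aspects <- list()
      pass_grade <- numeric(); pass_ann <- list()
      for (pi in seq_len(cfg$passages_per_query)) {
        if (is_rel[pi]) {
          draw_aspect <- function() {
            unused <- setdiff(aspects, used)
            pick_new <- length(unused) > 0L &&
              (length(used) == 0L || stats::runif(1L) >= cfg$redundancy)
            if (pick_new) pick1(unused) else pick1(used)
          }
          a <- draw_aspect()
          used <- union(used, a)
          pa <- a
          if (stats::runif(1L) < 0.25) {
            a2 <- draw_aspect()
            used <- union(used, a2)
            pa <- union(pa, a2)
          }
          pool <- unlist(clusters[pa], use.names = FALSE)
          from_bg <- stats::runif(cfg$passage_len) < cfg$noise_rate
          toks <- ifelse(from_bg,
                         sample(background, cfg$passage_len, replace = TRUE),
                         sample(pool, cfg$passage_len, replace = TRUE))
          # occasionally place two query terms adjacently (proximity signal)
          if (stats::runif(1L) < 0.5 && cfg$passage_len >= 3L) {
            k <- sample.int(cfg$passage_len - 1L, 1L)
            toks[k:(k + 1L)] <- sample(queries[[qid]], 2L)
          }
          ann <- pa
          if (stats::runif(1L) < 0.2) ann <- union(ann, pick1(noise_aspects))
          grade <- if (stats::runif(1L) < 0.2) 2 else 1
        } else {
          # distractor mixture: non-relevant passages still mention query
          # topics occasionally, at a quarter of the relevant cluster share,
          # so lexical separation is imperfect (as in real collections)
          all_cluster <- unlist(clusters, use.names = FALSE)
          from_cl <- stats::runif(cfg$passage_len) <
            0.5 * (1 - cfg$noise_rate)
          toks <- ifelse(from_cl,
                         sample(all_cluster, cfg$passage_len, replace = TRUE),
                         sample(background, cfg$passage_len, replace = TRUE))
          pa <- character()
          ann <- sample(noise_aspects, 1L + (stats::runif(1L) < 0.5))
          grade <- 0
        }
        pass_tokens[[pi]] <- toks
        pass_rel[pi] <- is_rel[pi]
        pass_aspects[[pi]] <- pa
        pass_grade[pi] <- grade
        pass_ann[[pi]] <- sort(ann)
      }
      # pack passages five to a document in generation order, paragraph
      # breaks between them (ranking order is feature-driven, so the on-disk
      # order carries no relevance signal)
      per_doc <- 5L
      doc_of <- ceiling(seq_len(cfg$passages_per_query) / per_doc)
      qcand <- character()
      for (di in unique(doc_of)) {
        sel <- which(doc_of == di)
        doc_id <- sprintf("%s_d%02d", qid, di)
        texts <- vapply(pass_tokens[sel], paste, character(1L), collapse = " ")
        full <- paste(texts, collapse = " ")
        # break offsets: after each passage plus its trailing separator space
        ends <- cumsum(nchar(texts) + 1L)
        breaks <- ends[-length(ends)]
        documents[[doc_id]] <- document(doc_id, full, breaks)
        starts <- c(0L, breaks)
        for (k in seq_along(sel)) {
          i <- sel[k]
          pid <- sprintf("%s_p%03d", doc_id, k)
          passage_rows[[pid]] <- data.frame(
            passage_id = pid, doc_id = doc_id, start = starts[k],
            length = nchar(texts[k]), text = texts[k],
            stringsAsFactors = FALSE)
          annotations[[pid]] <- pass_ann[[i]]
          qcand <- c(qcand, pid)
          if (pass_rel[i]) {
            qrels_rows[[length(qrels_rows) + 1L]] <- data.frame(
              query_id = qid, doc_id = doc_id, start = starts[k],
              length = nchar(texts[k]), grade = pass_grade[i],
              aspects = I(list(sort(pass_aspects[[i]]))),
              stringsAsFactors = FALSE)
          }
        }
      }
      candidates[[qid]] <- qcand
    }

    passages <- do.call(rbind, passage_rows)
    rownames(passages) <- NULL
    passages <- tokenize_passages(passages)
    structure(list(documents = documents, passages = passages,
                   queries = queries, candidates = candidates,
                   qrels = do.call(rbind, qrels_rows),
                   annotations = annotations, query_aspects = query_aspects,
                   config = cfg),
              class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf(paste0("<synth_corpus: %d queries, %d documents, %d passages, ",
                     "%d judged spans, redundancy %.2f, seed %d>\n"),
              length(x$queries), length(x$documents), nrow(x$passages),
              nrow(x$qrels), x$config$redundancy, x$config$seed))
  invisible(x)
}

#' Write a synthetic collection to disk
#'
#' Emits the module file formats: `corpus.jsonl`, `qrels.txt`,
#' `annotations.tsv` (`passage_id <TAB> aspect1,aspect2`), `query_aspects.tsv`
#' (`query_id <TAB> aspects`), `queries.tsv` (`query_id <TAB> tokens`) and
#' the 8-column `general.letor` feature file. Byte-identical for a fixed
#' config seed.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @param params [feature_params()] for the LETOR file.
#' @return `dir`, invisibly.
#' @export
write_synth_corpus <- function(corpus, dir, params = feature_params()) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus_jsonl(corpus$documents, file.path(dir, "corpus.jsonl"))
  write_qrels(corpus$qrels, file.path(dir, "qrels.txt"))
  write_annotations(corpus$annotations, file.path(dir, "annotations.tsv"))
  write_annotations(corpus$query_aspects, file.path(dir, "query_aspects.tsv"))
  writeLines(sprintf("%s\t%s", names(corpus$queries),
                     vapply(corpus$queries, paste, character(1L), collapse = " ")),
             file.path(dir, "queries.tsv"))
  dataset <- build_ltr_dataset(corpus, params)
  write_letor(dataset$queries, file.path(dir, "general.letor"))
  invisible(dir)
}

#' Read / write aspect annotation tables
#'
#' TSV with two columns: an identifier (passage or query id) and a
#' comma-separated aspect list (`-` for the empty set).
#'
#' @param path File path.
#' @return `read_annotations()`: named list of character vectors.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop(sprintf("malformed annotation line %d", bad[1L]))
  m <- do.call(rbind, parts)
  stats::setNames(lapply(m[, 2L], function(a)
    if (a == "-") character() else strsplit(a, ",", fixed = TRUE)[[1L]]),
    m[, 1L])
}

#' @rdname read_annotations
#' @param annotations Named list of character vectors.
#' @export
write_annotations <- function(annotations, path) {
  vals <- vapply(annotations, function(a)
    if (length(a)) paste(a, collapse = ",") else "-", character(1L))
  writeLines(sprintf("%s\t%s", names(annotations), vals), path)
  invisible(path)
}

#' Build the feature dataset from a synthetic collection
#'
#' Indexes all passages, extracts the eight general features for every
#' query's candidate set and transfers the gold relevance onto the extracted
#' passages.
#'
#' @param corpus A [generate_corpus()] result.
#' @param params A [feature_params()].
#' @param config A [tokenizer_config()] used to tokenize queries/passages
#'   (the generator's token streams are already canonical).
#' @return An [ltr_dataset()] ready for [cross_validate()], [sweep_alpha()]
#'   and friends.
#' @export
build_ltr_dataset <- function(corpus, params = feature_params(),
                              config = tokenizer_config()) {
  stopifnot(inherits(corpus, "synth_corpus"))
  index <- build_index(corpus$passages)
  queries <- lapply(names(corpus$queries), function(qid) {
    cand <- corpus$candidates[[qid]]
    feats <- extract_general_features(corpus$queries[[qid]], cand, index, params)
    meta <- corpus$passages[match(cand, corpus$passages$passage_id),
                            c("passage_id", "doc_id", "start", "length")]
    labeled <- transfer_relevance(meta, corpus$qrels, qid)
    list(query = corpus$queries[[qid]], features = feats,
         grades = labeled$grade, aspects = labeled$aspects, meta = meta)
  })
  names(queries) <- names(corpus$queries)
  ltr_dataset(queries, corpus$qrels, annotations = corpus$annotations,
              query_aspects = corpus$query_aspects)
}

#' Planted-model fixture for the coordinate-ascent learner
#'
#' Labeled feature matrices where one designated feature equals the
#' relevance grade plus Gaussian noise and the remaining features are
#' uninformative noise — the separable recovery fixture: with `noise_sd = 0`
#' a one-hot model on the planted feature ranks every relevant passage first
#' and training MAP reaches 1.
#'
#' @param num_queries,passages_per_query Problem size.
#' @param planted Name of the planted feature (one of
#'   [general_feature_names()]).
#' @param noise_sd Standard deviation of the noise added to the planted
#'   feature.
#' @param relevance_rate Fraction of relevant passages per query.
#' @param seed Mandatory integer seed.
#' @return Named list per query of `list(features, grades, meta)`, directly
#'   usable as [train_coordinate_ascent()] input.
#' @export
generate_separable_ltr_set <- function(num_queries = 10L,
                                       passages_per_query = 20L,
                                       planted = "BM25", noise_sd = 0.05,
                                       relevance_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(planted %in% general_feature_names(), noise_sd >= 0)
  withr::with_seed(seed, {
    out <- lapply(seq_len(num_queries), function(qi) {
      n <- passages_per_query
      grades <- as.numeric(stats::runif(n) < relevance_rate)
      if (!any(grades > 0)) grades[sample.int(n, 1L)] <- 1
      feats <- matrix(stats::rnorm(n * 8L, sd = 0.5), nrow = n,
                      dimnames = list(sprintf("q%03d_p%03d", qi, seq_len(n)),
                                      general_feature_names()))
      feats[, planted] <- grades + stats::rnorm(n, sd = noise_sd)
      doc <- sprintf("q%03d_d%02d", qi, ceiling(seq_len(n) / 5))
      meta <- data.frame(passage_id = rownames(feats), doc_id = doc,
                         start = (seq_len(n) - 1L) * 100L, length = 90L,
                         stringsAsFactors = FALSE)
      list(features = feats, grades = grades, meta = meta)
    })
    names(out) <- sprintf("q%03d", seq_len(num_queries))
    out
  })
}
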