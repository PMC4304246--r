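#' Construct a document
#'
#' A document is an opaque identifier, a character sequence and the sorted
#' 0-based character offsets of its paragraph boundaries (the positions where
#' an HTML paragraph tag sat in the original markup; the tag itself consumes
#' no characters).
#'
#' @param doc_id Single string.
#' @param text Single string (the document content with markup removed).
#' @param paragraph_breaks Integer vector of strictly increasing offsets in
#'   `[0, nchar(text)]`.
#' @return A list of class `document`.
#' @export
document <- function(doc_id, text, paragraph_breaks = integer()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L, !is.na(text))
  pb <- as.integer(paragraph_breaks)
  if (anyNA(pb) || is.unsorted(pb, strictly = TRUE) ||
      (length(pb) && (pb[1L] < 0L || pb[length(pb)] > nchar(text))))
    stop("paragraph_breaks must be strictly increasing offsets within [0, nchar(text)]")
  structure(list(doc_id = doc_id, text = text, paragraph_breaks = pb),
            class = "document")
}

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document %s: %d chars, %d paragraph breaks>\n",
              x$doc_id, nchar(x$text), length(x$paragraph_breaks)))
  invisible(x)
}

#' Reduce simple HTML to a document
#'
#' Thin preprocessor: `<p>`-family tags become paragraph breaks, every other
#' tag is stripped. Intended for paragraph-tagged full text, not general HTML.
#'
#' @param doc_id Document identifier.
#' @param html Single string of markup.
#' @return A [document()].
#' @export
html_to_document <- function(doc_id, html) {
  stopifnot(is.character(html), length(html) == 1L)
  # split on opening/closing paragraph tags, strip remaining tags per segment
  segs <- strsplit(html, "(?i)</?p\\b[^>]*>", perl = TRUE)[[1L]]
  segs <- gsub("<[^>]*>", "", segs)
  text <- paste0(segs, collapse = "")
  breaks <- if (length(segs) > 1L) cumsum(nchar(segs))[-length(segs)] else integer()
  document(doc_id, text, unique(breaks[breaks > 0 & breaks < nchar(text)]))
}

#' Extract passages from a document
#'
#' A passage is a maximal span of consecutive text within one document that
#' does not cross a paragraph boundary. Spans are 0-based half-open
#' `[start, start + length)`; each raw inter-break segment is trimmed of
#' leading/trailing whitespace and dropped if empty after trimming.
#'
#' @param doc A [document()].
#' @return A data.frame with columns `passage_id`, `doc_id`, `start`,
#'   `length`, `text`, in document order.
#' @export
extract_passages <- function(doc) {
  stopifnot(inherits(doc, "document"))
  n <- nchar(doc$text)
  bounds <- unique(c(0L, doc$paragraph_breaks, n))
  bounds <- sort(bounds[bounds >= 0L & bounds <= n])
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    if (e <= s) next
    seg <- substr(doc$text, s + 1L, e)
    lead <- regmatches(seg, regexpr("^[[:space:]]*", seg))
    trail <- regmatches(seg, regexpr("[[:space:]]*$", seg))
    s2 <- s + nchar(lead)
    e2 <- e - nchar(trail)
    if (e2 <= s2) next
    out[[length(out) + 1L]] <- data.frame(
      doc_id = doc$doc_id, start = s2, length = e2 - s2,
      text = substr(doc$text, s2 + 1L, e2), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(passage_id = character(), doc_id = character(),
                      start = integer(), length = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- cbind(passage_id = sprintf("%s_p%03d", res$doc_id, seq_len(nrow(res))),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Tokenize a passage table
#'
#' Adds a `tokens` list-column to a passage data.frame (as produced by
#' [extract_passages()] or the synthetic generator).
#'
#' @param passages Passage data.frame with a `text` column.
#' @param config A [tokenizer_config()].
#' @return The same data.frame with a `tokens` list-column.
#' @export
tokenize_passages <- function(passages, config = tokenizer_config()) {
  stopifnot(is.data.frame(passages), "text" %in% names(passages))
  passages$tokens <- lapply(passages$text, tokenize, config = config)
  passages
}

#' Build an inverted index with collection statistics
#'
#' @param passages Passage data.frame with `passage_id` and a `tokens`
#'   list-column (see [tokenize_passages()]). Duplicate passage ids are an
#'   error.
#' @return An object of class `passage_index`: postings (term ->
#'   data.frame(passage_id, tf)), per-passage term-frequency tables, token
#'   sequences, passage lengths, the passage table, and `stats` holding
#'   `num_passages`, `avg_passage_len`, `doc_freq`, `coll_freq`,
#'   `total_tokens`.
#' @export
build_index <- function(passages) {
  stopifnot(is.data.frame(passages), "passage_id" %in% names(passages),
            "tokens" %in% names(passages))
  pids <- as.character(passages$passage_id)
  if (anyDuplicated(pids)) stop("duplicate passage_id in corpus: ",
                                paste(unique(pids[duplicated(pids)]), collapse = ", "))
  toks <- passages$tokens
  names(toks) <- pids
  tf <- lapply(toks, function(t) {
    if (!length(t)) return(integer())
    tab <- table(t)
    stats::setNames(as.integer(tab), names(tab))
  })
  len <- stats::setNames(vapply(toks, length, integer(1L)), pids)
  all_tokens <- unlist(toks, use.names = FALSE)
  coll_freq <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  term_presence <- unlist(lapply(tf, names), use.names = FALSE)
  doc_freq <- if (length(term_presence)) {
    tab <- table(term_presence)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  postings <- list()
  if (length(term_presence)) {
    long <- data.frame(
      term = term_presence,
      passage_id = rep(pids, vapply(tf, length, integer(1L))),
      tf = unlist(tf, use.names = FALSE),
      stringsAsFactors = FALSE)
    postings <- split(long[c("passage_id", "tf")], long$term)
  }
  structure(list(
    postings = postings,
    tf = tf,
    tokens = toks,
    passage_len = len,
    passages = passages[setdiff(names(passages), "tokens")],
    stats = list(
      num_passages = length(pids),
      avg_passage_len = if (length(len)) mean(len) else 0,
      doc_freq = doc_freq,
      coll_freq = coll_freq,
      total_tokens = length(all_tokens))),
    class = "passage_index")
}

#' @export
print.passage_index <- function(x, ...) {
  cat(sprintf("<passage_index: %d passages, %d terms, %d tokens, avg length %.1f>\n",
              x$stats$num_passages, length(x$stats$doc_freq),
              x$stats$total_tokens, x$stats$avg_passage_len))
  invisible(x)
}

#' Transfer gold relevance onto extracted passages
#'
#' An extracted passage inherits relevance from every gold span in the same
#' document whose half-open character interval overlaps it by at least one
#' character: its grade is the maximum grade over overlapping spans and its
#' aspect set the union of aspects of overlapping spans with positive grade
#' (a judged-nonrelevant span grants no aspect credit). Passages overlapping
#' nothing get grade 0 and an empty aspect set.
#'
#' @param passages Passage data.frame (`passage_id`, `doc_id`, `start`,
#'   `length`).
#' @param qrels Judgment data.frame as returned by [read_qrels()]:
#'   `query_id`, `doc_id`, `start`, `length`, `grade`, `aspects` list-column.
#' @param query_id Which query's judgments to transfer.
#' @return `passages` with `grade` (numeric) and `aspects` (list of character)
#'   columns added. Gold spans naming a document absent from `passages` are
#'   skipped with a warning.
#' @export
transfer_relevance <- function(passages, qrels, query_id) {
  stopifnot(is.data.frame(passages), is.data.frame(qrels))
  gold <- qrels[qrels$query_id == query_id, , drop = FALSE]
  unknown <- setdiff(unique(gold$doc_id), unique(passages$doc_id))
  if (length(unknown)) {
    warning("gold spans reference unknown doc_id(s), skipped: ",
            paste(unknown, collapse = ", "))
    gold <- gold[!(gold$doc_id %in% unknown), , drop = FALSE]
  }
  n <- nrow(passages)
  grades <- numeric(n)
  aspects <- rep(list(character()), n)
  if (nrow(gold)) {
    p_end <- passages$start + passages$length
    g_end <- gold$start + gold$length
    for (i in seq_len(n)) {
      hit <- gold$doc_id == passages$doc_id[i] &
        gold$start < p_end[i] & g_end > passages$start[i]
      if (any(hit)) {
        grades[i] <- max(gold$grade[hit])
        pos <- hit & gold$grade > 0
        if (any(pos))
          aspects[[i]] <- sort(unique(unlist(gold$aspects[pos])))
      }
    }
  }
  passages$grade <- grades
  passages$aspects <- aspects
  passages
}

#' Read / write a JSON-lines corpus
#'
#' One JSON object per line: `{"doc_id": ..., "text": ..., "paragraph_breaks":
#' [...]}`.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()`: a list of [document()] objects.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    document(x$doc_id, x$text, as.integer(unlist(x$paragraph_breaks)))
  })
}

#' @rdname read_corpus_jsonl
#' @param docs List of [document()] objects.
#' @export
write_corpus_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, text = d$text,
                          paragraph_breaks = d$paragraph_breaks),
                     auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
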