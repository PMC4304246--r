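#' Read and write qrels files
#'
#' Whitespace-separated judgment files with one gold span per line:
#' `query_id doc_id start length grade aspects`, where `aspects` is a
#' comma-separated list of aspect identifiers or `-` for none. Character
#' spans are 0-based half-open.
#'
#' @param path File path.
#' @return `read_qrels()`: data.frame with columns `query_id`, `doc_id`,
#'   `start`, `length`, `grade` and an `aspects` list-column.
#' @export
read_qrels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lineno <- which(keep)
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    stop(sprintf("malformed qrels line %d: expected 6 fields, got %d",
                 lineno[bad[1L]], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 3L]))
  len <- suppressWarnings(as.integer(m[, 4L]))
  grade <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is.na(start) | is.na(len) | is.na(grade) | start < 0L |
                 len < 0L | grade < 0)
  if (length(bad))
    stop(sprintf("malformed qrels line %d: non-numeric or negative span/grade",
                 lineno[bad[1L]]))
  data.frame(query_id = m[, 1L], doc_id = m[, 2L], start = start,
             length = len, grade = grade,
             aspects = I(lapply(m[, 6L], function(a)
               if (a == "-") character() else strsplit(a, ",", fixed = TRUE)[[1L]])),
             stringsAsFactors = FALSE)
}

#' @rdname read_qrels
#' @param qrels Judgment data.frame in the [read_qrels()] layout.
#' @export
write_qrels <- function(qrels, path) {
  asp <- vapply(qrels$aspects, function(a)
    if (length(a)) paste(a, collapse = ",") else "-", character(1L))
  writeLines(sprintf("%s %s %d %d %s %s", qrels$query_id, qrels$doc_id,
                     as.integer(qrels$start), as.integer(qrels$length),
                     format_grade(qrels$grade), asp), path)
  invisible(path)
}

format_grade <- function(g) {
  ifelse(g == round(g), sprintf("%d", as.integer(g)), sprintf("%g", g))
}

#' Read and write run files
#'
#' TREC-style submission layout, one retrieved passage per line:
#' `query_id doc_id start length rank score tag`. Within a query, ranks must
#' be consecutive from 1 and scores non-increasing; violations are rejected
#' with the offending line number. Scores are serialized with six decimals,
#' so writing what was read reproduces a canonical file byte for byte.
#'
#' @param path File path.
#' @return `read_run()`: data.frame with columns `query_id`, `doc_id`,
#'   `start`, `length`, `rank`, `score`, `tag`.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lineno <- which(keep)
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("malformed run line %d: expected 7 fields, got %d",
                 lineno[bad[1L]], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  run <- data.frame(query_id = m[, 1L], doc_id = m[, 2L],
                    start = suppressWarnings(as.integer(m[, 3L])),
                    length = suppressWarnings(as.integer(m[, 4L])),
                    rank = suppressWarnings(as.integer(m[, 5L])),
                    score = suppressWarnings(as.numeric(m[, 6L])),
                    tag = m[, 7L], stringsAsFactors = FALSE)
  bad <- which(is.na(run$start) | is.na(run$length) | is.na(run$rank) |
                 is.na(run$score) | run$start < 0L | run$length <= 0L)
  if (length(bad))
    stop(sprintf("malformed run line %d: non-numeric or invalid span/rank/score",
                 lineno[bad[1L]]))
  validate_run(run, lineno)
  run
}

validate_run <- function(run, lineno = seq_len(nrow(run))) {
  for (q in unique(run$query_id)) {
    idx <- which(run$query_id == q)
    sub <- run[idx, , drop = FALSE]
    o <- order(sub$rank)
    if (!identical(sub$rank[o], seq_along(idx)))
      stop(sprintf("run validation: query %s ranks not consecutive from 1 (line %d)",
                   q, lineno[idx[o][which(sub$rank[o] != seq_along(idx))[1L]]]))
    if (any(diff(sub$score[o]) > 1e-9))
      stop(sprintf("run validation: query %s scores increase with rank (line %d)",
                   q, lineno[idx[o][which(diff(sub$score[o]) > 1e-9)[1L] + 1L]]))
  }
  invisible(run)
}

#' @rdname read_run
#' @param run Run data.frame in the [read_run()] layout.
#' @export
write_run <- function(run, path) {
  validate_run(run)
  writeLines(sprintf("%s %s %d %d %d %.6f %s", run$query_id, run$doc_id,
                     as.integer(run$start), as.integer(run$length),
                     as.integer(run$rank), run$score, run$tag), path)
  invisible(path)
}

#' Read and write LETOR-dialect feature files
#'
#' SVMlight-style lines: `<grade> qid:<qid> 1:<v1> ... k:<vk> # <passage_id>`.
#' Feature columns are written in index order and must be dense.
#'
#' @param path File path.
#' @param feature_names Character vector naming the feature columns, in order.
#' @return `read_letor()`: a named list (one entry per query) of lists with
#'   `features` (matrix, rownames = passage ids), `grades` (numeric).
#' @export
read_letor <- function(path, feature_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(sub("[[:space:]]*#[[:space:]]*", "\t#", trimws(lines[i])),
                      "[\t]")[[1L]]
    pid <- if (length(parts) == 2L) sub("^#", "", parts[2L]) else NA_character_
    toks <- strsplit(parts[1L], "[[:space:]]+")[[1L]]
    if (length(toks) < 2L || !grepl("^qid:", toks[2L]))
      stop(sprintf("malformed LETOR line %d", i))
    grade <- as.numeric(toks[1L])
    qid <- sub("^qid:", "", toks[2L])
    fv <- toks[-(1:2)]
    idx <- as.integer(sub(":.*$", "", fv))
    val <- as.numeric(sub("^[^:]*:", "", fv))
    if (anyNA(idx) || anyNA(val) || !identical(idx, seq_along(idx)))
      stop(sprintf("malformed LETOR line %d: features must be dense 1..k", i))
    list(qid = qid, grade = grade, values = val, pid = pid)
  })
  k <- length(parsed[[1L]]$values)
  if (is.null(feature_names)) feature_names <- sprintf("f%d", seq_len(k))
  if (length(feature_names) != k)
    stop("feature_names length does not match file feature count")
  qids <- vapply(parsed, `[[`, character(1L), "qid")
  out <- lapply(split(parsed, factor(qids, levels = unique(qids))), function(rows) {
    mat <- do.call(rbind, lapply(rows, `[[`, "values"))
    colnames(mat) <- feature_names
    rownames(mat) <- vapply(rows, `[[`, character(1L), "pid")
    list(features = mat, grades = vapply(rows, `[[`, numeric(1L), "grade"))
  })
  out
}

#' @rdname read_letor
#' @param data Named list per query of `list(features, grades)` as produced by
#'   [read_letor()] or the training-set builders.
#' @export
write_letor <- function(data, path) {
  lines <- character()
  for (qid in names(data)) {
    mat <- data[[qid]]$features
    grades <- data[[qid]]$grades
    for (i in seq_len(nrow(mat))) {
      feat <- paste(sprintf("%d:%.6g", seq_len(ncol(mat)), mat[i, ]),
                    collapse = " ")
      lines <- c(lines, sprintf("%s qid:%s %s # %s", format_grade(grades[i]),
                                qid, feat, rownames(mat)[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
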