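#' Tokenizer configuration
#'
#' Settings for [tokenize()]. Tokenization is deliberately simple and fully
#' deterministic: lowercase, split on any non-alphanumeric character, then
#' optionally drop stopwords and apply a light suffix stemmer.
#'
#' @param stem Logical; apply the light suffix stemmer (plural and
#'   `-ing`/`-ed` stripping). Off by default: passage retrieval features are
#'   computed on surface forms unless the caller opts in.
#' @param stopwords Character vector of (lowercase) tokens to drop after
#'   splitting. Empty by default.
#' @return A list of class `tokenizer_config`.
#' @export
#' @examples
#' tokenize("BRCA1 and BRCA1.", tokenizer_config())
tokenizer_config <- function(stem = FALSE, stopwords = character()) {
  stopifnot(is.logical(stem), length(stem) == 1L, is.character(stopwords))
  structure(list(stem = stem, stopwords = tolower(stopwords)),
            class = "tokenizer_config")
}

#' Tokenize text
#'
#' Lowercases, splits on non-alphanumeric characters, optionally removes
#' stopwords and applies light stemming. Deterministic for a fixed config;
#' empty input yields an empty token vector.
#'
#' @param text A single character string (NA treated as empty).
#' @param config A [tokenizer_config()].
#' @return Character vector of tokens, order-preserving.
#' @export
tokenize <- function(text, config = tokenizer_config()) {
  stopifnot(inherits(config, "tokenizer_config"))
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- regmatches(tolower(text), gregexpr("[[:alnum:]]+", tolower(text)))[[1L]]
  if (length(config$stopwords)) toks <- toks[!(toks %in% config$stopwords)]
  if (isTRUE(config$stem)) toks <- vapply(toks, light_stem, character(1L), USE.NAMES = FALSE)
  toks
}

# Light suffix stemmer: conflates plurals and the most common verbal suffixes.
# Not a full Porter implementation; rules are ordered, first match wins, and a
# rule never fires when it would leave fewer than 3 characters.
light_stem <- function(tok) {
  n <- nchar(tok)
  strip <- function(suf) substr(tok, 1L, n - nchar(suf))
  if (n > 4L && endsWith(tok, "sses")) return(paste0(strip("sses"), "ss"))
  if (n > 4L && endsWith(tok, "ies"))  return(paste0(strip("ies"), "i"))
  if (n > 3L && endsWith(tok, "s") && !endsWith(tok, "ss") && !endsWith(tok, "us"))
    return(strip("s"))
  if (n > 5L && endsWith(tok, "ing")) return(strip("ing"))
  if (n > 4L && endsWith(tok, "ed"))  return(strip("ed"))
  tok
}
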