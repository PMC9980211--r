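# Deterministic text normalization applied before sentiment, topic and
# embedding extraction. Theme counting deliberately bypasses stop-word
# removal and stemming (function words are themselves themes) and uses
# .tokenize_raw() below.

.EMOTICON_RE <- "(?:[:;=8][-'o]?[)(DdPpOo|\\\\/]|<3|:'\\()"

.strip_accents <- function(x) {
  # fold accented letters to their base letter; non-convertible chars dropped
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- ""
  gsub("[`'^~\"]", "", out)
}

.tokenize_raw <- function(text) {
  # lowercase + accent folding + punctuation stripped; no removal, no stems
  x <- tolower(text)
  x <- .strip_accents(x)
  x <- gsub(.EMOTICON_RE, " ", x, perl = TRUE)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Normalize raw text into a token stream
#'
#' Lowercases, folds accents to base letters, removes emoticons, strips
#' punctuation and splits on whitespace. Idempotent: normalizing the
#' space-joined output reproduces it.
#'
#' @param raw_text a single character string (any unicode).
#' @return character vector of lowercase tokens (possibly empty).
#' @examples
#' normalize_text("Café!! Great.")
#' @export
normalize_text <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text)) return(character(0))
  .tokenize_raw(raw_text)
}

#' Count words and emoticons in raw text
#'
#' The word-count feature keeps its pre-removal magnitude: tokens are counted
#' before any stop/common-word removal, and emoticons count as words.
#'
#' @param raw_text a single character string.
#' @return non-negative integer.
#' @export
count_words <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text)) return(0L)
  n_emo <- length(gregexpr(.EMOTICON_RE, raw_text, perl = TRUE)[[1]])
  if (n_emo == 1L &&
      gregexpr(.EMOTICON_RE, raw_text, perl = TRUE)[[1]][1] == -1L) {
    n_emo <- 0L
  }
  length(.tokenize_raw(raw_text)) + n_emo
}

#' Remove stop words and overly common words
#'
#' Order-preserving removal of two configurable word lists: a standard
#' English stop list and a list of words overused in response to app prompts
#' (defaults ship with the package; see [default_stopwords()]).
#'
#' @param tokens character vector of normalized tokens.
#' @param stop_list,common_list character vectors of words to remove.
#' @return filtered token vector, original order preserved.
#' @export
remove_common <- function(tokens,
                          stop_list = default_stopwords(),
                          common_list = default_common_words()) {
  stopifnot(is.character(tokens))
  tokens[!(tokens %in% c(stop_list, common_list))]
}

#' Stem a normalized token stream
#'
#' Applies the Porter stemmer token-wise; stems align one-to-one with input
#' tokens.
#'
#' @param tokens character vector of normalized tokens.
#' @return character vector of stems.
#' @export
stem_tokens <- function(tokens) {
  porter_stem(tokens)
}

#' Read a one-word-per-line word list
#'
#' @param path UTF-8 text file, one word per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of lowercase words.
#' @export
read_wordlist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Packaged default stop and common word lists
#'
#' The stop list is a standard English function-word list seeded with the
#' usual pronouns, auxiliaries, conjunctions and prepositions; the common
#' list holds words overused in short prompt responses. Both are inputs to
#' the pipeline, never hard-coded in the extractors.
#'
#' @return character vector of words.
#' @export
default_stopwords <- function() {
  read_wordlist(system.file("extdata", "stopwords_en.txt",
                            package = "perilang", mustWork = TRUE))
}

#' @rdname default_stopwords
#' @export
default_common_words <- function() {
  read_wordlist(system.file("extdata", "common_words.txt",
                            package = "perilang", mustWork = TRUE))
}

# Full preprocessing used by the feature extractors: normalize -> remove.
# Returns list(tokens, stems, word_count).
.preprocess_text <- function(raw_text, stop_list, common_list) {
  toks <- normalize_text(raw_text)
  kept <- remove_common(toks, stop_list, common_list)
  list(tokens = kept, stems = stem_tokens(kept),
       word_count = count_words(raw_text))
}
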