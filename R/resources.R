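# Readers for the auxiliary language resources: LIWC-dialect theme
# dictionaries, a stemmed sentiment lexicon (term -> positive/negative sense
# scores), and word-embedding tables in word2vec text format.

#' Read a LIWC-dialect theme dictionary
#'
#' Format: a header delimited by lines containing only `%`, holding
#' `id<TAB>name` pairs, followed by `pattern<TAB>id[ id ...]` lines. A
#' trailing `*` in a pattern is a prefix wildcard (`depress*` matches
#' `depressed`).
#'
#' @param path path to a `.dic` file.
#' @return a `perilang_themes` object: named list mapping theme name to a
#'   character vector of lowercase patterns.
#' @export
read_theme_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) {
    stop(sprintf("%s: missing %%-delimited header", path), call. = FALSE)
  }
  header <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  body <- if (pct[2] < length(lines)) lines[(pct[2] + 1L):length(lines)]
          else character(0)

  ids <- character(0)
  for (ln in header) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop(sprintf("%s: malformed header line %s", path, dQuote(ln)),
           call. = FALSE)
    }
    id <- trimws(parts[1])
    nm <- trimws(parts[2])
    if (id %in% names(ids) || nm %in% unname(ids)) {
      stop(sprintf("%s: duplicate theme id or name (%s / %s)", path, id, nm),
           call. = FALSE)
    }
    ids[id] <- nm
  }

  themes <- setNames(vector("list", length(ids)), unname(ids))
  for (i in seq_along(themes)) themes[[i]] <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop(sprintf("%s: malformed pattern line %s", path, dQuote(ln)),
           call. = FALSE)
    }
    pat <- tolower(trimws(parts[1]))
    refs <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    for (id in refs) {
      nm <- if (id %in% names(ids)) ids[[id]] else NA_character_
      if (is.na(nm)) {
        stop(sprintf("%s: pattern %s references unknown theme id %s",
                     path, dQuote(pat), id), call. = FALSE)
      }
      themes[[nm]] <- c(themes[[nm]], pat)
    }
  }
  empty <- names(themes)[vapply(themes, length, integer(1)) == 0L]
  if (length(empty)) {
    warning(sprintf("%s: themes with no patterns: %s", path,
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  structure(themes, class = "perilang_themes")
}

#' @export
print.perilang_themes <- function(x, ...) {
  cat(sprintf("<perilang_themes> %d themes, %d patterns\n", length(x),
              sum(vapply(x, length, integer(1)))))
  invisible(x)
}

#' Read a sentiment lexicon
#'
#' TSV with one line per word sense: `term<TAB>positive<TAB>negative`,
#' scores in [0, 1]. A term occurring on several lines has several senses;
#' sense scores are averaged at scoring time (see [sentiment_scores()]).
#' Terms are expected to be stems.
#'
#' @param path path to the TSV file.
#' @return a `perilang_lexicon`: data frame with columns term, pos, neg.
#' @export
read_sentiment_lexicon <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("term", "pos", "neg"), comment.char = "#")
  if (any(is.na(df$pos)) || any(is.na(df$neg)) ||
      any(df$pos < 0 | df$pos > 1 | df$neg < 0 | df$neg > 1)) {
    stop(sprintf("%s: sentiment scores must lie in [0, 1]", path),
         call. = FALSE)
  }
  df$term <- tolower(df$term)
  structure(df, class = c("perilang_lexicon", "data.frame"))
}

#' Read a word-embedding table (word2vec text format)
#'
#' First line `V d`, then `V` lines of `token v1 ... vd`. Duplicate tokens:
#' the last occurrence wins, with a warning.
#'
#' @param path path to the embedding file.
#' @return a `perilang_embeddings`: list with `dim` and a `V x d` numeric
#'   matrix `vectors` with token rownames.
#' @export
read_embeddings <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  header <- strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1]]
  if (length(header) != 2L) {
    stop(sprintf("%s: malformed word2vec header", path), call. = FALSE)
  }
  v <- as.integer(header[1])
  d <- as.integer(header[2])
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != v) {
    stop(sprintf("%s: header promises %d rows, found %d", path, v,
                 length(lines)), call. = FALSE)
  }
  toks <- character(v)
  mat <- matrix(NA_real_, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop(sprintf("%s: row at line %d has %d fields, expected %d",
                   path, i + 1L, length(parts), d + 1L), call. = FALSE)
    }
    toks[i] <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) {
      stop(sprintf("%s: non-numeric value at line %d", path, i + 1L),
           call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(toks)) {
    dup <- unique(toks[duplicated(toks)])
    warning(sprintf("%s: duplicate tokens (last occurrence wins): %s", path,
                    paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
    keep <- !duplicated(toks, fromLast = TRUE)
    toks <- toks[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- toks
  structure(list(dim = d, vectors = mat), class = "perilang_embeddings")
}

#' @export
print.perilang_embeddings <- function(x, ...) {
  cat(sprintf("<perilang_embeddings> %d tokens, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Bundle the language resources used by the feature extractors
#'
#' Convenience loader: with no arguments, loads the compact fixture
#' resources shipped under `inst/extdata` (a hand-curated sentiment lexicon,
#' theme dictionaries for the summary/psychological-process themes plus the
#' two bespoke COVID-19 and pregnancy-health themes, a 50-dimensional
#' embedding fixture, and the default stop/common lists). External
#' full-scale resources (e.g. a 300-dimensional embedding table) can be
#' passed by path.
#'
#' @param lexicon,themes,embeddings file paths, or NULL for the packaged
#'   fixtures.
#' @param stop_list,common_list character vectors of words to remove.
#' @return a `perilang_resources` list.
#' @export
feature_resources <- function(lexicon = NULL, themes = NULL,
                              embeddings = NULL,
                              stop_list = default_stopwords(),
                              common_list = default_common_words()) {
  pkgfile <- function(f) system.file("extdata", f, package = "perilang",
                                     mustWork = TRUE)
  structure(list(
    lexicon = read_sentiment_lexicon(lexicon %||% pkgfile("sentiment_fixture.tsv")),
    themes = read_theme_dictionary(themes %||% pkgfile("themes.dic")),
    embeddings = read_embeddings(embeddings %||% pkgfile("embeddings_fixture.txt")),
    stop_list = stop_list,
    common_list = common_list
  ), class = "perilang_resources")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
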