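# Porter (1980) suffix-stripping stemmer.
#
# Implemented from the original algorithm description: words are viewed as
# [C](VC)^m[V]; each step strips or rewrites the longest matching suffix whose
# condition on the remaining stem holds. Within a step, once a suffix matches,
# the step ends whether or not its condition passed.

.is_vowel <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(TRUE)
  # y is a vowel when preceded by a consonant
  if (ch == "y" && i > 1L) return(!.is_vowel(chars, i - 1L))
  FALSE
}

# measure m of the stem chars[1..n]: number of VC alternations
.measure <- function(chars, n) {
  if (n < 1L) return(0L)
  types <- vapply(seq_len(n), function(i) .is_vowel(chars, i), logical(1))
  m <- 0L
  prev <- types[1]
  for (i in seq_len(n)[-1]) {
    if (prev && !types[i]) m <- m + 1L
    prev <- types[i]
  }
  m
}

.contains_vowel <- function(chars, n) {
  if (n < 1L) return(FALSE)
  any(vapply(seq_len(n), function(i) .is_vowel(chars, i), logical(1)))
}

.double_consonant <- function(chars, n) {
  n >= 2L && chars[n] == chars[n - 1L] && !.is_vowel(chars, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(chars, n) {
  if (n < 3L) return(FALSE)
  !.is_vowel(chars, n - 2L) && .is_vowel(chars, n - 1L) &&
    !.is_vowel(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

.ends_with <- function(word, suffix) {
  nc <- nchar(word)
  ns <- nchar(suffix)
  nc >= ns && substring(word, nc - ns + 1L, nc) == suffix
}

.chop <- function(word, k) substring(word, 1L, nchar(word) - k)

# Apply the first (longest) matching rule of a step-2/3/4 style table.
# rules: named character vector suffix -> replacement; condition on stem measure.
.apply_rules <- function(word, rules, min_m) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, nchar(suf))
      chars <- strsplit(stem, "", fixed = TRUE)[[1]]
      if (.measure(chars, length(chars)) > min_m) {
        return(paste0(stem, rules[[suf]]))
      }
      return(word) # suffix matched, condition failed: step ends
    }
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (.ends_with(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (.ends_with(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!.ends_with(word, "ss") && .ends_with(word, "s")) {
    word <- .chop(word, 1L)
  }

  # Step 1b
  step1b_extra <- FALSE
  if (.ends_with(word, "eed")) {
    stem <- .chop(word, 3L)
    chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (.measure(chars, length(chars)) > 0L) word <- .chop(word, 1L)
  } else if (.ends_with(word, "ed")) {
    stem <- .chop(word, 2L)
    chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (.contains_vowel(chars, length(chars))) {
      word <- stem
      step1b_extra <- TRUE
    }
  } else if (.ends_with(word, "ing")) {
    stem <- .chop(word, 3L)
    chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (.contains_vowel(chars, length(chars))) {
      word <- stem
      step1b_extra <- TRUE
    }
  }
  if (step1b_extra) {
    if (.ends_with(word, "at") || .ends_with(word, "bl") ||
        .ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else {
      chars <- strsplit(word, "", fixed = TRUE)[[1]]
      n <- length(chars)
      if (.double_consonant(chars, n) && !(chars[n] %in% c("l", "s", "z"))) {
        word <- .chop(word, 1L)
      } else if (.measure(chars, n) == 1L && .ends_cvc(chars, n)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (.ends_with(word, "y")) {
    stem <- .chop(word, 1L)
    chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (.contains_vowel(chars, length(chars))) word <- paste0(stem, "i")
  }

  # Step 2 (m > 0)
  word <- .apply_rules(word, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), min_m = 0L)

  # Step 3 (m > 0)
  word <- .apply_rules(word, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), min_m = 0L)

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  sufs4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
             "ic", "ou")
  sufs4 <- sufs4[order(-nchar(sufs4))]
  for (suf in sufs4) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, nchar(suf))
      chars <- strsplit(stem, "", fixed = TRUE)[[1]]
      n <- length(chars)
      ok <- .measure(chars, n) > 1L
      if (suf == "ion") ok <- ok && n >= 1L && chars[n] %in% c("s", "t")
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (.ends_with(word, "e")) {
    stem <- .chop(word, 1L)
    chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    n <- length(chars)
    m <- .measure(chars, n)
    if (m > 1L || (m == 1L && !.ends_cvc(chars, n))) word <- stem
  }

  # Step 5b
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n >= 1L && chars[n] == "l" && .double_consonant(chars, n) &&
      .measure(chars, n) > 1L) {
    word <- .chop(word, 1L)
  }

  word
}

#' Porter stem a character vector
#'
#' Deterministic suffix-stripping stemmer used to match tokens against the
#' stemmed sentiment lexicon. Input is assumed already lowercased; tokens of
#' one or two characters are returned unchanged, as in the original algorithm.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length and order as `words`.
#' @examples
#' porter_stem(c("running", "caresses", "happiness"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  vapply(words, .porter1, character(1), USE.NAMES = FALSE)
}
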