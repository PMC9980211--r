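# Independent oracles and fixture builders shared across the suite.

# Literal re-derivation of the pairing rules, written as explicit per-entry
# and per-screen scans (no shared code with pair_text_epds). Returns a list
# of samples with entry days, concatenated text, label mean and screen days.
oracle_pair <- function(entry_days, entry_texts, epds_days, epds_scores, W) {
  n <- length(entry_days)
  if (n == 0L || length(epds_days) == 0L) return(list())
  # cluster id per entry: a new cluster starts at entry j iff some screen
  # fell on or after the previous entry's day and strictly before entry j
  cl <- integer(n)
  cl[1] <- 1L
  if (n > 1L) {
    for (j in 2:n) {
      triggered <- FALSE
      for (d in epds_days) {
        if (d >= entry_days[j - 1] && d < entry_days[j]) triggered <- TRUE
      }
      cl[j] <- cl[j - 1] + as.integer(triggered)
    }
  }
  out <- list()
  for (c in sort(unique(cl))) {
    idx <- which(cl == c)
    anchor <- max(entry_days[idx])
    later <- entry_days[cl > c]
    next_entry <- if (length(later)) min(later) else Inf
    contrib <- integer(0)
    for (s in seq_along(epds_days)) {
      d <- epds_days[s]
      if (d >= anchor && d - anchor <= W && d < next_entry) {
        contrib <- c(contrib, s)
      }
    }
    if (length(contrib) == 0L) next
    first_screen <- min(epds_days[contrib])
    keep <- idx[first_screen - entry_days[idx] <= W]
    out[[length(out) + 1L]] <- list(
      entry_days = entry_days[keep],
      text = paste(entry_texts[keep], collapse = " "),
      mean_epds = mean(epds_scores[contrib]),
      epds_days = epds_days[contrib])
  }
  out
}

# AUROC by explicit enumeration of every positive-negative pair.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Random participant timeline for pairing equivalence checks.
random_timeline <- function(max_entries = 8L, max_epds = 8L,
                           horizon = 140L) {
  n_e <- sample.int(max_entries + 1L, 1L) - 1L
  n_s <- sample.int(max_epds + 1L, 1L) - 1L
  e_days <- sort(sample(0:horizon, n_e, replace = TRUE))
  s_days <- sort(sample(0:horizon, n_s, replace = TRUE))
  list(entry_days = e_days,
       entry_texts = if (n_e) paste0("w", seq_len(n_e)) else character(0),
       epds_days = s_days,
       epds_scores = if (n_s) sample(0:30, n_s, replace = TRUE)
                     else integer(0))
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_lexicon <- function(rows) {
  # rows: list of c(term, pos, neg)
  path <- write_tmp(vapply(rows, paste, character(1), collapse = "\t"),
                    ".tsv")
  read_sentiment_lexicon(path)
}

tiny_themes <- function(header, body) {
  read_theme_dictionary(write_tmp(c("%", header, "%", body), ".dic"))
}

tiny_embeddings <- function(tokens, vectors) {
  d <- length(vectors[[1]])
  lines <- c(sprintf("%d %d", length(tokens), d),
             vapply(seq_along(tokens), function(i) {
               paste(tokens[i], paste(vectors[[i]], collapse = " "))
             }, character(1)))
  read_embeddings(write_tmp(lines, ".txt"))
}

# Small cohort fixture with hand-set records for IO round trips.
small_cohort <- function() {
  baselines <- data.frame(
    participant_id = c("p1", "p2", "p3"),
    age_years = c(28, 34, 22),
    race_ethnicity = c("White", "Black", "Asian"),
    income_ge_50k = c(1L, 0L, 1L),
    education_ge_associate = c(1L, 1L, 0L),
    history_depression = c(0L, 1L, 0L),
    history_anxiety = c(1L, 0L, 0L),
    stringsAsFactors = FALSE)
  entries <- data.frame(
    participant_id = c("p1", "p1", "p2"),
    day = c(10L, 40L, 5L),
    text = c("tired today", "feeling great", "migraine again"),
    stringsAsFactors = FALSE)
  moods <- data.frame(participant_id = c("p1", "p2"), day = c(12L, 6L),
                      mood = c(4L, 2L), stringsAsFactors = FALSE)
  epds <- data.frame(participant_id = c("p1", "p2"), day = c(50L, 20L),
                     score = c(8L, 15L), stringsAsFactors = FALSE)
  symptoms <- data.frame(participant_id = "p2", day = 6L,
                         physical_symptom = 1L, stringsAsFactors = FALSE)
  cohort(baselines, entries, moods, epds, symptoms)
}
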