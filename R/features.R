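# The four language-feature families plus word count and assembly.
#
# Sentiment: lexicon positive/negative scores, sense-averaged per stem,
#   averaged over lexicon-matched stems; fluctuation = avg_pos - avg_neg.
# Themes: LIWC-convention percentages of raw (unprocessed, unstemmed)
#   tokens matching each theme's literal or prefix-wildcard patterns.
# Topics: per-document LDA loadings (simplex).
# Embeddings: componentwise max over in-vocabulary token vectors.

#' Lexicon sentiment scores for a stemmed token stream
#'
#' A stem with several lexicon senses gets the average of its sense scores;
#' avg_pos and avg_neg are means over the lexicon-matched stem occurrences
#' (unmatched stems do not enter the denominator). With no matched stem the
#' three scores are NA and are mean-imputed downstream.
#'
#' @param stems character vector of stems (processed text).
#' @param lexicon a `perilang_lexicon` from [read_sentiment_lexicon()].
#' @return named numeric vector: avg_pos, avg_neg, sentiment_fluctuation.
#' @export
sentiment_scores <- function(stems, lexicon) {
  agg_pos <- tapply(lexicon$pos, lexicon$term, mean)
  agg_neg <- tapply(lexicon$neg, lexicon$term, mean)
  m <- match(stems, names(agg_pos))
  hit <- !is.na(m)
  if (!any(hit)) {
    return(c(avg_pos = NA_real_, avg_neg = NA_real_,
             sentiment_fluctuation = NA_real_))
  }
  ap <- mean(agg_pos[m[hit]])
  an <- mean(agg_neg[m[hit]])
  c(avg_pos = ap, avg_neg = an, sentiment_fluctuation = ap - an)
}

.compile_themes <- function(dictionary) {
  lapply(dictionary, function(pats) {
    wild <- endsWith(pats, "*")
    list(exact = pats[!wild],
         prefix = substr(pats[wild], 1L, nchar(pats[wild]) - 1L))
  })
}

.match_any <- function(tokens, compiled) {
  hit <- tokens %in% compiled$exact
  for (pre in compiled$prefix) {
    hit <- hit | startsWith(tokens, pre)
  }
  hit
}

#' Theme-dictionary percentages for raw text
#'
#' Counts on the unprocessed text (so pronouns and other function words are
#' captured): tokenization lowercases and strips punctuation but performs
#' no stop-word removal and no stemming. Each theme's value is the
#' percentage of tokens matching any of its patterns; `word_count` carries
#' the magnitude separately.
#'
#' @param raw_text a single character string.
#' @param dictionary a `perilang_themes` from [read_theme_dictionary()].
#' @return named numeric vector: one `theme_<name>` percentage per theme
#'   plus `word_count`.
#' @export
theme_counts <- function(raw_text, dictionary) {
  compiled <- .compile_themes(dictionary)
  tokens <- .tokenize_raw(raw_text)
  n <- length(tokens)
  vals <- vapply(compiled, function(cp) {
    if (n == 0L) return(0)
    100 * sum(.match_any(tokens, cp)) / n
  }, numeric(1))
  names(vals) <- paste0("theme_", names(dictionary))
  c(vals, word_count = count_words(raw_text))
}

#' Max-pooled embedding vector for a token stream
#'
#' Component j is the maximum of vector\[j\] over the in-vocabulary tokens;
#' out-of-vocabulary tokens are skipped. With no in-vocabulary token the
#' block is NA and is mean-imputed downstream.
#'
#' @param tokens character vector of processed tokens.
#' @param table a `perilang_embeddings` from [read_embeddings()].
#' @return named numeric vector `w2v_1` ... `w2v_d`.
#' @export
embed_maxpool <- function(tokens, table) {
  d <- table$dim
  out <- setNames(rep(NA_real_, d), paste0("w2v_", seq_len(d)))
  m <- match(tokens, rownames(table$vectors))
  m <- m[!is.na(m)]
  if (length(m) == 0L) return(out)
  sub <- table$vectors[m, , drop = FALSE]
  out[] <- apply(sub, 2L, max)
  out
}

#' Assemble the full feature vector for paired samples
#'
#' Runs the preprocessing pipeline once per sample and concatenates the
#' blocks in fixed order: sentiment (3), theme percentages, topic loadings
#' (when a topic model is attached), max-pooled embeddings, word count.
#' Missing sentiment/embedding blocks (no lexicon/vocabulary hit) are left
#' NA here; imputation parameters are estimated on the training rows by the
#' model stage.
#'
#' @param samples data frame from [pair_text_epds()] (usable samples).
#' @param resources a `perilang_resources` bundle.
#' @param topic_model optional `perilang_lda`; when NULL the topic block is
#'   omitted.
#' @return numeric matrix, one row per sample, named columns.
#' @export
assemble_features <- function(samples, resources, topic_model = NULL) {
  stopifnot(inherits(resources, "perilang_resources"))
  n <- nrow(samples)
  pre <- lapply(samples$concatenated_text, .preprocess_text,
                stop_list = resources$stop_list,
                common_list = resources$common_list)

  sent <- t(vapply(pre, function(p) {
    sentiment_scores(p$stems, resources$lexicon)
  }, numeric(3)))

  them <- t(vapply(samples$concatenated_text, function(txt) {
    theme_counts(txt, resources$themes)
  }, numeric(length(resources$themes) + 1L)))
  rownames(them) <- NULL
  wc <- them[, "word_count", drop = FALSE]
  them <- them[, setdiff(colnames(them), "word_count"), drop = FALSE]

  emb <- t(vapply(pre, function(p) {
    embed_maxpool(p$tokens, resources$embeddings)
  }, numeric(resources$embeddings$dim)))

  blocks <- list(sent, them)
  if (!is.null(topic_model)) {
    blocks <- c(blocks, list(topic_loadings(topic_model,
                                            lapply(pre, `[[`, "tokens"))))
  }
  blocks <- c(blocks, list(emb, wc))
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Family of each feature column
#'
#' Maps assembled feature names to their family: sentiment, theme, topic,
#' w2v, word_count, mood, symptom or baseline. Used for the per-family
#' retained-coefficient report.
#'
#' @param feature_names character vector of column names.
#' @return character vector of family labels.
#' @export
feature_family <- function(feature_names) {
  fam <- rep("baseline", length(feature_names))
  fam[feature_names %in% c("avg_pos", "avg_neg",
                           "sentiment_fluctuation")] <- "sentiment"
  fam[startsWith(feature_names, "theme_")] <- "theme"
  fam[startsWith(feature_names, "topic_")] <- "topic"
  fam[startsWith(feature_names, "w2v_")] <- "w2v"
  fam[feature_names == "word_count"] <- "word_count"
  fam[feature_names %in% c("mood_mean", "mood_min", "mood_max")] <- "mood"
  fam[feature_names == "symptom_any"] <- "symptom"
  fam
}
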