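test_that("sentiment scores sense-average and subtract negatives from positives", {
  lex <- tiny_lexicon(list(c("good", "0.8", "0.0"), c("bad", "0.0", "0.6")))
  s <- sentiment_scores(c("good", "bad"), lex)
  expect_equal(unname(s["avg_pos"]), 0.4)
  expect_equal(unname(s["avg_neg"]), 0.3)
  expect_equal(unname(s["sentiment_fluctuation"]), 0.1)

  # a term with two senses is averaged before scoring
  lex2 <- tiny_lexicon(list(c("cool", "0.5", "0.1"),
                            c("cool", "0.3", "0.3")))
  s2 <- sentiment_scores("cool", lex2)
  expect_equal(unname(s2["avg_pos"]), 0.4)
  expect_equal(unname(s2["avg_neg"]), 0.2)

  # repeats count per occurrence; unmatched stems do not dilute
  lex3 <- tiny_lexicon(list(c("good", "0.9", "0.1")))
  s3 <- sentiment_scores(c("good", "good", "unknown"), lex3)
  expect_equal(unname(s3["avg_pos"]), 0.9)

  # no matched stems -> absent block
  expect_true(all(is.na(sentiment_scores(character(0), lex))))
  expect_true(all(is.na(sentiment_scores("zzz", lex))))
})

test_that("sentiment fluctuation stays within [-1, 1] for [0,1] lexicons", {
  set.seed(3)
  lex <- tiny_lexicon(lapply(letters[1:10], function(w) {
    c(w, sprintf("%.3f", runif(1)), sprintf("%.3f", runif(1)))
  }))
  for (i in 1:50) {
    stems <- sample(c(letters[1:10], "oov"), sample(1:12, 1), replace = TRUE)
    s <- sentiment_scores(stems, lex)
    if (!is.na(s["sentiment_fluctuation"])) {
      expect_gte(s[["sentiment_fluctuation"]], -1)
      expect_lte(s[["sentiment_fluctuation"]], 1)
      expect_equal(s[["sentiment_fluctuation"]],
                   s[["avg_pos"]] - s[["avg_neg"]])
    }
  }
})

test_that("theme counts are percentages of raw tokens", {
  d <- tiny_themes("1\tfirst_person_plural", c("we\t1", "our\t1"))
  v <- theme_counts("we love our home", d)
  expect_equal(unname(v["theme_first_person_plural"]), 50)
  expect_equal(unname(v["word_count"]), 4)

  d2 <- tiny_themes("1\tpregnancy_health",
                    c("heartburn\t1", "contractions\t1"))
  v2 <- theme_counts("heartburn and contractions", d2)
  expect_equal(unname(v2["theme_pregnancy_health"]), 100 * 2 / 3)

  v3 <- theme_counts("nothing matches here at all", d2)
  expect_equal(unname(v3["theme_pregnancy_health"]), 0)
  v4 <- theme_counts("", d2)
  expect_equal(unname(v4["theme_pregnancy_health"]), 0)
  expect_equal(unname(v4["word_count"]), 0)

  # function words are captured because counting runs on raw text
  d5 <- tiny_themes("1\tfpp", "we\t1")
  expect_equal(unname(theme_counts("We are; WE, we!", d5)["theme_fpp"]),
               75)
})

test_that("theme percentages are invariant under text duplication", {
  d <- tiny_themes("1\tmh", c("depress*\t1", "trauma\t1"))
  txt <- "feeling depressed after trauma talk"
  v1 <- theme_counts(txt, d)
  v2 <- theme_counts(paste(txt, txt), d)
  expect_equal(v1["theme_mh"], v2["theme_mh"])
  expect_equal(unname(v2["word_count"]), 2 * unname(v1["word_count"]))
})

test_that("embedding max-pooling is an elementwise maximum over known tokens", {
  e <- tiny_embeddings(c("a", "b"), list(c(-1, 2), c(3, 0)))
  expect_equal(unname(embed_maxpool("a", e)), c(-1, 2))
  expect_equal(unname(embed_maxpool(c("a", "b"), e)), c(3, 2))
  expect_equal(unname(embed_maxpool(c("a", "oov", "b"), e)), c(3, 2))
  expect_true(all(is.na(embed_maxpool(c("x", "y"), e))))
  expect_true(all(is.na(embed_maxpool(character(0), e))))
})

test_that("max-pooling is permutation-invariant and monotone", {
  set.seed(8)
  toks <- paste0("w", 1:12)
  e <- tiny_embeddings(toks, lapply(1:12, function(i) round(rnorm(5), 3)))
  for (i in 1:20) {
    sel <- sample(toks, sample(2:8, 1), replace = TRUE)
    base <- embed_maxpool(sel, e)
    expect_identical(embed_maxpool(sample(sel), e), base)
    more <- embed_maxpool(c(sel, sample(toks, 1)), e)
    expect_true(all(more >= base - 1e-15))
  }
})

test_that("assembled vectors have fixed arity, order and determinism", {
  res <- feature_resources()
  samples <- data.frame(
    participant_id = c("p1", "p2"),
    concatenated_text = c("so happy about the nursery we painted",
                          "so happy about the nursery we painted"),
    stringsAsFactors = FALSE)
  docs <- lapply(samples$concatenated_text, function(t) {
    remove_common(normalize_text(t))
  })
  tm <- fit_topic_model(rep(docs, 3), k = 2, seed = 1)
  m <- assemble_features(samples, res, tm)
  expect_equal(ncol(m), 3 + length(res$themes) + 2 +
                 res$embeddings$dim + 1)
  expect_identical(m[1, ], m[2, ]) # identical texts -> identical vectors
  blocks <- feature_family(colnames(m))
  expect_equal(rle(blocks)$values,
               c("sentiment", "theme", "topic", "w2v", "word_count"))
  m2 <- assemble_features(samples, res, tm)
  expect_identical(m, m2)
})
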