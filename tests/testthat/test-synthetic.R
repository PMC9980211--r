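test_that("generation is deterministic given the seed", {
  spec <- generator_spec(n_participants = 30, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_cohort(generator_spec(n_participants = 30, seed = 6))
  expect_false(identical(a$cohort$entries$text, c2$cohort$entries$text))
})

test_that("generated records satisfy all cohort invariants", {
  sim <- generate_cohort(generator_spec(n_participants = 50, seed = 2))
  expect_silent(validate_cohort(sim$cohort))
  expect_true(all(sim$cohort$epds$score %in% 0:30))
  expect_true(all(sim$cohort$moods$mood %in% 1:5))
  # ground truth records every channel, zero channels as zero
  gt0 <- generate_cohort(null_generator_spec(20, seed = 3))$ground_truth
  expect_true(all(unlist(gt0$effects) == 0))
  expect_equal(nrow(gt0$severity), 20L)
})

test_that("null effects leave severity and EPDS unassociated", {
  sim <- generate_cohort(null_generator_spec(n_participants = 500, seed = 9))
  mean_epds <- tapply(sim$cohort$epds$score, sim$cohort$epds$participant_id,
                      mean)
  z <- setNames(sim$ground_truth$severity$z,
                sim$ground_truth$severity$participant_id)
  r <- cor(z[names(mean_epds)], mean_epds)
  expect_lt(abs(r), 0.1)
})

test_that("a strong EPDS loading makes mean EPDS track severity", {
  sim <- generate_cohort(generator_spec(n_participants = 500, seed = 9))
  mean_epds <- tapply(sim$cohort$epds$score, sim$cohort$epds$participant_id,
                      mean)
  z <- setNames(sim$ground_truth$severity$z,
                sim$ground_truth$severity$participant_id)
  r <- cor(z[names(mean_epds)], mean_epds, method = "spearman")
  expect_gt(r, 0.5)
})

test_that("cohort descriptives are calibrated to the study's structure", {
  sim <- generate_cohort(generator_spec(n_participants = 500, seed = 4))
  s <- summarize_cohort(sim$cohort)
  expect_gt(s$words_per_entry["mean"], 40)
  expect_lt(s$words_per_entry["mean"], 70)
  expect_gt(s$entries_per_participant["mean"], 1)
  expect_lt(s$entries_per_participant["mean"], 4)
  expect_equal(sum(s$severity_proportions), 1, tolerance = 1e-12)
  # most screens indicate no or mild symptoms, as in screening practice
  expect_gt(s$severity_proportions["none"] + s$severity_proportions["mild"],
            0.75)
})

test_that("summary handles a degenerate single-entry cohort", {
  b <- small_cohort()$baselines[1, , drop = FALSE]
  ch <- cohort(b, data.frame(participant_id = "p1", day = 1L,
                             text = "one two three",
                             stringsAsFactors = FALSE),
               epds = data.frame(participant_id = "p1", day = 2L,
                                 score = 5L, stringsAsFactors = FALSE))
  s <- summarize_cohort(ch)
  expect_equal(unname(s$words_per_entry["mean"]), 3)
  expect_equal(unname(s$words_per_entry["sd"]), 0)
  ch_empty <- tryCatch(cohort(b[0, , drop = FALSE]), error = identity)
  if (!inherits(ch_empty, "error")) {
    expect_error(summarize_cohort(ch_empty), "empty")
  }
})

test_that("raising the flattening effect lowers realized sentiment fluctuation", {
  res <- feature_resources()
  fluct_at <- function(effect, seed) {
    eff <- effect_sizes(sentiment_flatten = effect)
    sim <- generate_cohort(generator_spec(n_participants = 150, seed = seed,
                                          effects = eff))
    txt <- sim$cohort$entries$text
    z <- setNames(sim$ground_truth$severity$z,
                  sim$ground_truth$severity$participant_id)
    high <- sim$cohort$entries$participant_id %in%
      names(z)[z > 0.5]
    vals <- vapply(txt[high], function(t) {
      st <- stem_tokens(remove_common(normalize_text(t)))
      unname(sentiment_scores(st, res$lexicon)["sentiment_fluctuation"])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  f <- vapply(c(0, 1.2, 2.5), fluct_at, numeric(1), seed = 21)
  expect_true(f[1] > f[2] && f[2] > f[3])
})
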