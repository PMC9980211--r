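test_that("JSONL records round-trip through write_cohort and read_cohort", {
  ch <- small_cohort()
  dir <- tempfile("cohort_")
  paths <- write_cohort(ch, dir)
  back <- read_cohort(paths)
  for (nm in c("baselines", "entries", "moods", "epds", "symptoms")) {
    expect_equal(back[[nm]], ch[[nm]], info = nm)
  }

  # single-entry identity
  one <- cohort(ch$baselines,
                data.frame(participant_id = "p1", day = 10L,
                           text = "tired today", stringsAsFactors = FALSE))
  p2 <- write_cohort(one, tempfile("cohort_"))
  back2 <- read_cohort(p2)
  expect_equal(nrow(back2$entries), 1L)
  expect_equal(back2$entries$text, "tired today")
  expect_equal(back2$entries$day, 10L)
})

test_that("round-trip is the identity on randomized cohorts", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 3L
    ids <- paste0("r", seq_len(n))
    baselines <- data.frame(
      participant_id = ids,
      age_years = sample(20:40, n),
      race_ethnicity = sample(c("White", "Black", "Hispanic/Latinx",
                                "Asian", "other"), n, replace = TRUE),
      income_ge_50k = sample(0:1, n, TRUE),
      education_ge_associate = sample(0:1, n, TRUE),
      history_depression = sample(0:1, n, TRUE),
      history_anxiety = sample(0:1, n, TRUE), stringsAsFactors = FALSE)
    entries <- data.frame(
      participant_id = sample(ids, 5, TRUE),
      day = sample(0:200, 5), text = paste("text", sample(letters, 5)),
      stringsAsFactors = FALSE)
    moods <- data.frame(participant_id = sample(ids, 4, TRUE),
                        day = sample(0:200, 4), mood = sample(1:5, 4, TRUE),
                        stringsAsFactors = FALSE)
    epds <- data.frame(participant_id = sample(ids, 4, TRUE),
                       day = sample(0:200, 4), score = sample(0:30, 4),
                       stringsAsFactors = FALSE)
    ch <- cohort(baselines, entries, moods, epds)
    back <- read_cohort(write_cohort(ch, tempfile()))
    expect_equal(back$entries, ch$entries)
    expect_equal(back$moods, ch$moods)
    expect_equal(back$epds, ch$epds)
    # rereading the same files twice yields identical cohorts
    pp <- write_cohort(ch, tempfile())
    expect_identical(read_cohort(pp), read_cohort(pp))
  }
})

test_that("record validation rejects out-of-range values", {
  ch <- small_cohort()
  bad_mood <- ch$moods
  bad_mood$mood[1] <- 6L
  expect_error(cohort(ch$baselines, ch$entries, bad_mood, ch$epds),
               "mood")
  bad_epds <- ch$epds
  bad_epds$score[1] <- 31L
  expect_error(cohort(ch$baselines, ch$entries, ch$moods, bad_epds),
               "EPDS")
  bad_entry <- ch$entries
  bad_entry$text[1] <- ""
  expect_error(cohort(ch$baselines, bad_entry), "non-empty")

  # a mood=6 in the file surfaces as a validation error on read
  dir <- tempfile()
  paths <- write_cohort(ch, dir)
  lines <- readLines(paths$moods)
  writeLines(gsub("\"mood\":4", "\"mood\":6", lines, fixed = TRUE),
             paths$moods)
  expect_error(read_cohort(paths), "mood")
})

test_that("malformed JSONL errors name the file and line", {
  ch <- small_cohort()
  paths <- write_cohort(ch, tempfile())
  lines <- readLines(paths$entries)
  lines[2] <- "{not json"
  writeLines(lines, paths$entries)
  expect_error(read_cohort(paths), "line 2")
})

test_that("EPDS severity categories partition 0..30 at the cut-points", {
  expect_equal(as.character(categorize_epds(c(0, 6))), c("none", "none"))
  expect_equal(as.character(categorize_epds(c(7, 13))), c("mild", "mild"))
  expect_equal(as.character(categorize_epds(c(14, 19))),
               c("moderate", "moderate"))
  expect_equal(as.character(categorize_epds(c(20, 30))),
               c("severe", "severe"))
  # partition: every integer maps to exactly one category
  cats <- categorize_epds(0:30)
  expect_false(any(is.na(cats)))
  expect_equal(as.numeric(table(cats)), c(7, 7, 6, 11))
  expect_error(categorize_epds(31), "0..30")
  expect_error(categorize_epds(-1), "0..30")
  expect_error(categorize_epds(7.5), "0..30")
})
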