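entries_df <- function(days, pid = "p1") {
  data.frame(participant_id = rep(pid, length(days)), day = days,
             text = if (length(days)) paste0("t", days) else character(0),
             stringsAsFactors = FALSE)
}
epds_df <- function(days, scores, pid = "p1") {
  data.frame(participant_id = rep(pid, length(days)), day = days,
             score = scores, stringsAsFactors = FALSE)
}

test_that("entries preceding a screen are concatenated and forward-averaged", {
  # entries at 10 and 40, screens at 50 and 130, window 60: one sample;
  # the screen at 130 is 90 days after the anchor and is excluded
  s <- pair_text_epds(entries_df(c(10, 40)), epds_df(c(50, 130), c(8, 20)),
                      60)
  expect_equal(nrow(s), 1L)
  expect_equal(s$concatenated_text, "t10 t40")
  expect_equal(s$mean_epds, 8)
  expect_equal(s$entry_days[[1]], c(10, 40))

  # averaging continues while no newer entry arrives
  s2 <- pair_text_epds(entries_df(10), epds_df(c(20, 60), c(10, 20)), 60)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$mean_epds, 15)
  expect_equal(s2$n_epds, 2L)

  # no entries -> no samples
  s3 <- pair_text_epds(entries_df(integer(0)), epds_df(50, 9), 60)
  expect_equal(nrow(s3), 0L)
  # no screens -> no samples
  s4 <- pair_text_epds(entries_df(10), epds_df(integer(0), integer(0)), 60)
  expect_equal(nrow(s4), 0L)
})

test_that("a newer text entry stops the averaging window", {
  # screen at 20 follows entry 10; entry 30 starts a new cluster, so the
  # screen at 50 belongs to the second sample only
  s <- pair_text_epds(entries_df(c(10, 30)), epds_df(c(20, 50), c(10, 20)),
                      60)
  expect_equal(nrow(s), 2L)
  expect_equal(s$mean_epds, c(10, 20))
  expect_equal(s$concatenated_text, c("t10", "t30"))
})

test_that("a screen on the anchor day counts as following (difference 0)", {
  s <- pair_text_epds(entries_df(10), epds_df(10, 12), 30)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_epds, 12)
})

test_that("label binarization follows the moderate-to-severe > 13 rule", {
  s <- pair_text_epds(entries_df(10), epds_df(c(20, 30), c(13, 14)), 60)
  expect_equal(s$mean_epds, 13.5)
  expect_equal(s$label_moderate_severe, 1L)
  s2 <- pair_text_epds(entries_df(10), epds_df(20, 13), 60)
  expect_equal(s2$label_moderate_severe, 0L)
})

test_that("unsorted input is rejected", {
  e <- entries_df(c(40, 10))
  expect_error(pair_text_epds(e, epds_df(50, 9), 60), "sorted")
  expect_error(pair_text_epds(entries_df(10), epds_df(c(60, 20), c(1, 2)),
                              60), "sorted")
})

test_that("pairing matches the literal brute-force oracle on random timelines", {
  set.seed(11)
  for (i in 1:200) {
    tl <- random_timeline()
    for (W in c(30, 60)) {
      got <- pair_text_epds(
        entries_df(tl$entry_days),
        epds_df(tl$epds_days, tl$epds_scores), W)
      want <- oracle_pair(tl$entry_days, paste0("t", tl$entry_days),
                          tl$epds_days, tl$epds_scores, W)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$mean_epds,
                     vapply(want, `[[`, numeric(1), "mean_epds"))
        expect_equal(got$concatenated_text,
                     vapply(want, `[[`, character(1), "text"))
        expect_equal(got$entry_days, lapply(want, `[[`, "entry_days"))
      }
    }
  }
})

test_that("shrinking the window never adds contributing screens and samples stay well-formed", {
  set.seed(23)
  for (i in 1:60) {
    tl <- random_timeline()
    s60 <- pair_text_epds(entries_df(tl$entry_days),
                          epds_df(tl$epds_days, tl$epds_scores), 60)
    s30 <- pair_text_epds(entries_df(tl$entry_days),
                          epds_df(tl$epds_days, tl$epds_scores), 30)
    expect_lte(sum(s30$n_epds), sum(s60$n_epds))
    for (s in list(s30, s60)) {
      if (nrow(s) == 0L) next
      expect_true(all(vapply(s$entry_days, length, integer(1)) >= 1L))
      expect_true(all(s$n_epds >= 1L))
      expect_true(all(s$mean_epds >= 0 & s$mean_epds <= 30))
      # every screen contributes to at most one sample: the day-multiset
      # of contributing screens never exceeds the timeline's multiset
      all_screens <- unlist(s$epds_days)
      lev <- sort(unique(c(all_screens, tl$epds_days)))
      used <- table(factor(all_screens, levels = lev))
      avail <- table(factor(tl$epds_days, levels = lev))
      expect_true(all(used <= avail))
      # retained entries precede the first contributing screen within W
      W <- s$window_days[1]
      for (r in seq_len(nrow(s))) {
        expect_true(all(min(s$epds_days[[r]]) - s$entry_days[[r]] <= W))
        expect_true(all(s$entry_days[[r]] <= max(s$epds_days[[r]])))
      }
    }
  }
})

test_that("mood summaries cover the sample timeframe and absent mood keeps the sample", {
  s <- pair_text_epds(entries_df(c(10, 20)), epds_df(30, 9), 30)
  moods <- data.frame(participant_id = "p1", day = c(5, 12, 25, 55),
                      mood = c(1L, 3L, 5L, 2L), stringsAsFactors = FALSE)
  out <- attach_mood(s, moods, 30)
  # window [10, 50]: moods 3, 5 (and day-55 excluded, day-5 excluded)
  expect_equal(out$mood_mean, 4)
  expect_equal(out$mood_min, 3)
  expect_equal(out$mood_max, 5)

  none <- attach_mood(s, moods[moods$day > 100, , drop = FALSE], 30)
  expect_true(is.na(none$mood_mean))
  expect_equal(nrow(none), 1L)

  single <- attach_mood(s, moods[moods$day == 12, , drop = FALSE], 30)
  expect_equal(single$mood_mean, 3)
  expect_equal(single$mood_min, 3)
  expect_equal(single$mood_max, 3)

  # symptom flag: any in-window report
  sym <- data.frame(participant_id = "p1", day = 12L,
                    physical_symptom = 1L, stringsAsFactors = FALSE)
  expect_equal(attach_mood(s, moods, 30, sym)$symptom_any, 1L)
  sym0 <- data.frame(participant_id = "p1", day = 12L,
                     physical_symptom = 0L, stringsAsFactors = FALSE)
  expect_equal(attach_mood(s, moods, 30, sym0)$symptom_any, 0L)
})

test_that("the usability filter keeps only samples with a meaningful token", {
  s <- pair_text_epds(entries_df(c(1, 2, 3)), epds_df(c(1, 2, 3), c(1, 2, 3)), 30)
  s$concatenated_text <- c("I did be yes today", "migraine", "")
  s$mean_epds <- c(1, 2, 3)
  kept <- filter_usable(s, stop_list = c("i", "did", "be"),
                        common_list = c("yes", "today"))
  expect_equal(kept$concatenated_text, "migraine")
})
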