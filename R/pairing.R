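# Temporal pairing of text entries with subsequent EPDS screens.
#
# Rule set (per participant, all days integer, window W in {30, 60}):
#   * Entries accumulate into a cluster. A new cluster begins at the first
#     entry that occurs strictly after at least one EPDS screen has followed
#     the current cluster (EPDS day >= cluster's last entry day). Entries
#     arriving before any EPDS extend the current cluster.
#   * The cluster's anchor is its last entry day. EPDS screens with
#     anchor <= day <= anchor + W contribute, but averaging stops at the
#     first entry of the next cluster (strictly before it). An EPDS on the
#     same day as an entry counts as following that entry (difference 0).
#   * The label is the mean of contributing scores; entries more than W days
#     before the earliest contributing screen are dropped from the sample so
#     every retained entry precedes a contributing screen within W days.
#   * Clusters with no contributing screen, and screens with no preceding
#     cluster, are eliminated.

.pair_one <- function(entries, epds, window_days) {
  ed <- entries$day
  if (is.unsorted(ed)) stop("entries must be sorted by day", call. = FALSE)
  sd_ <- epds$day
  if (is.unsorted(sd_)) stop("EPDS must be sorted by day", call. = FALSE)
  if (length(ed) == 0L || length(sd_) == 0L) return(NULL)

  clusters <- list()
  cur <- 1L
  if (length(ed) > 1L) {
    for (j in 2L:length(ed)) {
      last_day <- ed[cur[length(cur)]]
      if (any(sd_ >= last_day & sd_ < ed[j])) {
        clusters[[length(clusters) + 1L]] <- cur
        cur <- j
      } else {
        cur <- c(cur, j)
      }
    }
  }
  clusters[[length(clusters) + 1L]] <- cur

  out <- list()
  for (ci in seq_along(clusters)) {
    idx <- clusters[[ci]]
    anchor <- ed[idx[length(idx)]]
    next_entry <- if (ci < length(clusters)) ed[clusters[[ci + 1L]][1L]]
                  else Inf
    in_e <- which(sd_ >= anchor & sd_ <= anchor + window_days &
                    sd_ < next_entry)
    if (length(in_e) == 0L) next
    d1 <- min(sd_[in_e])
    keep <- idx[ed[idx] >= d1 - window_days]
    out[[length(out) + 1L]] <- list(
      entry_days = ed[keep],
      concatenated_text = paste(entries$text[keep], collapse = " "),
      mean_epds = mean(epds$score[in_e]),
      n_epds = length(in_e),
      epds_days = sd_[in_e]
    )
  }
  out
}

#' Pair text entries with subsequent EPDS screens
#'
#' Clusters each participant's entries, concatenates their text in
#' chronological order, and labels each cluster with the forward average of
#' the EPDS screens that follow it within the window (stopping at the next
#' cluster's first entry). Clusters without a following screen and screens
#' without preceding text are dropped.
#'
#' @param entries data frame with participant_id, day, text (sorted by day
#'   within participant).
#' @param epds data frame with participant_id, day, score (sorted by day
#'   within participant).
#' @param window_days 30 or 60.
#' @return data frame of paired samples: participant_id, window_days,
#'   entry_days and epds_days (list columns), concatenated_text, mean_epds,
#'   n_epds, label_moderate_severe (mean_epds > 13).
#' @export
pair_text_epds <- function(entries, epds, window_days) {
  stopifnot(window_days %in% c(30, 60))
  entries <- as.data.frame(entries)
  epds <- as.data.frame(epds)
  ids <- unique(entries$participant_id)
  rows <- list()
  for (pid in ids) {
    e <- entries[entries$participant_id == pid, , drop = FALSE]
    s <- epds[epds$participant_id == pid, , drop = FALSE]
    pairs <- .pair_one(e, s, window_days)
    for (p in pairs) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, window_days = window_days,
        concatenated_text = p$concatenated_text, mean_epds = p$mean_epds,
        n_epds = p$n_epds,
        label_moderate_severe = as.integer(p$mean_epds > 13),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$entry_days <- list(p$entry_days)
      rows[[length(rows)]]$epds_days <- list(p$epds_days)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(participant_id = character(0), window_days = integer(0),
                      concatenated_text = character(0), mean_epds = numeric(0),
                      n_epds = integer(0), label_moderate_severe = integer(0))
    out$entry_days <- list()
    out$epds_days <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach windowed mood and symptom summaries to paired samples
#'
#' Mood reports (and physical-symptom flags) falling in the same timeframe
#' as a sample's text — the interval from its first entry day to its anchor
#' day plus the window — are summarized to mean/min/max mood and an
#' any-symptom flag. Samples with no in-window mood carry NA summaries and
#' are retained.
#'
#' @param samples output of [pair_text_epds()].
#' @param moods data frame with participant_id, day, mood.
#' @param window_days 30 or 60 (must match the samples).
#' @param symptoms optional data frame with participant_id, day,
#'   physical_symptom.
#' @return `samples` with columns mood_mean, mood_min, mood_max,
#'   symptom_any added.
#' @export
attach_mood <- function(samples, moods, window_days, symptoms = NULL) {
  stopifnot(window_days %in% c(30, 60))
  n <- nrow(samples)
  samples$mood_mean <- rep(NA_real_, n)
  samples$mood_min <- rep(NA_real_, n)
  samples$mood_max <- rep(NA_real_, n)
  samples$symptom_any <- rep(0L, n)
  for (i in seq_len(n)) {
    pid <- samples$participant_id[i]
    days <- samples$entry_days[[i]]
    lo <- min(days)
    hi <- max(days) + window_days
    m <- moods[moods$participant_id == pid & moods$day >= lo &
                 moods$day <= hi, , drop = FALSE]
    if (nrow(m)) {
      samples$mood_mean[i] <- mean(m$mood)
      samples$mood_min[i] <- min(m$mood)
      samples$mood_max[i] <- max(m$mood)
    }
    if (!is.null(symptoms)) {
      s <- symptoms[symptoms$participant_id == pid & symptoms$day >= lo &
                      symptoms$day <= hi, , drop = FALSE]
      samples$symptom_any[i] <- as.integer(nrow(s) > 0 &&
                                             any(s$physical_symptom == 1L))
    }
  }
  samples
}

#' Keep samples with at least one meaningful token
#'
#' The usability filter: a sample is retained only if its concatenated text
#' keeps at least one token after normalization and stop/common-word
#' removal.
#'
#' @param samples output of [pair_text_epds()] / [attach_mood()].
#' @param stop_list,common_list word lists passed to [remove_common()].
#' @return the usable subset of `samples`.
#' @export
filter_usable <- function(samples, stop_list = default_stopwords(),
                          common_list = default_common_words()) {
  if (nrow(samples) == 0L) return(samples)
  keep <- vapply(samples$concatenated_text, function(txt) {
    length(remove_common(normalize_text(txt), stop_list, common_list)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
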