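# Cohort container and record-file IO.
#
# A cohort is a list of five data frames sharing a participant_id key:
#   baselines: participant_id, age_years, race_ethnicity, income_ge_50k,
#              education_ge_associate, history_depression, history_anxiety
#   entries:   participant_id, day, text
#   moods:     participant_id, day, mood            (1..5)
#   epds:      participant_id, day, score           (0..30)
#   symptoms:  participant_id, day, physical_symptom (0/1)
# Record files are JSON-Lines (one object per line); baselines are CSV.

RACE_LEVELS <- c("White", "Black", "Hispanic/Latinx", "Asian", "other")

.empty_records <- function(value_col, value_type) {
  df <- data.frame(participant_id = character(0), day = integer(0))
  df[[value_col]] <- value_type(0)
  df
}

#' Construct a cohort object
#'
#' Validates every record against the domain invariants (day >= 0, non-empty
#' text, mood in 1..5, EPDS in 0..30, binary symptom flag) and sorts records
#' by (participant_id, day).
#'
#' @param baselines data frame of per-participant baseline covariates.
#' @param entries data frame of timestamped free-text entries.
#' @param moods data frame of 1-5 Likert mood reports.
#' @param epds data frame of EPDS screen scores (0-30).
#' @param symptoms data frame of binary physical-symptom reports.
#' @return an object of class `perilang_cohort`.
#' @export
cohort <- function(baselines,
                   entries = .empty_records("text", character),
                   moods = .empty_records("mood", integer),
                   epds = .empty_records("score", integer),
                   symptoms = .empty_records("physical_symptom", integer)) {
  obj <- structure(
    list(baselines = as.data.frame(baselines),
         entries = as.data.frame(entries),
         moods = as.data.frame(moods),
         epds = as.data.frame(epds),
         symptoms = as.data.frame(symptoms)),
    class = "perilang_cohort"
  )
  validate_cohort(obj)
  for (nm in c("entries", "moods", "epds", "symptoms")) {
    df <- obj[[nm]]
    obj[[nm]] <- df[order(df$participant_id, df$day), , drop = FALSE]
    rownames(obj[[nm]]) <- NULL
  }
  obj$baselines <- obj$baselines[order(obj$baselines$participant_id), ,
                                 drop = FALSE]
  rownames(obj$baselines) <- NULL
  obj
}

.check <- function(ok, msg) if (!all(ok)) stop(msg, call. = FALSE)

#' Validate cohort invariants
#'
#' @param x a `perilang_cohort`.
#' @return `x`, invisibly; errors if any invariant is violated.
#' @export
validate_cohort <- function(x) {
  b <- x$baselines
  need <- c("participant_id", "age_years", "race_ethnicity", "income_ge_50k",
            "education_ge_associate", "history_depression", "history_anxiety")
  .check(need %in% names(b),
         paste("baselines missing columns:",
               paste(setdiff(need, names(b)), collapse = ", ")))
  .check(!duplicated(b$participant_id), "duplicate participant_id in baselines")
  .check(b$age_years > 0, "age_years must be positive")
  .check(b$race_ethnicity %in% RACE_LEVELS,
         paste("race_ethnicity must be one of:",
               paste(RACE_LEVELS, collapse = ", ")))
  for (col in c("income_ge_50k", "education_ge_associate",
                "history_depression", "history_anxiety")) {
    .check(b[[col]] %in% c(0L, 1L), paste(col, "must be 0/1"))
  }
  .check(x$entries$day >= 0, "entry day must be >= 0")
  .check(nzchar(x$entries$text) & !is.na(x$entries$text),
         "entry text must be non-empty")
  .check(x$moods$day >= 0, "mood day must be >= 0")
  .check(x$moods$mood %in% 1:5, "mood must be an integer in 1..5")
  .check(x$epds$day >= 0, "EPDS day must be >= 0")
  .check(x$epds$score %in% 0:30, "EPDS score must be an integer in 0..30")
  .check(x$symptoms$physical_symptom %in% c(0L, 1L),
         "physical_symptom must be 0/1")
  invisible(x)
}

#' @export
print.perilang_cohort <- function(x, ...) {
  cat("<perilang_cohort>\n")
  cat(sprintf("  participants: %d\n", nrow(x$baselines)))
  cat(sprintf("  text entries: %d | moods: %d | EPDS: %d | symptoms: %d\n",
              nrow(x$entries), nrow(x$moods), nrow(x$epds), nrow(x$symptoms)))
  invisible(x)
}

.read_jsonl <- function(path, required, value_checks = list()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
    if (is.null(rec) || !all(required %in% names(rec))) {
      stop(sprintf("malformed record in %s at line %d", path, i),
           call. = FALSE)
    }
    recs[[i]] <- rec[required]
  }
  if (length(recs) == 0L) return(NULL)
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  names(df) <- required
  df
}

#' Read a cohort from record files
#'
#' @param paths named list/vector with elements `baselines` (CSV),
#'   `entries`, `moods`, `epds`, `symptoms` (JSON-Lines). Missing optional
#'   record files yield empty tables; `baselines` is required.
#' @return a validated `perilang_cohort`.
#' @export
read_cohort <- function(paths) {
  paths <- as.list(paths)
  stopifnot(!is.null(paths$baselines))
  b <- read.csv(paths$baselines, stringsAsFactors = FALSE)
  grab <- function(key, required, value_col, value_type) {
    if (is.null(paths[[key]]) || !file.exists(paths[[key]])) {
      return(.empty_records(value_col, value_type))
    }
    df <- .read_jsonl(paths[[key]], required)
    if (is.null(df)) return(.empty_records(value_col, value_type))
    df$day <- as.integer(df$day)
    df
  }
  entries <- grab("entries", c("participant_id", "day", "text"),
                  "text", character)
  moods <- grab("moods", c("participant_id", "day", "mood"), "mood", integer)
  if (nrow(moods)) moods$mood <- as.integer(moods$mood)
  epds <- grab("epds", c("participant_id", "day", "score"), "score", integer)
  if (nrow(epds)) epds$score <- as.integer(epds$score)
  symptoms <- grab("symptoms", c("participant_id", "day", "physical_symptom"),
                   "physical_symptom", integer)
  if (nrow(symptoms)) {
    symptoms$physical_symptom <- as.integer(symptoms$physical_symptom)
  }
  cohort(b, entries, moods, epds, symptoms)
}

.write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Write a cohort to record files
#'
#' Inverse of [read_cohort()]: baselines as CSV, the four record streams as
#' JSON-Lines, into `dir` with fixed file names.
#'
#' @param x a `perilang_cohort`.
#' @param dir output directory (created if absent).
#' @return named list of the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "perilang_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(baselines = file.path(dir, "baselines.csv"),
                entries = file.path(dir, "entries.jsonl"),
                moods = file.path(dir, "moods.jsonl"),
                epds = file.path(dir, "epds.jsonl"),
                symptoms = file.path(dir, "symptoms.jsonl"))
  write.csv(x$baselines, paths$baselines, row.names = FALSE)
  .write_jsonl(x$entries, paths$entries)
  .write_jsonl(x$moods, paths$moods)
  .write_jsonl(x$epds, paths$epds)
  .write_jsonl(x$symptoms, paths$symptoms)
  invisible(paths)
}

#' EPDS severity category
#'
#' Maps integer EPDS totals to the screening cut-points used clinically:
#' 0-6 none, 7-13 mild, 14-19 moderate, 20-30 severe. Applies to raw integer
#' screens only; averaged (fractional) labels are binarized by the model's
#' > 13 rule instead, never categorized.
#'
#' @param score integer vector of EPDS totals in 0..30.
#' @return factor with levels none, mild, moderate, severe.
#' @examples
#' categorize_epds(c(0, 6, 7, 13, 14, 19, 20, 30))
#' @export
categorize_epds <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 0) || any(score > 30)) {
    stop("EPDS score must be an integer in 0..30", call. = FALSE)
  }
  cut(as.integer(score), breaks = c(-1, 6, 13, 19, 30),
      labels = c("none", "mild", "moderate", "severe"))
}
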