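# Orchestration: simulate (or load) -> pair -> featurize -> fit -> report
# for 2 windows x 3 variants, with a run manifest and a rendered markdown
# summary. Reruns with the same config + seed are bit-identical.

#' Pipeline configuration
#'
#' @param out_dir run directory (created by [run_all()]).
#' @param seed global integer seed; stage seeds derive from it.
#' @param generator a `perilang_genspec` for simulated runs, or NULL to
#'   load a cohort from `cohort_dir`.
#' @param cohort_dir directory of cohort record files (see
#'   [read_cohort()]); ignored when `generator` is given.
#' @param resources a `perilang_resources` bundle (packaged fixtures by
#'   default).
#' @param windows EPDS pairing windows to run.
#' @param variants model variants to run.
#' @param k LDA topic count for the NLP block.
#' @param log_level "info" or "quiet".
#' @return a `perilang_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, generator = NULL,
                            cohort_dir = NULL,
                            resources = feature_resources(),
                            windows = c(30, 60),
                            variants = c("baseline_only",
                                         "baseline_plus_nlp",
                                         "baseline_nlp_mood_symptoms"),
                            k = 5L, log_level = "info") {
  stopifnot(!is.null(seed), all(windows %in% c(30, 60)),
            all(variants %in% .MODEL_VARIANTS))
  if (is.null(generator) && is.null(cohort_dir)) {
    stop("either a generator spec or a cohort_dir is required",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "perilang_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: out_dir, seed, cohort_dir, windows, variants, k,
#' log_level, generator (a mapping of [generator_spec()] arguments, with
#' `effects` as a nested mapping), resources (paths lexicon/themes/
#' embeddings/stopwords/common_words).
#'
#' @param path YAML file.
#' @return a `perilang_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) {
    gargs <- y$generator
    if (!is.null(gargs$effects)) {
      eff <- effect_sizes()
      for (nm in names(gargs$effects)) eff[[nm]] <- gargs$effects[[nm]]
      gargs$effects <- eff
    }
    gen <- do.call(generator_spec, gargs)
  }
  res_args <- y$resources %||% list()
  resources <- feature_resources(
    lexicon = res_args$lexicon, themes = res_args$themes,
    embeddings = res_args$embeddings,
    stop_list = if (is.null(res_args$stopwords)) default_stopwords()
                else read_wordlist(res_args$stopwords),
    common_list = if (is.null(res_args$common_words))
                    default_common_words()
                  else read_wordlist(res_args$common_words))
  pipeline_config(out_dir = y$out_dir %||% tempfile("perilang_run_"),
                  seed = y$seed %||% 1,
                  generator = gen, cohort_dir = y$cohort_dir,
                  resources = resources,
                  windows = unlist(y$windows %||% c(30, 60)),
                  variants = unlist(y$variants %||% .MODEL_VARIANTS),
                  k = as.integer(y$k %||% 5L),
                  log_level = y$log_level %||% "info")
}

.log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[perilang] ", fmt), ...))
}

.fit_to_report <- function(fit) {
  list(window_days = fit$window_days, variant = fit$variant,
       selected_penalty = fit$selected_penalty,
       intercept = fit$intercept,
       train_dev_auroc = fit$train_dev_auroc,
       test_auroc = fit$test_auroc,
       train_dev_r2 = fit$train_dev_r2, test_r2 = fit$test_r2,
       n_entries_per_split = as.list(fit$n_entries_per_split),
       retained_by_family = as.list(fit$retained_by_family),
       coefficients = as.list(fit$coefficients[fit$coefficients != 0]))
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort, runs every (window, variant) experiment,
#' and writes to the run directory: cohort record files, per-window
#' feature matrices (`features_<w>.csv`), per-experiment reports
#' (`report_<w>_<variant>.json`), coefficient tables
#' (`coefficients_<w>_<variant>.csv`), cohort descriptives
#' (`descriptives.json`) and a manifest (seed, config hash, package
#' version).
#'
#' @param config a `perilang_config`.
#' @return list of `perilang_fit` objects (invisibly), named
#'   `<window>_<variant>`; side effect: populated run directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "perilang_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$generator)) {
    .log(config, "simulating cohort (n = %d, seed = %s)",
         config$generator$n_participants, format(config$generator$seed))
    sim <- generate_cohort(config$generator)
    ch <- sim$cohort
    gt_path <- file.path(config$out_dir, "ground_truth.json")
    jsonlite::write_json(list(severity = sim$ground_truth$severity,
                              effects = sim$ground_truth$effects),
                         gt_path, auto_unbox = TRUE, digits = NA)
  } else {
    .log(config, "loading cohort from %s", config$cohort_dir)
    ch <- read_cohort(list(
      baselines = file.path(config$cohort_dir, "baselines.csv"),
      entries = file.path(config$cohort_dir, "entries.jsonl"),
      moods = file.path(config$cohort_dir, "moods.jsonl"),
      epds = file.path(config$cohort_dir, "epds.jsonl"),
      symptoms = file.path(config$cohort_dir, "symptoms.jsonl")))
  }
  cohort_dir <- file.path(config$out_dir, "cohort")
  write_cohort(ch, cohort_dir)

  desc <- summarize_cohort(ch)
  jsonlite::write_json(unclass(desc),
                       file.path(config$out_dir, "descriptives.json"),
                       auto_unbox = TRUE, digits = NA)

  fits <- list()
  for (w in config$windows) {
    wrote_features <- FALSE
    for (v in config$variants) {
      .log(config, "experiment: %d-day window, %s", w, v)
      spec <- model_spec(window_days = w, variant = v, k = config$k,
                         seed = config$seed)
      fit <- run_experiment(ch, config$resources, spec)
      fits[[sprintf("%d_%s", w, v)]] <- fit
      jsonlite::write_json(
        .fit_to_report(fit),
        file.path(config$out_dir, sprintf("report_%d_%s.json", w, v)),
        auto_unbox = TRUE, digits = NA)
      write.csv(fit$coef_table,
                file.path(config$out_dir,
                          sprintf("coefficients_%d_%s.csv", w, v)),
                row.names = FALSE)
      if (!wrote_features && v != "baseline_only") {
        fm <- data.frame(participant_id = fit$sample_index$participant_id,
                         split = fit$sample_index$split,
                         mean_epds = fit$sample_index$mean_epds,
                         fit$features, check.names = FALSE)
        write.csv(fm, file.path(config$out_dir,
                                sprintf("features_%d.csv", w)),
                  row.names = FALSE)
        wrote_features <- TRUE
      }
    }
  }

  cfg_for_hash <- config[c("seed", "windows", "variants", "k")]
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_for_hash, cfg_file, auto_unbox = TRUE)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("perilang")),
    windows = config$windows, variants = config$variants, k = config$k,
    simulated = !is.null(config$generator))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  render_report(config$out_dir)
  invisible(fits)
}

.fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x) | is.null(x), "NA", formatC(x, digits = digits,
                                              format = "f"))
}

#' Render a markdown summary of a completed run
#'
#' Tables of AUROC/R^2 per (window, variant), retained-feature counts per
#' family, top coefficients by magnitude, and the cohort severity-category
#' proportions. Missing stage outputs produce a partial report with
#' warnings.
#'
#' @param run_dir directory produced by [run_all()].
#' @return the markdown text (character), invisibly; side effect: writes
#'   `report.md` into `run_dir`.
#' @export
render_report <- function(run_dir) {
  lines <- c("# perilang run report", "")
  mf <- file.path(run_dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf)
    lines <- c(lines, sprintf("Seed: %s | config hash: %s | version: %s",
                              m$seed, m$config_hash, m$package_version), "")
  } else {
    warning("manifest.json missing; partial report", call. = FALSE)
  }

  dfile <- file.path(run_dir, "descriptives.json")
  if (file.exists(dfile)) {
    d <- jsonlite::read_json(dfile)
    lines <- c(lines, "## Cohort descriptives", "",
               sprintf("- participants: %s", d$n_participants),
               sprintf("- entries/participant: %.2f",
                       d$entries_per_participant[[1]]),
               sprintf("- words/entry: %.1f (SD %.1f)",
                       d$words_per_entry[[1]], d$words_per_entry[[2]]),
               sprintf("- EPDS severity proportions: %s",
                       paste(sprintf("%s %.3f",
                                     names(d$severity_proportions),
                                     unlist(d$severity_proportions)),
                             collapse = ", ")),
               "")
  } else {
    warning("descriptives.json missing; partial report", call. = FALSE)
  }

  reports <- sort(list.files(run_dir, pattern = "^report_.*\\.json$",
                             full.names = TRUE))
  if (length(reports)) {
    lines <- c(lines, "## Model results", "",
               "| Window | Variant | Train+dev AUROC | Test AUROC | Test R2 |",
               "|---|---|---|---|---|")
    near_chance <- character(0)
    for (rf in reports) {
      r <- jsonlite::read_json(rf)
      ta <- if (is.null(r$test_auroc)) NA_real_ else r$test_auroc
      lines <- c(lines, sprintf(
        "| %d-day | %s | %s | %s | %s |", r$window_days, r$variant,
        .fmt_num(r$train_dev_auroc %||% NA_real_), .fmt_num(ta),
        .fmt_num(r$test_r2 %||% NA_real_)))
      if (!is.na(ta) && abs(ta - 0.5) < 0.1) {
        near_chance <- c(near_chance,
                         sprintf("%d-day %s", r$window_days, r$variant))
      }
    }
    lines <- c(lines, "")
    if (length(near_chance)) {
      lines <- c(lines, sprintf(
        "Near-chance test AUROC (|AUROC - 0.5| < 0.1): %s.",
        paste(near_chance, collapse = "; ")), "")
    }
    lines <- c(lines, "## Retained features and top coefficients", "")
    for (rf in reports) {
      r <- jsonlite::read_json(rf)
      lines <- c(lines, sprintf("### %d-day, %s", r$window_days, r$variant),
                 "",
                 sprintf("Retained per family: %s",
                         paste(sprintf("%s %s", names(r$retained_by_family),
                                       unlist(r$retained_by_family)),
                               collapse = ", ")), "")
      co <- unlist(r$coefficients)
      if (length(co)) {
        co <- co[order(-abs(co))]
        top <- head(co, 10L)
        lines <- c(lines, "| Feature | Coefficient |", "|---|---|",
                   sprintf("| %s | %+.4f |", names(top), top), "")
      } else {
        lines <- c(lines, "(no nonzero coefficients)", "")
      }
    }
  } else {
    warning("no report_*.json found; partial report", call. = FALSE)
  }

  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(run_dir, "report.md"))
  invisible(txt)
}
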