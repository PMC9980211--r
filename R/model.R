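# Participant-grouped splitting, standardization, cross-validated LASSO and
# evaluation. The LASSO is glmnet's gaussian coordinate descent with the
# objective 1/(2n) RSS + lambda * ||beta||_1, so the analytic null penalty
# is lambda_max = max_j |x_j' (y - ybar)| / n on standardized columns.

#' Log-spaced LASSO penalty grid
#'
#' 50 points log-spaced on \[1e-4, 1\].
#'
#' @return decreasing-free numeric vector (ascending).
#' @export
lasso_penalty_grid <- function() {
  exp(seq(log(1e-4), log(1), length.out = 50L))
}

#' Split participants into train / development / test sets
#'
#' Assignment is by participant: every sample of a participant shares a
#' split. Counts follow the rounded fractions (test and dev rounded, the
#' remainder to train). Deterministic given the seed.
#'
#' @param participant_ids character vector of unique participant ids (a
#'   `perilang_cohort` is also accepted).
#' @param fractions length-3 numeric (train, dev, test), summing to 1.
#' @param seed integer seed.
#' @return data frame: participant_id, split (factor train/dev/test).
#' @export
split_participants <- function(participant_ids,
                               fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (inherits(participant_ids, "perilang_cohort")) {
    participant_ids <- participant_ids$baselines$participant_id
  }
  ids <- unique(as.character(participant_ids))
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 participants to split", call. = FALSE)
  n_dev <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_dev - n_test
  if (min(n_train, n_dev, n_test) < 1L) {
    stop("fractions leave an empty split", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  perm <- sample(ids)
  split <- rep(c("train", "dev", "test"), c(n_train, n_dev, n_test))
  out <- data.frame(participant_id = perm, split = factor(split,
    levels = c("train", "dev", "test")), stringsAsFactors = FALSE)
  out[order(out$participant_id), , drop = FALSE]
}

#' Standardize feature columns to mean 0, SD 1
#'
#' Estimates centers and scales on the training matrix; zero-variance
#' columns are mapped to all-zeros with a warning. The returned parameters
#' are reapplied to development/test columns via [apply_standardization()].
#'
#' @param train_matrix numeric matrix (>= 2 rows).
#' @return list: `x` (transformed training matrix), `center`, `scale`.
#' @export
standardize_features <- function(train_matrix) {
  stopifnot(is.matrix(train_matrix), nrow(train_matrix) >= 2L)
  center <- colMeans(train_matrix)
  scale_ <- apply(train_matrix, 2L, sd)
  zero <- !is.finite(scale_) | scale_ == 0
  if (any(zero)) {
    warning(sprintf("zero-variance columns mapped to 0: %s",
                    paste(colnames(train_matrix)[zero], collapse = ", ")),
            call. = FALSE)
    scale_[zero] <- 1
    center[zero] <- colMeans(train_matrix)[zero]
  }
  list(x = apply_standardization(list(center = center, scale = scale_),
                                 train_matrix),
       center = center, scale = scale_)
}

#' @rdname standardize_features
#' @param params list with `center` and `scale` from
#'   [standardize_features()].
#' @param new_matrix matrix with the same columns as the training matrix.
#' @export
apply_standardization <- function(params, new_matrix) {
  sweep(sweep(new_matrix, 2L, params$center, "-"), 2L, params$scale, "/")
}

# NA-block mean imputation fitted on training rows
.fit_impute <- function(train_matrix) {
  mu <- colMeans(train_matrix, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  mu
}

.apply_impute <- function(mu, m) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mu[j]
  }
  m
}

#' Tie-corrected rank AUROC
#'
#' Probability that a random positive outranks a random negative, ties
#' counting one half (equivalent to the Mann-Whitney U statistic). With all
#' scores equal this is exactly 0.5.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 (or logical) outcomes.
#' @return AUROC in \[0, 1\], or NA with a warning if only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC undefined: test labels are all one class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Fit a LASSO with cross-validated penalty
#'
#' Five-fold cross validation on the pooled training + development rows,
#' folds grouped by participant, scanning the penalty grid; the penalty
#' minimizing mean CV MSE (ties broken toward the larger penalty, i.e. the
#' sparser model) is refit on all supplied rows.
#'
#' @param x standardized numeric feature matrix (train + dev rows).
#' @param y numeric mean-EPDS labels.
#' @param groups participant id per row (grouped folds).
#' @param seed integer seed for the fold assignment.
#' @param penalty_grid penalties to scan, all within \[1e-4, 1\].
#' @param cv_folds number of folds.
#' @return a `perilang_lasso` list: `selected_penalty`, `intercept`,
#'   `coefficients` (named, standardized scale), `cv_mse` (per penalty),
#'   `nonzero` (count per penalty), `glmnet_fit`.
#' @export
fit_lasso_cv <- function(x, y, groups, seed = 1,
                         penalty_grid = lasso_penalty_grid(),
                         cv_folds = 5L) {
  if (length(penalty_grid) == 0L) stop("empty penalty grid", call. = FALSE)
  stopifnot(nrow(x) == length(y), length(groups) == length(y))
  grid <- sort(penalty_grid) # ascending
  lambda_path <- rev(grid)   # glmnet wants decreasing

  ug <- unique(groups)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  fold_of_group <- setNames(sample(rep_len(seq_len(cv_folds), length(ug))),
                            ug)
  fold <- fold_of_group[as.character(groups)]

  mse <- matrix(NA_real_, nrow = cv_folds, ncol = length(grid))
  for (f in seq_len(cv_folds)) {
    tr <- which(fold != f)
    ho <- which(fold == f)
    if (length(ho) == 0L || length(tr) < 2L) next
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "gaussian",
                          lambda = lambda_path, standardize = FALSE,
                          thresh = 1e-9)
    # interpolation at the supplied grid; suppress approx()'s tie notice
    pred <- suppressWarnings(predict(fit, newx = x[ho, , drop = FALSE],
                                     s = grid, exact = FALSE))
    mse[f, ] <- colMeans((y[ho] - pred)^2)
  }
  cv_mse <- colMeans(mse, na.rm = TRUE)
  best_mse <- min(cv_mse)
  # ties -> larger penalty (sparser model)
  sel <- max(grid[cv_mse <= best_mse + 1e-12])

  final <- glmnet::glmnet(x, y, family = "gaussian", lambda = lambda_path,
                          standardize = FALSE, thresh = 1e-9)
  beta <- suppressWarnings(coef(final, s = sel, exact = TRUE, x = x, y = y))
  coefs <- as.numeric(beta)[-1]
  names(coefs) <- rownames(beta)[-1]
  nz <- vapply(grid, function(l) {
    b <- suppressWarnings(coef(final, s = l, exact = FALSE))
    sum(as.numeric(b)[-1] != 0)
  }, numeric(1))
  structure(list(selected_penalty = sel,
                 intercept = as.numeric(beta)[1],
                 coefficients = coefs,
                 cv_mse = setNames(cv_mse, format(grid, digits = 6)),
                 penalty_grid = grid,
                 nonzero = setNames(nz, format(grid, digits = 6)),
                 glmnet_fit = final),
            class = "perilang_lasso")
}

#' @export
print.perilang_lasso <- function(x, ...) {
  cat(sprintf("<perilang_lasso> penalty %.5g, %d/%d nonzero coefficients\n",
              x$selected_penalty, sum(x$coefficients != 0),
              length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted LASSO
#'
#' @param object a `perilang_lasso`.
#' @param newx standardized feature matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.perilang_lasso <- function(object, newx, ...) {
  as.numeric(object$intercept +
               newx %*% object$coefficients[colnames(newx)])
}

#' Evaluate continuous EPDS predictions on a test set
#'
#' AUROC uses the moderate-to-severe rule (true mean EPDS > 13) against the
#' continuous predictions; R^2 = 1 - SSE/SST on the continuous labels.
#'
#' @param fit a `perilang_lasso`.
#' @param x_test standardized test feature matrix.
#' @param y_test continuous mean-EPDS test labels.
#' @return list: `auroc`, `r2`, `predictions`.
#' @export
evaluate <- function(fit, x_test, y_test) {
  pred <- predict(fit, x_test)
  a <- auroc(pred, y_test > 13)
  sst <- sum((y_test - mean(y_test))^2)
  r2 <- if (sst > 0) 1 - sum((y_test - pred)^2) / sst else NA_real_
  list(auroc = a, r2 = r2, predictions = pred)
}

.MODEL_VARIANTS <- c("baseline_only", "baseline_plus_nlp",
                     "baseline_nlp_mood_symptoms")

#' Specification of one model run
#'
#' @param window_days 30 or 60.
#' @param variant one of baseline_only, baseline_plus_nlp,
#'   baseline_nlp_mood_symptoms.
#' @param k number of LDA topics for the NLP block.
#' @param penalty_grid penalties in \[1e-4, 1\].
#' @param cv_folds CV folds for the penalty search.
#' @param split_fractions train/dev/test fractions.
#' @param seed integer seed (split, folds, LDA).
#' @return a `perilang_modelspec` list.
#' @export
model_spec <- function(window_days = 30, variant = "baseline_plus_nlp",
                       k = 5L, penalty_grid = lasso_penalty_grid(),
                       cv_folds = 5L, split_fractions = c(0.70, 0.15, 0.15),
                       seed = 1) {
  stopifnot(window_days %in% c(30, 60), variant %in% .MODEL_VARIANTS,
            all(penalty_grid >= 1e-4 - 1e-12 & penalty_grid <= 1 + 1e-12),
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(as.list(environment()), class = "perilang_modelspec")
}

# baseline covariate design: age, race one-hot (White = reference, dropped),
# income, education, histories
.baseline_design <- function(baselines) {
  race <- factor(baselines$race_ethnicity, levels = RACE_LEVELS)
  onehot <- sapply(RACE_LEVELS[-1], function(l) as.numeric(race == l))
  colnames(onehot) <- paste0("race_", gsub("[^A-Za-z]+", "_",
                                           RACE_LEVELS[-1]))
  m <- cbind(age_years = baselines$age_years, onehot,
             income_ge_50k = baselines$income_ge_50k,
             education_ge_associate = baselines$education_ge_associate,
             history_depression = baselines$history_depression,
             history_anxiety = baselines$history_anxiety)
  rownames(m) <- baselines$participant_id
  m
}

#' Run one end-to-end experiment (window x variant)
#'
#' Pipeline: pair text with EPDS at the window, attach mood/symptom
#' summaries, apply the usability filter, split by participant, fit the
#' topic model on training + development documents only, assemble and
#' mean-impute features with training + development parameters,
#' standardize, fit the cross-validated LASSO, and evaluate on the held-out
#' test participants. The mood variant drops samples with no in-window
#' mood report.
#'
#' @param cohort a `perilang_cohort`.
#' @param resources a `perilang_resources` bundle.
#' @param spec a `perilang_modelspec`.
#' @return a `perilang_fit` report: fit, metrics, split sizes,
#'   retained-feature counts per family, standardization/imputation
#'   parameters and topic model (for audit).
#' @export
run_experiment <- function(cohort, resources, spec) {
  stopifnot(inherits(cohort, "perilang_cohort"),
            inherits(spec, "perilang_modelspec"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  samples <- stage("pairing", {
    s <- pair_text_epds(cohort$entries, cohort$epds, spec$window_days)
    s <- attach_mood(s, cohort$moods, spec$window_days, cohort$symptoms)
    filter_usable(s, resources$stop_list, resources$common_list)
  })
  if (spec$variant == "baseline_nlp_mood_symptoms") {
    samples <- samples[!is.na(samples$mood_mean), , drop = FALSE]
  }
  if (nrow(samples) < 10L) {
    stop("[pairing] too few usable samples to model", call. = FALSE)
  }

  split <- split_participants(cohort, spec$split_fractions, spec$seed)
  smap <- setNames(as.character(split$split), split$participant_id)
  sample_split <- smap[samples$participant_id]
  traindev <- which(sample_split %in% c("train", "dev"))
  test <- which(sample_split == "test")

  use_nlp <- spec$variant != "baseline_only"
  featstage <- stage("featurize", {
    tm <- NULL
    if (use_nlp) {
      docs <- lapply(samples$concatenated_text, function(t) {
        remove_common(normalize_text(t), resources$stop_list,
                      resources$common_list)
      })
      tm <- fit_topic_model(docs[traindev], spec$k, seed = spec$seed)
      nlp <- assemble_features(samples, resources, tm)
    } else {
      nlp <- NULL
    }
    base <- .baseline_design(cohort$baselines)
    bm <- base[samples$participant_id, , drop = FALSE]
    rownames(bm) <- NULL
    m <- cbind(bm, nlp)
    if (spec$variant == "baseline_nlp_mood_symptoms") {
      m <- cbind(m, mood_mean = samples$mood_mean,
                 mood_min = samples$mood_min, mood_max = samples$mood_max,
                 symptom_any = samples$symptom_any)
    }
    list(m = m, tm = tm)
  })
  feats <- featstage$m
  topic_model <- featstage$tm

  fitres <- stage("fit", {
    impute_mu <- .fit_impute(feats[traindev, , drop = FALSE])
    x_td <- .apply_impute(impute_mu, feats[traindev, , drop = FALSE])
    std <- suppressWarnings(standardize_features(x_td))
    fit <- fit_lasso_cv(std$x, samples$mean_epds[traindev],
                        groups = samples$participant_id[traindev],
                        seed = spec$seed, penalty_grid = spec$penalty_grid,
                        cv_folds = spec$cv_folds)
    list(fit = fit, std = std, impute_mu = impute_mu)
  })

  ev <- stage("evaluate", {
    x_te <- apply_standardization(fitres$std,
                                  .apply_impute(fitres$impute_mu,
                                                feats[test, , drop = FALSE]))
    td_eval <- evaluate(fitres$fit, fitres$std$x,
                        samples$mean_epds[traindev])
    te_eval <- if (length(test)) {
      evaluate(fitres$fit, x_te, samples$mean_epds[test])
    } else list(auroc = NA_real_, r2 = NA_real_, predictions = numeric(0))
    list(td = td_eval, te = te_eval)
  })

  coefs <- fitres$fit$coefficients
  fam <- feature_family(names(coefs))
  retained <- table(factor(fam[coefs != 0],
                           levels = unique(feature_family(names(coefs)))))
  coef_table <- data.frame(feature = names(coefs), family = fam,
                           coefficient = unname(coefs),
                           stringsAsFactors = FALSE)
  coef_table <- coef_table[order(-abs(coef_table$coefficient)), ,
                           drop = FALSE]
  rownames(coef_table) <- NULL

  structure(list(
    window_days = spec$window_days, variant = spec$variant,
    selected_penalty = fitres$fit$selected_penalty,
    intercept = fitres$fit$intercept,
    coefficients = coefs,
    coef_table = coef_table,
    retained_by_family = retained,
    train_dev_auroc = ev$td$auroc, test_auroc = ev$te$auroc,
    train_dev_r2 = ev$td$r2, test_r2 = ev$te$r2,
    n_entries_per_split = c(train_dev = length(traindev),
                            test = length(test)),
    split = split,
    lasso = fitres$fit,
    standardization = list(center = fitres$std$center,
                           scale = fitres$std$scale),
    imputation = fitres$impute_mu,
    topic_model = topic_model,
    features = feats,
    sample_index = data.frame(participant_id = samples$participant_id,
                              split = unname(sample_split),
                              mean_epds = samples$mean_epds,
                              stringsAsFactors = FALSE)
  ), class = "perilang_fit")
}

#' @export
print.perilang_fit <- function(x, ...) {
  cat(sprintf("<perilang_fit> %s, %d-day window\n", x$variant,
              x$window_days))
  cat(sprintf("  samples: %d train+dev, %d test\n",
              x$n_entries_per_split["train_dev"],
              x$n_entries_per_split["test"]))
  cat(sprintf("  penalty: %.5g | test AUROC: %s | test R2: %s\n",
              x$selected_penalty,
              ifelse(is.na(x$test_auroc), "NA",
                     sprintf("%.3f", x$test_auroc)),
              ifelse(is.na(x$test_r2), "NA", sprintf("%.3f", x$test_r2))))
  invisible(x)
}
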