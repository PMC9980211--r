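# Topic modelling: LDA fit via collapsed Gibbs sampling (see
# src/lda_gibbs.cpp) and deterministic fold-in inference for new documents.
# Priors are fixed and symmetric (document-topic alpha = 0.3, topic-word
# eta = 0.05), suited to short, topically focused entries.

.LDA_ALPHA <- 0.3
.LDA_ETA <- 0.05

#' Fit a k-topic LDA model
#'
#' Collapsed Gibbs sampling with a seeded, self-contained RNG: identical
#' corpus + seed gives identical topic-word matrices. Topic-word rows sum
#' to 1. Documents are token vectors (already normalized and
#' stop/common-filtered).
#'
#' @param corpus list of character vectors (one per document).
#' @param k number of topics, 1..50.
#' @param seed integer seed for the sampler.
#' @param n_iter,burnin Gibbs iterations and burn-in (estimates average the
#'   post-burn-in samples).
#' @return a `perilang_lda` object: `k`, `vocab`, `phi` (k x V topic-word
#'   matrix), `theta` (training document loadings), `alpha`, `eta`, `seed`.
#' @export
fit_topic_model <- function(corpus, k, seed, n_iter = 200L, burnin = 100L) {
  stopifnot(is.list(corpus), k >= 1, k <= 50)
  nonempty <- vapply(corpus, length, integer(1)) > 0L
  if (sum(nonempty) < k) {
    stop(sprintf("corpus has %d non-empty documents, need at least k = %d",
                 sum(nonempty), k), call. = FALSE)
  }
  vocab <- sort(unique(unlist(corpus)))
  idx <- lapply(corpus, function(toks) {
    m <- match(toks, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  res <- .lda_gibbs_cpp(idx, length(vocab), as.integer(k),
                        .LDA_ALPHA, .LDA_ETA,
                        as.integer(n_iter), as.integer(burnin),
                        as.numeric(seed))
  phi <- res$phi
  colnames(phi) <- vocab
  structure(list(k = as.integer(k), vocab = vocab, phi = phi,
                 theta = res$theta, alpha = .LDA_ALPHA, eta = .LDA_ETA,
                 seed = seed),
            class = "perilang_lda")
}

#' @export
print.perilang_lda <- function(x, ...) {
  cat(sprintf("<perilang_lda> k = %d topics over %d terms (seed %s)\n",
              x$k, length(x$vocab), format(x$seed)))
  invisible(x)
}

#' Infer topic loadings for documents
#'
#' Deterministic fold-in: with the topic-word matrix fixed, iterates the
#' posterior responsibility update until the document-topic distribution
#' converges. Out-of-vocabulary tokens are skipped; a document with no
#' in-vocabulary token gets the uniform prior loading.
#'
#' @param model a `perilang_lda`.
#' @param corpus list of character vectors.
#' @param n_iter fixed-point iterations.
#' @return numeric matrix, one row per document, rows sum to 1.
#' @export
topic_loadings <- function(model, corpus, n_iter = 50L) {
  stopifnot(inherits(model, "perilang_lda"))
  k <- model$k
  alpha <- model$alpha
  out <- matrix(1 / k, nrow = length(corpus), ncol = k)
  colnames(out) <- paste0("topic_", seq_len(k))
  for (d in seq_along(corpus)) {
    ids <- match(corpus[[d]], model$vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) next
    pw <- model$phi[, ids, drop = FALSE] # k x n
    theta <- rep(1 / k, k)
    for (it in seq_len(n_iter)) {
      r <- pw * theta                      # k x n responsibilities
      cs <- colSums(r)
      cs[cs == 0] <- 1
      r <- sweep(r, 2L, cs, "/")
      theta_new <- (alpha + rowSums(r)) / (length(ids) + k * alpha)
      if (max(abs(theta_new - theta)) < 1e-10) {
        theta <- theta_new
        break
      }
      theta <- theta_new
    }
    out[d, ] <- theta / sum(theta)
  }
  out
}

#' Select the number of topics by split-wise LASSO predictiveness
#'
#' For each candidate k, the training samples are split five ways by
#' participant; topics are fit on each split's fit portion, loadings are
#' extracted for both portions, and a LASSO predicting the mean-EPDS label
#' from the loadings — its penalty chosen by cross validation inside the
#' fit portion, never on the held-out rows — is scored once on the held-out
#' portion. The k with the lowest mean held-out MSE wins; ties go to the
#' smallest k.
#'
#' @param corpus list of token vectors for the training samples.
#' @param y numeric mean-EPDS labels, one per document.
#' @param groups participant ids, one per document (grouped splitting).
#' @param k_values candidate topic counts, each in 1..50.
#' @param seed integer seed (split assignment and LDA fits).
#' @param n_splits number of splits of the training set.
#' @param n_iter,burnin passed to [fit_topic_model()].
#' @return list: `k` (selected), `scores` (mean held-out MSE per candidate).
#' @export
select_k <- function(corpus, y, groups, k_values, seed, n_splits = 5L,
                     n_iter = 150L, burnin = 75L) {
  if (any(k_values < 1 | k_values > 50)) {
    stop("k_values must lie in 1..50", call. = FALSE)
  }
  stopifnot(length(corpus) == length(y), length(groups) == length(y))
  k_values <- sort(unique(as.integer(k_values)))
  if (length(k_values) == 1L) {
    return(list(k = k_values, scores = setNames(NA_real_,
                                                as.character(k_values))))
  }
  ug <- unique(groups)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  fold_of_group <- setNames(sample(rep_len(seq_len(n_splits), length(ug))),
                            ug)
  fold <- fold_of_group[as.character(groups)]

  scores <- setNames(numeric(length(k_values)), as.character(k_values))
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    fold_mse <- numeric(n_splits)
    for (f in seq_len(n_splits)) {
      fit_idx <- which(fold != f)
      hold_idx <- which(fold == f)
      if (length(hold_idx) == 0L || length(fit_idx) < max(2L, k)) {
        fold_mse[f] <- NA_real_
        next
      }
      model <- fit_topic_model(corpus[fit_idx], k,
                               seed = seed + 1000L * f + k,
                               n_iter = n_iter, burnin = burnin)
      x_fit <- topic_loadings(model, corpus[fit_idx])
      x_hold <- topic_loadings(model, corpus[hold_idx])
      if (k == 1L) {
        # single topic: intercept-only prediction
        pred <- rep(mean(y[fit_idx]), length(hold_idx))
        fold_mse[f] <- mean((y[hold_idx] - pred)^2)
        next
      }
      std <- suppressWarnings(standardize_features(x_fit))
      inner <- fit_lasso_cv(std$x, y[fit_idx], groups = groups[fit_idx],
                            seed = seed + f, cv_folds = 3L)
      pred <- predict(inner, apply_standardization(std, x_hold))
      fold_mse[f] <- mean((y[hold_idx] - pred)^2)
    }
    scores[ki] <- mean(fold_mse, na.rm = TRUE)
  }
  best <- k_values[which.min(scores)] # which.min takes the first = smallest k
  list(k = best, scores = scores)
}
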