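std_design <- function(n = 200, p = 5, seed = 1, beta = NULL,
                       noise = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  colnames(x) <- paste0("f", seq_len(p))
  if (is.null(beta)) beta <- seq(0.2, 1, length.out = p)
  y <- as.numeric(x %*% beta + rnorm(n, 0, noise))
  list(x = x, y = y, beta = beta)
}

test_that("participant splits have the rounded 70/15/15 counts and are grouped", {
  s <- split_participants(paste0("p", 1:100), seed = 3)
  expect_equal(as.numeric(table(s$split)), c(70, 15, 15))
  expect_identical(split_participants(paste0("p", 1:100), seed = 3), s)
  expect_false(identical(split_participants(paste0("p", 1:100), seed = 4),
                         s))
  # duplicated ids (multiple samples / windows) share one assignment
  s2 <- split_participants(rep(paste0("p", 1:20), each = 3), seed = 1)
  expect_equal(nrow(s2), 20L)
  expect_error(split_participants(c("a", "b")), "at least 3")
})

test_that("standardization reaches mean 0 / sd 1 and flags constant columns", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
  std <- standardize_features(m)
  expect_equal(unname(colMeans(std$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$x, 2, sd)), c(1, 1), tolerance = 1e-12)

  expect_warning(std2 <- standardize_features(cbind(k = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(unname(std2$x[, 1]), c(0, 0, 0))

  set.seed(5)
  big <- matrix(rnorm(600), 100, 6)
  colnames(big) <- paste0("c", 1:6)
  stdb <- standardize_features(big)
  expect_true(all(abs(colMeans(stdb$x)) < 1e-10))
  # parameters transfer to new rows
  new <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("c", 1:6)))
  tr <- apply_standardization(stdb, new)
  expect_equal(tr, sweep(sweep(new, 2, stdb$center), 2, stdb$scale, "/"))
})

test_that("penalties at or above the analytic lambda_max zero every coefficient", {
  d <- std_design(n = 150, p = 6, seed = 2, noise = 2)
  # rescale y so lambda_max falls inside the grid
  y <- d$y / max(abs(crossprod(d$x, d$y - mean(d$y))) / nrow(d$x)) * 0.4
  lam_max <- max(abs(crossprod(d$x, y - mean(y)))) / nrow(d$x)
  fit <- fit_lasso_cv(d$x, y, groups = seq_along(y), seed = 1)
  grid <- fit$penalty_grid
  for (l in grid[grid >= lam_max]) {
    b <- suppressWarnings(coef(fit$glmnet_fit, s = l, exact = TRUE,
                               x = d$x, y = y))
    expect_true(all(abs(as.numeric(b)[-1]) < 1e-10))
  }
  expect_true(any(fit$nonzero[grid < lam_max] > 0))
})

test_that("a vanishing penalty recovers the OLS solution", {
  d <- std_design(n = 400, p = 5, seed = 7, noise = 0.3)
  fit <- fit_lasso_cv(d$x, d$y, groups = seq_along(d$y), seed = 1)
  b_lasso <- suppressWarnings(coef(fit$glmnet_fit, s = 1e-4, exact = TRUE,
                                   x = d$x, y = d$y))
  b_ols <- coef(lm(d$y ~ d$x))
  rel <- abs(as.numeric(b_lasso)[-1] - b_ols[-1]) / abs(b_ols[-1])
  expect_true(all(rel < 0.05))
})

test_that("sparsity is monotone along the grid and ties pick the larger penalty", {
  d <- std_design(n = 120, p = 8, seed = 9, noise = 1)
  fit <- fit_lasso_cv(d$x, d$y, groups = seq_along(d$y), seed = 2)
  nz <- fit$nonzero # indexed by ascending penalty
  expect_true(all(diff(nz) <= 0))
  # the selected penalty attains the CV minimum; among ties, the largest
  best <- min(fit$cv_mse)
  tied <- fit$penalty_grid[fit$cv_mse <= best + 1e-12]
  expect_equal(fit$selected_penalty, max(tied))
  expect_error(fit_lasso_cv(d$x, d$y, groups = seq_along(d$y),
                            penalty_grid = numeric(0)), "empty")
})

test_that("rank AUROC matches the spec's conventions", {
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 0)), 1.0)
  expect_equal(auroc(c(5, 5, 5, 5), c(1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.2, 0.9), c(1, 0)), 0)
  expect_warning(a <- auroc(c(1, 2), c(1, 1)), "one class")
  expect_true(is.na(a))
})

test_that("rank AUROC equals brute-force pairwise enumeration with ties", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("evaluation reports AUROC at the > 13 rule and out-of-sample R2", {
  d <- std_design(n = 300, p = 4, seed = 13, noise = 0.5)
  y <- 10 + 4 * d$x[, 1] + rnorm(300, 0, 0.5)
  fit <- fit_lasso_cv(d$x, y, groups = seq_along(y), seed = 1)
  ev <- evaluate(fit, d$x, y)
  expect_gt(ev$auroc, 0.9)
  expect_gt(ev$r2, 0.8)
  expect_lte(ev$auroc, 1)
})

test_that("model specs validate window, variant and grid range", {
  expect_error(model_spec(window_days = 45), "30, 60|%in%")
  expect_error(model_spec(variant = "everything"), "variant")
  expect_error(model_spec(penalty_grid = c(0.5, 2)), "penalty_grid")
  s <- model_spec()
  expect_equal(s$split_fractions, c(0.70, 0.15, 0.15))
})
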