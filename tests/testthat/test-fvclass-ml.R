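separable_fm <- function(n_per_class = 40L, seed = 1L) {
  # class signal is constant within class (margin 10 SD of the noise
  # feature), so every estimator family can rank the classes perfectly
  with_seed(seed, data.frame(
    residue = as.character(seq_len(2L * n_per_class)),
    f1 = rep(c(0, 10), each = n_per_class),
    f2 = stats::rnorm(2L * n_per_class),
    label = rep(c(0L, 1L), each = n_per_class)))
}

test_that("published grid shapes are honoured in paper mode", {
  expect_length(hyper_grid("knn", "paper"), 48L)                # k = 3..50
  expect_length(hyper_grid("decision_tree", "paper"), 2L * 49L * 20L * 5L)
  expect_length(hyper_grid("random_forest", "paper"), 30L * 6L * 10L)
  expect_length(hyper_grid("gradient_boosted_trees", "paper"), 25L * 5L * 5L)
  svm_grid <- hyper_grid("svm", "paper")
  expect_length(svm_grid, 30L * 4L * 39L + 30L)  # polynomial cross + radial gammas
  expect_equal(range(vapply(hyper_grid("knn", "paper"), `[[`, 0, "k")), c(3, 50))
})

test_that("stratified folds preserve class ratios and reject oversized k", {
  y <- rep(c(0L, 1L), c(120L, 24L))
  folds <- stratified_folds(y, k = 6L, seed = 3L)
  for (f in 1:6) {
    expect_equal(sum(y[folds == f] == 1L), 4L)
    expect_equal(sum(y[folds == f] == 0L), 20L)
  }
  expect_error(stratified_folds(rep(c(0L, 1L), c(50L, 4L)), k = 10L), "k <= 4")
})

test_that("every estimator separates the 10-SD-margin fixture perfectly", {
  fm <- separable_fm()
  for (est in fvclass_estimators()) {
    r <- grid_search_cv(fm, est, preprocess_combo(),
                        grid = hyper_grid(est)[1:2], k = 5L, seed = 2L)
    expect_equal(r$auc_mean, 1.0, info = est)
  }
})

test_that("AUC agrees with the Mann-Whitney rank-formula oracle", {
  with_seed(9, {
    y <- rep(c(0L, 1L), c(60L, 30L))
    score <- stats::rnorm(90) + y
    expect_equal(fvrin:::roc_auc(y, score), oracle_auc(y, score), tolerance = 1e-12)
    # with ties
    score_t <- round(score)
    expect_equal(fvrin:::roc_auc(y, score_t), oracle_auc(y, score_t), tolerance = 1e-12)
  })
})

test_that("ADASYN reaches class parity deterministically and never touches labels 0", {
  with_seed(4, {
    x <- rbind(matrix(stats::rnorm(200), 100L), matrix(stats::rnorm(40, 3), 20L))
    y <- rep(c(0L, 1L), c(100L, 20L))
  })
  a1 <- adasyn(x, y, seed = 5L)
  a2 <- adasyn(x, y, seed = 5L)
  expect_equal(sum(a1$y == 1L), sum(a1$y == 0L))
  expect_identical(a1$x, a2$x)
  expect_equal(a1$x[1:120, ], x)  # originals untouched
})

test_that("ADASYN with a single minority point falls back to duplication", {
  x <- matrix(stats::rnorm(40), 20L)
  y <- c(rep(0L, 19L), 1L)
  expect_warning(a <- adasyn(x, y, seed = 2L), "duplication")
  expect_equal(sum(a$y == 1L), 19L)
})

test_that("validation folds are never oversampled", {
  fm <- with_seed(6, data.frame(
    residue = as.character(1:150),
    f1 = stats::rnorm(150), f2 = stats::rnorm(150),
    label = rep(c(0L, 1L), c(120L, 30L))))
  r <- grid_search_cv(fm, "decision_tree", preprocess_combo(use_oversampling = TRUE),
                      grid = hyper_grid("decision_tree")[1], k = 5L, seed = 7L)
  counts <- r$fold_val_class_counts
  # each validation fold keeps the full-data class ratio within one instance
  expect_true(all(counts[, "n1"] == 6L))
  expect_true(all(counts[, "n0"] == 24L))
})

test_that("pure-noise features give chance-level cross-validated AUC", {
  aucs <- vapply(1:4, function(seed) {
    fm <- with_seed(seed + 100, data.frame(
      residue = as.character(1:300),
      f1 = stats::rnorm(300), f2 = stats::rnorm(300), f3 = stats::rnorm(300),
      label = rep(c(0L, 1L), c(240L, 60L))))
    combo <- if (seed %% 2 == 0) preprocess_combo(use_oversampling = TRUE)
             else preprocess_combo()
    est <- c("knn", "decision_tree")[1 + seed %% 2]
    grid_search_cv(fm, est, combo, grid = hyper_grid(est)[1], k = 5L,
                   seed = seed)$auc_mean
  }, 0)
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("refitting with the same seed reproduces predictions exactly", {
  fm <- separable_fm(seed = 12L)
  sel <- lapply(fvclass_estimators(), function(est)
    grid_search_cv(fm, est, preprocess_combo(), grid = hyper_grid(est)[1],
                   k = 5L, seed = 3L))
  names(sel) <- fvclass_estimators()
  m1 <- train_final_models(fm, sel, seed = 4L)
  m2 <- train_final_models(fm, sel, seed = 4L)
  v1 <- ensemble_vote(m1, fm)
  v2 <- ensemble_vote(m2, fm)
  expect_identical(v1$vote, v2$vote)
})

test_that("the ensemble vote equals a manual count over the five models", {
  fm <- separable_fm(seed = 13L)
  sel <- lapply(fvclass_estimators(), function(est)
    grid_search_cv(fm, est, preprocess_combo(), grid = hyper_grid(est)[1],
                   k = 5L, seed = 5L))
  names(sel) <- fvclass_estimators()
  models <- train_final_models(fm, sel, seed = 6L)
  votes <- ensemble_vote(models, fm)
  per_model <- attr(votes, "per_model")
  expect_equal(votes$vote, as.integer(rowSums(per_model)))
  expect_true(all(votes$vote >= 0L & votes$vote <= 5L))
  # the separable fixture is classified consistently at the extremes
  expect_true(all(votes$vote[fm$label == 1L] >= 4L))
  expect_true(all(votes$vote[fm$label == 0L] <= 1L))
})

test_that("scoring refuses a table with a missing feature column", {
  fm <- separable_fm(seed = 14L)
  sel <- list(knn = grid_search_cv(fm, "knn", preprocess_combo(),
                                   grid = hyper_grid("knn")[1], k = 5L, seed = 1L))
  models <- train_final_models(fm, sel, seed = 1L)
  expect_error(ensemble_vote(models, fm[, c("residue", "f1")]), "f2")
})

test_that("degenerate zero-variance features are dropped with a warning", {
  fm <- separable_fm(seed = 15L)
  fm$f2 <- 1.0
  expect_warning(
    r <- grid_search_cv(fm, "knn", preprocess_combo(),
                        grid = hyper_grid("knn")[1], k = 5L, seed = 2L),
    "zero-variance")
  expect_equal(r$auc_mean, 1.0)
})

test_that("PCA preprocessing keeps the separable signal", {
  fm <- separable_fm(seed = 16L)
  r <- grid_search_cv(fm, "svm", preprocess_combo(use_pca = TRUE),
                      grid = hyper_grid("svm")[1], k = 5L, seed = 2L)
  expect_gt(r$auc_mean, 0.95)
})
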