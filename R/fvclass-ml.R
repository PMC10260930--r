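# Imbalance-aware mutation-risk classification.
#
# Five estimator families (decision tree, random forest, gradient-boosted
# trees, SVM, kNN) are tuned by grid search under 10-fold stratified
# cross-validation, scored by mean validation AUC from continuous scores.
# Four preprocessing combinations are considered: PCA or not, ADASYN
# oversampling to class parity or not; features are always standardized.
# All preprocessing is fit on training folds only and applied to
# validation folds; oversampling is never applied to validation folds.
# The final per-residue score is the number of the five tuned classifiers
# (0-5) that predict a substitution at that residue to be detrimental.

.estimators <- c("decision_tree", "random_forest", "gradient_boosted_trees",
                 "svm", "knn")

#' The five estimator names
#' @return character vector
#' @export
fvclass_estimators <- function() .estimators

#' Preprocessing combination
#'
#' @param use_pca project standardized features onto principal components
#' @param use_oversampling balance classes on training folds with ADASYN
#' @return list of class `fv_combo` (standardization is always on)
#' @export
preprocess_combo <- function(use_pca = FALSE, use_oversampling = FALSE) {
  structure(list(use_pca = use_pca, use_oversampling = use_oversampling,
                 standardize = TRUE),
            class = "fv_combo")
}

#' All four preprocessing combinations
#' @return named list of `fv_combo`
#' @export
all_combos <- function() {
  list(
    plain     = preprocess_combo(FALSE, FALSE),
    pca       = preprocess_combo(TRUE, FALSE),
    over      = preprocess_combo(FALSE, TRUE),
    pca_over  = preprocess_combo(TRUE, TRUE)
  )
}

#' Hyperparameter grid for an estimator
#'
#' `preset = "paper"` reproduces the published search ranges verbatim:
#' tree split criterion \{gini, entropy\}, minimum split size 2..50,
#' minimum leaf size 1..20, cost-complexity pruning \{1, 0.1, 0.01, 0.001,
#' 0.0001\}; forest size 50..1500 step 50, feature-subset size 2..7, leaf
#' minimum 1..10; boosting depth 1..25, L2 weight and learning rate
#' \{1, ..., 1e-4\}; SVM kernel \{polynomial, radial\}, gamma 0.01..1.5
#' step 0.05, polynomial degree 2..5 and independent term 0.1..2 step 0.05
#' (degree and independent term apply to the polynomial kernel only, so
#' radial rows are deduplicated to unique gamma values); kNN neighbor
#' count 3..50. `preset = "fast"` is a reduced grid with the identical
#' contract, the default for routine runs.
#'
#' @param estimator one of [fvclass_estimators()]
#' @param preset `"fast"` (default) or `"paper"`
#' @return list of named parameter lists, in deterministic order
#' @export
hyper_grid <- function(estimator = .estimators, preset = c("fast", "paper")) {
  estimator <- match.arg(estimator)
  preset <- match.arg(preset)
  g <- if (preset == "paper") {
    switch(estimator,
      decision_tree = expand.grid(
        split = c("gini", "information"), minsplit = 2:50, minbucket = 1:20,
        cp = c(1, 0.1, 0.01, 0.001, 0.0001),
        stringsAsFactors = FALSE),
      random_forest = expand.grid(
        num_trees = seq(50L, 1500L, 50L), mtry = 2:7, min_node = 1:10),
      gradient_boosted_trees = expand.grid(
        max_depth = 1:25, lambda = c(1, 0.1, 0.01, 0.001, 0.0001),
        eta = c(1, 0.1, 0.01, 0.001, 0.0001)),
      svm = {
        # polynomial fully crossed; radial keeps unique gammas (degree and
        # independent term apply to the polynomial kernel only)
        poly <- expand.grid(kernel = "polynomial", gamma = seq(0.01, 1.5, 0.05),
                            degree = 2:5, coef0 = seq(0.1, 2, 0.05),
                            stringsAsFactors = FALSE)
        rad <- data.frame(kernel = "radial", gamma = seq(0.01, 1.5, 0.05),
                          degree = 3L, coef0 = 0, stringsAsFactors = FALSE)
        rbind(poly, rad)
      },
      knn = data.frame(k = 3:50)
    )
  } else {
    switch(estimator,
      decision_tree = expand.grid(
        split = "gini", minsplit = c(2L, 20L), minbucket = c(1L, 5L),
        cp = c(0.01, 0.001), stringsAsFactors = FALSE),
      random_forest = expand.grid(
        num_trees = c(100L, 300L), mtry = c(2L, 4L), min_node = c(1L, 5L)),
      gradient_boosted_trees = expand.grid(
        max_depth = c(2L, 4L), lambda = c(1, 0.01), eta = c(0.1, 0.3)),
      svm = data.frame(
        kernel = c("radial", "radial", "radial", "polynomial"),
        gamma = c(0.01, 0.05, 0.1, 0.05),
        degree = c(3L, 3L, 3L, 3L), coef0 = c(0, 0, 0, 1),
        stringsAsFactors = FALSE),
      knn = data.frame(k = c(5L, 15L, 25L, 35L))
    )
  }
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Stratified fold assignment
#'
#' Shuffles indices within each class and deals them round-robin into `k`
#' folds, so every fold's class ratio matches the full data within one
#' instance.
#'
#' @param y binary labels
#' @param k folds
#' @param seed RNG seed
#' @return integer vector of fold ids in 1..k
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  minority <- min(table(y))
  if (k > minority) {
    stop(sprintf("k = %d exceeds the minority class count %d; use k <= %d",
                 k, minority, minority))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' ADASYN oversampling of the minority class
#'
#' Generates synthetic minority examples by interpolation towards minority
#' neighbours, allocating more synthesis to minority points whose
#' neighbourhood is majority-dominated (the hard-to-learn regions), until
#' class parity. If the minority class has no usable neighbours, falls
#' back to random duplication with a warning.
#'
#' @param x numeric feature matrix
#' @param y binary labels (0/1)
#' @param k_neighbors neighbourhood size (default 5)
#' @param seed RNG seed
#' @return list with augmented `x` and `y`
#' @export
adasyn <- function(x, y, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  counts <- table(factor(y, levels = c(0, 1)))
  min_cl <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  idx_min <- which(y == min_cl)
  n_syn <- abs(counts[["0"]] - counts[["1"]])
  if (n_syn == 0L) return(list(x = x, y = y))

  if (length(idx_min) < 2L) {
    warning("ADASYN infeasible (no minority neighbours); falling back to random duplication")
    dup <- with_seed(seed,
      idx_min[sample.int(length(idx_min), n_syn, replace = TRUE)])
    return(list(x = rbind(x, x[dup, , drop = FALSE]), y = c(y, y[dup])))
  }

  k_all <- min(k_neighbors, nrow(x) - 1L)
  d_all <- as.matrix(stats::dist(x))
  r <- vapply(idx_min, function(i) {
    nb <- order(d_all[i, -i])[seq_len(k_all)]
    nb <- seq_len(nrow(x))[-i][nb]
    sum(y[nb] != min_cl) / k_all
  }, 0)
  w <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)

  g <- floor(w * n_syn)
  rem <- n_syn - sum(g)
  if (rem > 0L) {
    extra <- order(-(w * n_syn - g))[seq_len(rem)]
    g[extra] <- g[extra] + 1L
  }

  k_min <- min(k_neighbors, length(idx_min) - 1L)
  syn <- with_seed(seed, {
    rows <- vector("list", length(idx_min))
    for (m in seq_along(idx_min)) {
      if (g[m] == 0L) next
      i <- idx_min[m]
      d_min <- d_all[i, idx_min]
      nb <- idx_min[order(d_min)[-1L][seq_len(k_min)]]
      pick <- sample(nb, g[m], replace = TRUE)
      lam <- stats::runif(g[m])
      rows[[m]] <- x[rep(i, g[m]), , drop = FALSE] +
        lam * (x[pick, , drop = FALSE] - x[rep(i, g[m]), , drop = FALSE])
    }
    do.call(rbind, rows)
  })
  list(x = rbind(x, syn), y = c(y, rep(min_cl, nrow(syn))))
}

# --- preprocessing ----------------------------------------------------------

# standardization + optional PCA, fit on training data only
preprocess_fit <- function(x, combo, pca_var = 0.95, pca_ncomp = NULL) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  keep <- sd_ > 0
  if (!all(keep)) {
    warning("zero-variance feature(s) dropped before standardization: ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  prep <- list(mu = mu[keep], sd = sd_[keep], keep = colnames(x)[keep],
               rotation = NULL)
  if (combo$use_pca) {
    xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, prep$mu), 2L, prep$sd, "/")
    pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    ncomp <- pca_ncomp %||%
      which(cumsum(pr$sdev^2) / sum(pr$sdev^2) >= pca_var)[1L]
    prep$rotation <- pr$rotation[, seq_len(ncomp), drop = FALSE]
  }
  prep
}

preprocess_apply <- function(prep, x) {
  x <- as.matrix(x)[, prep$keep, drop = FALSE]
  xs <- sweep(sweep(x, 2L, prep$mu), 2L, prep$sd, "/")
  if (!is.null(prep$rotation)) xs <- xs %*% prep$rotation
  xs
}

# --- estimator fitting ------------------------------------------------------

fit_estimator <- function(estimator, x, y, params, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(estimator,
    decision_tree = {
      df <- data.frame(.y = yf, x, check.names = FALSE)
      with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = params$split),
        control = rpart::rpart.control(minsplit = params$minsplit,
                                       minbucket = params$minbucket,
                                       cp = params$cp, xval = 0L)))
    },
    random_forest = ranger::ranger(
      x = x, y = yf, probability = TRUE,
      num.trees = params$num_trees,
      mtry = min(params$mtry, ncol(x)),
      min.node.size = params$min_node,
      seed = seed, num.threads = 1L, verbose = FALSE),
    gradient_boosted_trees = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, lambda = params$lambda,
                      eta = params$eta, nthread = 1L),
        data = dtr, nrounds = 100L, verbose = 0L))
    },
    svm = e1071::svm(
      x = x, y = yf, kernel = params$kernel, gamma = params$gamma,
      degree = params$degree %||% 3L, coef0 = params$coef0 %||% 0,
      scale = FALSE),
    knn = list(x = x, y = y, k = min(params$k, nrow(x) - 1L)),
    stop("unknown estimator: ", estimator)
  )
  structure(list(estimator = estimator, fit = fit, params = params,
                 seed = seed, feature_names = colnames(x)),
            class = "fv_fitted")
}

#' Continuous class-1 score of a fitted estimator
#'
#' Probability of the deficiency class for the probabilistic estimators,
#' the (oriented) decision value for the SVM — always "higher = more
#' likely deficient", suitable for AUC from continuous scores.
#'
#' @param object an `fv_fitted` model
#' @param newx feature matrix on the model's preprocessed scale
#' @return numeric score vector
#' @export
predict_score <- function(object, newx) {
  stopifnot(inherits(object, "fv_fitted"))
  newx <- as.matrix(newx)
  colnames(newx) <- object$feature_names
  switch(object$estimator,
    decision_tree = {
      df <- data.frame(newx, check.names = FALSE)
      unname(stats::predict(object$fit, df, type = "prob")[, "1"])
    },
    random_forest = unname(stats::predict(object$fit, data = newx,
                                          num.threads = 1L)$predictions[, "1"]),
    gradient_boosted_trees = unname(stats::predict(object$fit,
                                                   xgboost::xgb.DMatrix(newx))),
    svm = {
      pr <- stats::predict(object$fit, newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # libsvm orients decision values towards the first internal label
      if (startsWith(colnames(dv)[1L], "1")) dv[, 1L] else -dv[, 1L]
    },
    knn = {
      cl <- factor(object$fit$y, levels = c(0, 1))
      pred <- with_seed(object$seed,
        class::knn(object$fit$x, newx, cl, k = object$fit$k, prob = TRUE))
      p_win <- attr(pred, "prob")
      unname(ifelse(pred == "1", p_win, 1 - p_win))
    }
  )
}

#' Hard 0/1 class prediction of a fitted estimator
#'
#' The probabilistic estimators threshold their class-1 score at 0.5; the
#' SVM predicts by its decision boundary.
#'
#' @param object an `fv_fitted` model
#' @param newx feature matrix on the model's preprocessed scale
#' @return integer vector of 0/1 predictions
#' @export
predict_class <- function(object, newx) {
  stopifnot(inherits(object, "fv_fitted"))
  if (object$estimator == "svm") {
    newx <- as.matrix(newx)
    colnames(newx) <- object$feature_names
    as.integer(stats::predict(object$fit, newx) == "1")
  } else {
    as.integer(predict_score(object, newx) >= 0.5)
  }
}

# AUC from continuous scores; orientation fixed (never auto-flipped)
roc_auc <- function(y, score) {
  as.numeric(pROC::auc(response = factor(y, levels = c(0, 1)),
                       predictor = as.numeric(score),
                       levels = c("0", "1"), direction = "<", quiet = TRUE))
}

# --- cross-validated grid search --------------------------------------------

#' Grid search with stratified cross-validated AUC
#'
#' For one estimator and one preprocessing combination, evaluates every
#' grid point by k-fold stratified cross-validation and returns the point
#' maximizing mean validation AUC (ties resolved by grid order).
#' Standardization and PCA are fit on each training fold only; ADASYN, if
#' enabled, is applied to the training fold only, never to validation
#' folds.
#'
#' @param fm feature matrix (data.frame with the registry features and a
#'   `label` column; extra columns such as `residue` are ignored)
#' @param estimator one of [fvclass_estimators()]
#' @param combo an [preprocess_combo()] object
#' @param grid list of parameter lists, e.g. from [hyper_grid()]
#' @param k folds (default 10); must not exceed the minority class count
#' @param seed controls fold assignment, oversampling and stochastic
#'   estimators
#' @param pca_var,pca_ncomp PCA component selection: smallest count
#'   explaining `pca_var` of the variance, or an explicit override
#' @return object of class `fv_cv_result`: estimator, combo, best_params,
#'   auc_mean, auc_sd, fold_aucs, leaderboard of all grid points,
#'   fold validation class counts, seed
#' @export
grid_search_cv <- function(fm, estimator, combo = preprocess_combo(),
                           grid = hyper_grid(estimator), k = 10L, seed = 1L,
                           pca_var = 0.95, pca_ncomp = NULL) {
  stopifnot("label" %in% names(fm), length(grid) > 0L)
  feats <- intersect(feature_registry(), names(fm))
  if (length(feats) == 0L) feats <- setdiff(names(fm), c("residue", "label"))
  x <- as.matrix(fm[, feats, drop = FALSE])
  y <- fm$label
  if (length(unique(y)) < 2L) stop("both classes must be present")

  folds <- stratified_folds(y, k, seed)
  fold_data <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    prep <- preprocess_fit(x[tr, , drop = FALSE], combo, pca_var, pca_ncomp)
    x_tr <- preprocess_apply(prep, x[tr, , drop = FALSE])
    y_tr <- y[tr]
    if (combo$use_oversampling) {
      aug <- adasyn(x_tr, y_tr, seed = seed + 131L * f)
      x_tr <- aug$x; y_tr <- aug$y
    }
    list(x_tr = x_tr, y_tr = y_tr,
         x_va = preprocess_apply(prep, x[!tr, , drop = FALSE]), y_va = y[!tr])
  })

  eval_point <- function(params) {
    vapply(seq_len(k), function(f) {
      fd <- fold_data[[f]]
      fit <- fit_estimator(estimator, fd$x_tr, fd$y_tr, params, seed = seed + f)
      roc_auc(fd$y_va, predict_score(fit, fd$x_va))
    }, 0)
  }

  fold_aucs_all <- lapply(grid, eval_point)
  means <- vapply(fold_aucs_all, mean, 0)
  best <- which.max(means)

  leaderboard <- data.frame(
    point = vapply(grid, function(p) paste(names(p), unlist(p), sep = "=",
                                           collapse = ","), ""),
    auc_mean = means,
    auc_sd = vapply(fold_aucs_all, stats::sd, 0),
    stringsAsFactors = FALSE
  )
  val_counts <- t(vapply(seq_len(k), function(f)
    c(n0 = sum(fold_data[[f]]$y_va == 0), n1 = sum(fold_data[[f]]$y_va == 1)),
    c(n0 = 0, n1 = 0)))

  structure(
    list(estimator = estimator, combo = combo,
         best_params = grid[[best]],
         auc_mean = means[best],
         auc_sd = stats::sd(fold_aucs_all[[best]]),
         fold_aucs = fold_aucs_all[[best]],
         leaderboard = leaderboard,
         fold_val_class_counts = val_counts,
         k = as.integer(k), seed = as.integer(seed)),
    class = "fv_cv_result"
  )
}

#' @export
print.fv_cv_result <- function(x, ...) {
  cat(sprintf("CV result: %s (pca=%s, oversample=%s)  mean AUC %.3f (sd %.3f, %d folds)\n  best: %s\n",
              x$estimator, x$combo$use_pca, x$combo$use_oversampling,
              x$auc_mean, x$auc_sd, x$k,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cross-validated leaderboard over estimators and combinations
#'
#' Runs [grid_search_cv()] for every estimator x preprocessing
#' combination and tabulates the tuned mean validation AUCs.
#'
#' @param fm feature matrix with `label`
#' @param estimators subset of [fvclass_estimators()]
#' @param combos named list of combos (default all four)
#' @param preset grid preset passed to [hyper_grid()]
#' @param k,seed passed through
#' @return data.frame (estimator, combo, use_pca, use_oversampling,
#'   auc_mean, auc_sd, best_params); attribute `results` holds the full
#'   `fv_cv_result` objects keyed `estimator.combo`
#' @export
cv_leaderboard <- function(fm, estimators = fvclass_estimators(),
                           combos = all_combos(), preset = "fast",
                           k = 10L, seed = 1L) {
  results <- list()
  rows <- list()
  for (est in estimators) {
    grid <- hyper_grid(est, preset)
    for (cn in names(combos)) {
      r <- grid_search_cv(fm, est, combos[[cn]], grid = grid, k = k, seed = seed)
      results[[paste(est, cn, sep = ".")]] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, combo = cn,
        use_pca = combos[[cn]]$use_pca,
        use_oversampling = combos[[cn]]$use_oversampling,
        auc_mean = r$auc_mean, auc_sd = r$auc_sd,
        best_params = paste(names(r$best_params), unlist(r$best_params),
                            sep = "=", collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Best tuned configuration per estimator
#'
#' @param leaderboard output of [cv_leaderboard()]
#' @return named list of the winning `fv_cv_result` per estimator
#' @export
select_best <- function(leaderboard) {
  results <- attr(leaderboard, "results")
  stopifnot(!is.null(results))
  out <- list()
  for (est in unique(leaderboard$estimator)) {
    sub <- leaderboard[leaderboard$estimator == est, ]
    win <- sub$combo[which.max(sub$auc_mean)]
    out[[est]] <- results[[paste(est, win, sep = ".")]]
  }
  out
}

#' Fit the final model set from tuned selections
#'
#' Refits each selected estimator, with its selected preprocessing, on the
#' full feature matrix using its best hyperparameters.
#'
#' @param fm feature matrix with `label`
#' @param selections list of `fv_cv_result`, one per estimator
#'   (e.g. from [select_best()])
#' @param seed RNG seed for refitting (oversampling and stochastic fits)
#' @param pca_var,pca_ncomp PCA component selection
#' @return object of class `fv_model_set`
#' @export
train_final_models <- function(fm, selections, seed = 1L,
                               pca_var = 0.95, pca_ncomp = NULL) {
  feats <- intersect(feature_registry(), names(fm))
  if (length(feats) == 0L) feats <- setdiff(names(fm), c("residue", "label"))
  x <- as.matrix(fm[, feats, drop = FALSE])
  y <- fm$label
  models <- lapply(selections, function(sel) {
    stopifnot(inherits(sel, "fv_cv_result"))
    prep <- preprocess_fit(x, sel$combo, pca_var, pca_ncomp)
    x_p <- preprocess_apply(prep, x)
    y_p <- y
    if (sel$combo$use_oversampling) {
      aug <- adasyn(x_p, y_p, seed = seed + 977L)
      x_p <- aug$x; y_p <- aug$y
    }
    list(prep = prep,
         fit = fit_estimator(sel$estimator, x_p, y_p, sel$best_params,
                             seed = seed),
         combo = sel$combo)
  })
  structure(list(models = models, feature_names = feats, seed = as.integer(seed)),
            class = "fv_model_set")
}

#' Ensemble vote score per residue
#'
#' Counts, for each residue, how many of the trained classifiers predict a
#' substitution there to be detrimental (class 1). A score of 0 marks
#' residues deemed safe to substitute by every model; the maximum score
#' marks the residues most likely to impair function.
#'
#' @param models an `fv_model_set`
#' @param fm feature matrix (rows to score; `label` not required)
#' @return data.frame (residue, vote) with attribute `per_model`, the
#'   0/1 prediction matrix underlying the counts
#' @export
ensemble_vote <- function(models, fm) {
  stopifnot(inherits(models, "fv_model_set"))
  missing_cols <- setdiff(models$feature_names, names(fm))
  if (length(missing_cols) > 0L) {
    stop("feature column(s) missing from input: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(fm[, models$feature_names, drop = FALSE])
  per_model <- vapply(models$models, function(m) {
    predict_class(m$fit, preprocess_apply(m$prep, x))
  }, integer(nrow(x)))
  if (is.null(dim(per_model))) per_model <- matrix(per_model, nrow = 1L)
  vote <- as.integer(rowSums(per_model))
  out <- data.frame(
    residue = fm$residue %||% as.character(seq_len(nrow(x))),
    vote = vote, stringsAsFactors = FALSE
  )
  attr(out, "per_model") <- per_model
  out
}
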