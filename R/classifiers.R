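# Per-phenotype faller classifiers: four model families, fold-wise
# preprocessing, stratified 5-fold cross-validation with F1-optimized grid
# search, and confusion-matrix metrics.

model_families <- c("random_forest", "gradient_boosted_trees",
                    "decision_tree", "feedforward_nn")

#' Default hyperparameter grids per model family
#'
#' The search spaces for the four families, expressed in each backend's
#' parameter space: `randomForest` (trees, feature-subset strategy, leaf
#' size), `xgboost` (rounds, depth, learning rate, row/column subsampling),
#' `rpart` (split criterion, depth, split/leaf minima) and `nnet`
#' (single-hidden-layer size, L2 decay, iteration cap).
#'
#' @return Named list of data frames, one grid per family.
#' @seealso [compact_model_grids()] for the reduced grids the end-to-end
#'   pipeline uses by default.
#' @export
default_model_grids <- function() {
  list(
    random_forest = expand.grid(
      ntree = c(100, 200, 300), mtry_strategy = c("sqrt", "log2", "all"),
      nodesize = c(1, 2, 4), stringsAsFactors = FALSE),
    gradient_boosted_trees = expand.grid(
      nrounds = c(100, 200, 300), max_depth = c(3, 6, 9),
      eta = c(0.01, 0.1, 0.2), subsample = c(0.8, 0.9, 1.0),
      colsample_bytree = c(0.8, 0.9, 1.0)),
    decision_tree = expand.grid(
      criterion = c("gini", "information"), maxdepth = c(5, 10, 15, 20, 25, 30),
      minsplit = c(2, 5, 10, 15, 20), minbucket = c(1, 2, 4, 8, 10),
      stringsAsFactors = FALSE),
    feedforward_nn = expand.grid(
      size = c(50, 100, 150), decay = c(1e-4, 1e-3, 1e-2),
      maxit = c(500, 1000, 1500))
  )
}

#' Compact hyperparameter grids
#'
#' Small sub-grids of [default_model_grids()] (4-8 settings per family) used
#' by [run_pipeline()] and suited to per-phenotype samples of a few dozen
#' subjects, where most of the full grid is flat in validation F1.
#'
#' @return Named list of data frames.
#' @export
compact_model_grids <- function() {
  list(
    random_forest = expand.grid(
      ntree = 100, mtry_strategy = c("sqrt", "all"), nodesize = c(1, 4),
      stringsAsFactors = FALSE),
    gradient_boosted_trees = expand.grid(
      nrounds = 100, max_depth = c(3, 6), eta = c(0.1, 0.2),
      subsample = 0.9, colsample_bytree = 0.9),
    decision_tree = expand.grid(
      criterion = "gini", maxdepth = c(5, 30), minsplit = c(2, 10),
      minbucket = c(1, 4), stringsAsFactors = FALSE),
    feedforward_nn = expand.grid(
      size = c(10, 25), decay = c(1e-3, 1e-2), maxit = 300)
  )
}

#' Model specification
#'
#' @param family One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"decision_tree"`, `"feedforward_nn"`.
#' @param grid Hyperparameter grid (data frame); default the family's entry
#'   in [default_model_grids()].
#' @param folds Number of stratified CV folds (fixed at 5 by default).
#' @param seed Seed controlling fold assignment and stochastic fits. Share it
#'   across families so their metrics are computed on identical folds.
#' @return An object of class `model_spec`. Scoring is fixed to F1.
#' @export
model_spec <- function(family, grid = NULL, folds = 5L, seed = 1L) {
  family <- match.arg(family, model_families)
  grid <- grid %||% default_model_grids()[[family]]
  structure(list(family = family, grid = grid, folds = as.integer(folds),
                 scoring = "f1", seed = as.integer(seed)),
            class = "model_spec")
}

# ---- preprocessing ---------------------------------------------------------

# fold-wise preprocessing: parameters fitted on training rows only
preproc_fit <- function(X, family) {
  all_missing <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_missing) > 0) {
    stop("all-missing feature column(s): ", paste(all_missing, collapse = ", "))
  }
  # imputation comes first; scaling statistics are fitted on the imputed
  # (and, for the neural net, clipped) matrix, as in an impute -> scale pipeline
  if (family == "feedforward_nn") {
    imp <- apply(X, 2, median, na.rm = TRUE)
    Xi <- X
    for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- imp[j]
    q1 <- apply(Xi, 2, quantile, 0.25)
    q3 <- apply(Xi, 2, quantile, 0.75)
    iqr <- q3 - q1
    lo <- q1 - 1.5 * iqr; hi <- q3 + 1.5 * iqr
    Xc <- pmin(pmax(Xi, matrix(lo, nrow(Xi), ncol(Xi), byrow = TRUE)),
               matrix(hi, nrow(Xi), ncol(Xi), byrow = TRUE))
    ctr <- apply(Xc, 2, median)
    sc <- apply(Xc, 2, quantile, 0.75) - apply(Xc, 2, quantile, 0.25)
    list(family = family, impute = imp, lo = lo, hi = hi,
         center = ctr, scale = ifelse(sc > 0, sc, 1))
  } else {
    mu <- colMeans(X, na.rm = TRUE)
    Xi <- X
    for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- mu[j]
    sdev <- apply(Xi, 2, sd)
    list(family = family, impute = mu, center = mu,
         scale = ifelse(is.finite(sdev) & sdev > 0, sdev, 1))
  }
}

preproc_apply <- function(rec, X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- rec$impute[j]
  if (rec$family == "feedforward_nn") {
    lo <- matrix(rec$lo, nrow(X), ncol(X), byrow = TRUE)
    hi <- matrix(rec$hi, nrow(X), ncol(X), byrow = TRUE)
    X <- pmin(pmax(X, lo), hi)
  }
  sweep(sweep(X, 2, rec$center), 2, rec$scale, "/")
}

#' Build the classifier design matrix for one family
#'
#' Extracts the 25 gait/clinical features (fall label excluded), fits the
#' family's preprocessing on the full data and applies it: mean imputation
#' plus z-scoring for the tree families; median imputation, IQR clipping
#' (to `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`) and robust scaling (median/IQR) for
#' the neural net. During cross-validation the same transformations are
#' refitted on training folds only — use this function for final-model
#' inputs, not for fold evaluation.
#'
#' @param subjects Subject feature data frame.
#' @param family Model family name.
#' @param features Feature columns (default [gait_feature_names()]).
#' @return List with `X` (transformed matrix), `y` (0/1 fall labels, if
#'   present) and `record` (the fitted preprocessing parameters).
#' @export
prepare_features <- function(subjects, family = "random_forest",
                             features = gait_feature_names()) {
  family <- match.arg(family, model_families)
  missing_cols <- setdiff(features, names(subjects))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(subjects[, features])
  rec <- preproc_fit(X, family)
  list(X = preproc_apply(rec, X),
       y = if ("fell" %in% names(subjects)) as.integer(subjects$fell) else NULL,
       record = rec)
}

# ---- model backends --------------------------------------------------------

class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * as.numeric(tab))
  setNames(w, c("0", "1"))
}

fit_family <- function(family, X, y, params, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cw <- class_weights(y)
  yf <- factor(y, levels = c(0, 1))
  if (family == "random_forest") {
    mtry <- switch(params$mtry_strategy,
                   sqrt = max(floor(sqrt(ncol(X))), 1),
                   log2 = max(floor(log2(ncol(X))), 1),
                   all = ncol(X))
    fit <- randomForest::randomForest(
      x = X, y = yf, ntree = params$ntree, mtry = mtry,
      nodesize = params$nodesize, classwt = cw)
  } else if (family == "gradient_boosted_trees") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    scale_pos_weight = cw[["1"]] / cw[["0"]],
                    nthread = 1, seed = as.integer(seed)),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
  } else if (family == "decision_tree") {
    df <- data.frame(y = yf, X, check.names = FALSE)
    fit <- rpart::rpart(
      y ~ ., data = df, method = "class",
      weights = as.numeric(cw[as.character(y)]),
      parms = list(split = params$criterion),
      control = rpart::rpart.control(
        maxdepth = params$maxdepth, minsplit = params$minsplit,
        minbucket = params$minbucket, cp = 0,
        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0, xval = 0))
  } else if (family == "feedforward_nn") {
    fit <- nnet::nnet(X, as.numeric(y), size = params$size,
                      decay = params$decay, maxit = params$maxit,
                      weights = as.numeric(cw[as.character(y)]),
                      entropy = TRUE, MaxNWts = 20000, trace = FALSE)
  } else stop("unknown family: ", family)
  fit
}

# P(fall) for each row of X
predict_family <- function(fit, family, X) {
  if (family == "random_forest") {
    unname(predict(fit, X, type = "prob")[, "1"])
  } else if (family == "gradient_boosted_trees") {
    unname(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  } else if (family == "decision_tree") {
    unname(predict(fit, data.frame(X, check.names = FALSE), type = "prob")[, "1"])
  } else {
    unname(predict(fit, X)[, 1])
  }
}

# ---- cross-validation ------------------------------------------------------

stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision (positive predictive value), recall (sensitivity),
#' specificity and F1 from 2x2 counts with fallers as the positive class.
#' Ratios with a zero denominator are reported as `NA`, not coerced to 0.
#'
#' @param cm Named numeric with `tp`, `fp`, `fn`, `tn` (or a 2x2 matrix with
#'   predictions in rows, truth in columns, positive class first).
#' @return Named numeric of the five metrics.
#' @export
confusion_metrics <- function(cm) {
  if (is.matrix(cm)) {
    cm <- c(tp = cm[1, 1], fn = cm[2, 1], fp = cm[1, 2], tn = cm[2, 2])
  }
  if (any(cm < 0)) stop("confusion counts must be nonnegative")
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(accuracy = ratio(tp + tn, tp + fp + fn + tn),
    precision = precision, recall = recall,
    specificity = ratio(tn, tn + fp), f1 = f1)
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1), tn = sum(pred == 0 & truth == 0))
}

#' Grid search with stratified cross-validation
#'
#' Exhaustive search over the specification's grid under stratified k-fold
#' cross-validation with inverse-frequency class weights. Preprocessing is
#' fitted on each training fold and applied to its validation fold (no
#' leakage). The setting with the highest mean validation F1 wins and the
#' final model is refit on all data with it; per-fold confusion matrices of
#' the winning setting are retained and each metric summarized as mean with a
#' normal-approximation 95% CI across folds.
#'
#' @param X Raw (untransformed) feature matrix.
#' @param y 0/1 fall labels; both classes must be present.
#' @param spec A [model_spec()].
#' @return An object of class `model_result`: list with `family`,
#'   `best_params`, `metrics` (data frame of mean/lo/hi per metric),
#'   `fold_confusions`, `cv_f1` per grid row, the fitted `model`, its
#'   preprocessing `record`, and the fold assignment.
#' @export
tune_and_crossvalidate <- function(X, y, spec) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  k <- spec$folds
  if (min(table(y)) < k) {
    stop("stratification failure: the minority class has fewer members than folds")
  }
  fold <- stratified_folds(y, k, spec$seed)
  grid <- spec$grid
  fold_preds <- function(params) {
    lapply(seq_len(k), function(f) {
      tr <- fold != f; va <- fold == f
      rec <- preproc_fit(X[tr, , drop = FALSE], spec$family)
      fit <- fit_family(spec$family, preproc_apply(rec, X[tr, , drop = FALSE]),
                        y[tr], params, seed = spec$seed + f)
      p <- predict_family(fit, spec$family, preproc_apply(rec, X[va, , drop = FALSE]))
      confusion_counts(y[va], as.integer(p >= 0.5))
    })
  }
  cv_f1 <- numeric(nrow(grid))
  all_cms <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cms <- fold_preds(grid[g, , drop = FALSE])
    f1s <- vapply(cms, function(cm) confusion_metrics(cm)[["f1"]], 0)
    cv_f1[g] <- mean(f1s, na.rm = TRUE)
    all_cms[[g]] <- cms
  }
  best_g <- which.max(ifelse(is.nan(cv_f1), -Inf, cv_f1))
  best_params <- grid[best_g, , drop = FALSE]
  cms <- all_cms[[best_g]]
  per_fold <- t(vapply(cms, confusion_metrics, numeric(5)))
  summarize <- function(v) {
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    n_ok <- sum(!is.na(v))
    half <- if (n_ok > 1 && is.finite(s)) 1.96 * s / sqrt(n_ok) else 0
    c(mean = m, lo = max(m - half, 0), hi = min(m + half, 1))
  }
  metrics <- as.data.frame(t(apply(per_fold, 2, summarize)))
  metrics$metric <- rownames(metrics)
  rownames(metrics) <- NULL
  rec <- preproc_fit(X, spec$family)
  final_params <- best_params
  if (spec$family == "feedforward_nn") {
    final_params$maxit <- max(final_params$maxit * 2, 1000)  # generous cap on the refit
  }
  model <- fit_family(spec$family, preproc_apply(rec, X), y, final_params,
                      seed = spec$seed)
  structure(list(family = spec$family, best_params = best_params,
                 metrics = metrics[, c("metric", "mean", "lo", "hi")],
                 fold_confusions = cms, cv_f1 = cv_f1, grid = grid,
                 model = model, record = rec, fold = fold, y = y),
            class = "model_result")
}

#' Mean cross-validated accuracy of a fitted model result
#'
#' @param result A [tune_and_crossvalidate()] result.
#' @return Scalar mean CV accuracy (the Borda model weight).
#' @export
model_accuracy <- function(result) {
  result$metrics$mean[result$metrics$metric == "accuracy"]
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (5-fold CV)\n", x$family))
  for (i in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-11s %.2f (%.2f, %.2f)\n", x$metrics$metric[i],
                x$metrics$mean[i], x$metrics$lo[i], x$metrics$hi[i]))
  }
  invisible(x)
}
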