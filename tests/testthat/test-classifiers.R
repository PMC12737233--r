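# Feature preprocessing, confusion metrics, grid-search cross-validation.

test_that("tree-family preprocessing mean-imputes and z-scores", {
  subj <- data.frame(matrix(rnorm(8 * 25), 8, 25))
  names(subj) <- gait_feature_names()
  subj$cadence <- c(1, 2, NA, 3, 1, 2, 3, 2)
  pf <- prepare_features(subj, "random_forest")
  imputed <- c(1, 2, 2, 3, 1, 2, 3, 2)  # mean of observed = 2
  expect_equal(pf$X[, "cadence"], (imputed - mean(imputed)) / sd(imputed),
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(pf$X)), rep(0, 25), tolerance = 1e-12)
})

test_that("neural-net preprocessing clips by the IQR fence and robust-scales", {
  x <- c(0, 2, 4, 6, 8, 10, 1000)  # Q1 = 1, Q3 = 9 -> fence at 21
  subj <- data.frame(matrix(rnorm(7 * 25), 7, 25))
  names(subj) <- gait_feature_names()
  subj$tug_s <- x
  pf <- prepare_features(subj, "feedforward_nn")
  q <- quantile(x, c(0.25, 0.75))
  clipped <- pmin(pmax(x, q[1] - 1.5 * diff(q)), q[2] + 1.5 * diff(q))
  expect_equal(pf$X[, "tug_s"], (clipped - median(x)) / diff(q), ignore_attr = TRUE)
  # the worked fence: Q1 = 0, Q3 = 10 clips 1000 to 25
  x2 <- c(rep(0, 2), rep(10, 2), 1000)
  q2 <- quantile(x2, c(0.25, 0.75))
  expect_equal(unname(pmin(x2, q2[2] + 1.5 * diff(q2)))[5], 25)
  subj$tug_s <- NA_real_
  expect_error(prepare_features(subj, "random_forest"), "all-missing")
})

test_that("confusion metrics follow the standard definitions and NA rules", {
  perfect <- confusion_metrics(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(perfect == 1))
  none <- confusion_metrics(c(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(none[["recall"]], 0)
  expect_true(is.na(none[["precision"]]))
  expect_error(confusion_metrics(c(tp = -1, fp = 0, fn = 0, tn = 1)), "nonnegative")
  set.seed(41)
  for (i in 1:25) {
    cm <- c(tp = sample(0:9, 1), fp = sample(0:9, 1),
            fn = sample(0:9, 1), tn = sample(0:9, 1))
    m <- confusion_metrics(cm)
    expect_equal(m[["accuracy"]], (cm[["tp"]] + cm[["tn"]]) / sum(cm))
    if (!is.na(m[["f1"]])) {
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    }
  }
})

test_that("all families separate two distant blobs perfectly in CV", {
  fx <- make_blobs(n = 60, gap = 8, seed = 42)
  grids <- compact_model_grids()
  # deterministic single-point settings (no row/column subsampling noise)
  grids$gradient_boosted_trees <- data.frame(nrounds = 100, max_depth = 3,
                                             eta = 0.2, subsample = 1,
                                             colsample_bytree = 1)
  for (fam in c("random_forest", "gradient_boosted_trees",
                "decision_tree", "feedforward_nn")) {
    spec <- model_spec(fam, grid = grids[[fam]][1, , drop = FALSE],
                       seed = 5)
    res <- tune_and_crossvalidate(fx$X, fx$y, spec)
    expect_equal(res$metrics$mean[res$metrics$metric == "f1"], 1, info = fam)
  }
})

test_that("fold-wise preprocessing equals an independently coded CV oracle", {
  fx <- make_blobs(n = 50, gap = 2.5, seed = 43)
  grid <- data.frame(criterion = "gini", maxdepth = 5, minsplit = 5, minbucket = 2,
                     stringsAsFactors = FALSE)
  spec <- model_spec("decision_tree", grid = grid, seed = 9)
  res <- tune_and_crossvalidate(fx$X, fx$y, spec)
  fold <- phenogait:::stratified_folds(fx$y, 5, 9)
  expect_equal(fold, res$fold)
  cw <- phenogait:::class_weights(fx$y)
  oracle_cms <- lapply(1:5, function(f) {
    tr <- fold != f
    Xtr <- fx$X[tr, ]; Xva <- fx$X[!tr, , drop = FALSE]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, sd)
    zt <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    zv <- sweep(sweep(Xva, 2, mu), 2, sdv, "/")
    ytr <- fx$y[tr]
    cwtr <- phenogait:::class_weights(ytr)
    fit <- rpart::rpart(y ~ ., data = data.frame(y = factor(ytr, levels = 0:1), zt),
                        method = "class", weights = as.numeric(cwtr[as.character(ytr)]),
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(maxdepth = 5, minsplit = 5,
                                                       minbucket = 2, cp = 0,
                                                       maxcompete = 0, maxsurrogate = 0,
                                                       usesurrogate = 0, xval = 0))
    p <- predict(fit, data.frame(zv), type = "prob")[, "1"]
    phenogait:::confusion_counts(fx$y[!tr], as.integer(p >= 0.5))
  })
  expect_equal(res$fold_confusions, oracle_cms)
})

test_that("class weighting does not hurt minority recall on imbalanced data", {
  wins <- 0
  for (seed in 1:5) {
    fx <- make_blobs(n = 100, gap = 1, seed = seed, prop_pos = 0.2)
    split <- seq_len(100) %% 2 == 0
    Xtr <- fx$X[split, ]; ytr <- fx$y[split]
    Xte <- fx$X[!split, ]; yte <- fx$y[!split]
    cw <- phenogait:::class_weights(ytr)
    df <- data.frame(y = factor(ytr, levels = 0:1), Xtr)
    fit_w <- rpart::rpart(y ~ ., df, method = "class",
                          weights = as.numeric(cw[as.character(ytr)]))
    fit_u <- rpart::rpart(y ~ ., df, method = "class")
    rec <- function(fit) {
      p <- predict(fit, data.frame(Xte), type = "class")
      sum(p == "1" & yte == 1) / sum(yte == 1)
    }
    if (rec(fit_w) >= rec(fit_u)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("shuffled labels give chance-level CV F1", {
  set.seed(44)
  f1s <- numeric(10)
  grid <- data.frame(criterion = "gini", maxdepth = 5, minsplit = 10, minbucket = 4,
                     stringsAsFactors = FALSE)
  for (r in 1:10) {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- sample(rep(0:1, each = 30))
    res <- tune_and_crossvalidate(X, y, model_spec("decision_tree", grid = grid,
                                                   seed = r))
    f1s[r] <- res$metrics$mean[res$metrics$metric == "f1"]
  }
  # balanced null: F1 at the prevalence-implied chance level (~0.5)
  expect_lt(abs(mean(f1s, na.rm = TRUE) - 0.5), 0.12)
})

test_that("degenerate inputs are rejected with clear messages", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(tune_and_crossvalidate(X, rep(0, 20), model_spec("decision_tree")),
               "both classes")
  expect_error(tune_and_crossvalidate(X, c(1, rep(0, 19)),
                                      model_spec("decision_tree")),
               "stratification")
})
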