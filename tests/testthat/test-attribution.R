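# Attributions (exact tree-Shapley, sampling Shapley), tie-averaged ranks and
# the weighted Borda consensus.

fit_result_stub <- function(model, family, X) {
  # minimal model_result for attribution tests
  structure(list(family = family, model = model,
                 record = phenogait:::preproc_fit(X, family)),
            class = "model_result")
}

test_that("a stump concentrates all attribution on its split feature", {
  set.seed(51)
  n <- 80
  subj <- data.frame(matrix(rnorm(n * 25), n, 25))
  names(subj) <- gait_feature_names()
  y <- as.integer(subj$tug_s > 0)
  df <- data.frame(y = factor(y, levels = 0:1), as.matrix(subj))
  stump <- rpart::rpart(y ~ ., df, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                       maxcompete = 0,
                                                       maxsurrogate = 0, xval = 0))
  res <- fit_result_stub(stump, "decision_tree", as.matrix(subj))
  res$record <- list(family = "decision_tree",
                     impute = rep(0, 25), center = rep(0, 25), scale = rep(1, 25))
  att <- positive_class_attributions(res, subj, seed = 1)
  nz <- colSums(abs(att$values)) > 1e-12
  expect_equal(names(which(nz)), "tug_s")
})

test_that("a constant model attributes nothing", {
  set.seed(52)
  subj <- data.frame(matrix(rnorm(40 * 25), 40, 25))
  names(subj) <- gait_feature_names()
  y <- rep(1L, 40)
  df <- data.frame(y = factor(y, levels = 0:1), as.matrix(subj))
  fit <- rpart::rpart(y ~ ., df, method = "class")  # no split possible
  res <- fit_result_stub(fit, "decision_tree", as.matrix(subj))
  att <- positive_class_attributions(res, subj, seed = 1)
  expect_true(all(abs(att$values) < 1e-12))
  expect_equal(att$base, 1)
})

test_that("tree-Shapley equals exhaustive coalition enumeration on a small tree", {
  set.seed(53)
  n <- 120; d <- 3
  X <- matrix(rbinom(n * d, 1, 0.5), n, d)
  colnames(X) <- paste0("f", 1:d)
  y <- as.integer(xor(X[, 1] == 1, X[, 2] == 1))  # depth-2 structure
  df <- data.frame(y = factor(y, levels = 0:1), X)
  fit <- rpart::rpart(y ~ ., df, method = "class",
                      control = rpart::rpart.control(maxdepth = 2, cp = 0,
                                                     minsplit = 2, minbucket = 1,
                                                     maxcompete = 0, maxsurrogate = 0,
                                                     xval = 0))
  leaves <- phenogait:::tree_leaf_paths(phenogait:::rpart_tree_nodes(fit, colnames(X)))
  Z <- X[1:20, , drop = FALSE]
  Xq <- X[21:30, , drop = FALSE]
  got <- phenogait:::tree_shapley(leaves, Xq, Z)
  predict_fn <- function(M) predict(fit, data.frame(M), type = "prob")[, "1"]
  for (i in seq_len(nrow(Xq))) {
    oracle <- shapley_enum_oracle(predict_fn, Xq[i, ], Z, d)
    expect_equal(unname(got$phi[i, ]), oracle, tolerance = 1e-10)
  }
  # local accuracy: base + contributions = model output
  expect_equal(got$base + rowSums(got$phi), unname(predict_fn(Xq)),
               tolerance = 1e-10)
})

test_that("random-forest Shapley satisfies local accuracy exactly", {
  set.seed(54)
  subj <- data.frame(matrix(rnorm(50 * 25), 50, 25))
  names(subj) <- gait_feature_names()
  subj$fell <- as.integer(subj$sppb + subj$cadence > 0)
  spec <- model_spec("random_forest",
                     grid = data.frame(ntree = 30, mtry_strategy = "sqrt",
                                       nodesize = 2, stringsAsFactors = FALSE),
                     seed = 2)
  res <- tune_and_crossvalidate(as.matrix(subj[, gait_feature_names()]),
                                subj$fell, spec)
  att <- positive_class_attributions(res, subj, seed = 3)
  Xp <- phenogait:::preproc_apply(res$record, as.matrix(subj[, gait_feature_names()]))
  fx <- phenogait:::predict_family(res$model, "random_forest", Xp)
  expect_equal(att$base + rowSums(att$values), fx, tolerance = 1e-10)
})

test_that("sampling Shapley for the neural net telescopes to local accuracy", {
  set.seed(55)
  subj <- data.frame(matrix(rnorm(40 * 25), 40, 25))
  names(subj) <- gait_feature_names()
  subj$fell <- as.integer(subj$tug_s > 0)
  spec <- model_spec("feedforward_nn",
                     grid = data.frame(size = 5, decay = 1e-2, maxit = 100),
                     seed = 2)
  res <- tune_and_crossvalidate(as.matrix(subj[, gait_feature_names()]),
                                subj$fell, spec)
  att <- positive_class_attributions(res, subj, n_perm = 8, seed = 3)
  Xp <- phenogait:::preproc_apply(res$record, as.matrix(subj[, gait_feature_names()]))
  fx <- phenogait:::predict_family(res$model, "feedforward_nn", Xp)
  expect_equal(att$base + rowSums(att$values), fx, tolerance = 1e-8)
})

test_that("boosted-tree attributions satisfy local accuracy on the margin scale", {
  set.seed(56)
  subj <- data.frame(matrix(rnorm(50 * 25), 50, 25))
  names(subj) <- gait_feature_names()
  subj$fell <- as.integer(subj$stride_length > 0)
  spec <- model_spec("gradient_boosted_trees",
                     grid = compact_model_grids()$gradient_boosted_trees[1, ],
                     seed = 2)
  res <- tune_and_crossvalidate(as.matrix(subj[, gait_feature_names()]),
                                subj$fell, spec)
  att <- positive_class_attributions(res, subj, seed = 3)
  Xp <- phenogait:::preproc_apply(res$record, as.matrix(subj[, gait_feature_names()]))
  margin <- predict(res$model, xgboost::xgb.DMatrix(Xp, nthread = 1),
                    outputmargin = TRUE)
  expect_equal(att$base + rowSums(att$values), unname(margin), tolerance = 1e-5)
})

test_that("tie-averaged descending ranks match the definition", {
  expect_equal(rank_with_ties(c(0.5, 0.3, 0.3, 0.1)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_with_ties(rep(2, 5)), rep(3, 5))
  expect_error(rank_with_ties(c(0.1, -0.2)), "nonnegative")
  set.seed(57)
  for (i in 1:20) {
    v <- round(runif(10), 1)
    r <- rank_with_ties(v)
    # sort-and-average oracle
    ord <- order(-v)
    oracle <- numeric(10)
    pos <- 1
    while (pos <= 10) {
      run <- which(v == v[ord[pos]])
      oracle[run] <- mean(which(v[ord] == v[ord[pos]]))
      pos <- pos + length(run)
    }
    expect_equal(r, oracle)
    expect_equal(sum(r), 55)  # tie-averaged permutation mass
  }
})

test_that("weighted Borda scores follow the formula and its invariances", {
  # single model
  expect_equal(weighted_borda(matrix(1, 1, 1, dimnames = list("f", NULL)), 1)$score, 1)
  R <- matrix(c(1, 3, 5, 2, 4, 2, 1, 5, 3, 4), 5, 2,
              dimnames = list(paste0("f", 1:5), c("m1", "m2")))
  out <- weighted_borda(R, c(1, 1))
  brute <- rowSums((5 - R + 1) %*% diag(2))
  expect_equal(out$score[match(rownames(R), out$feature)], unname(brute))

  set.seed(58)
  for (i in 1:10) {
    Rr <- vapply(1:3, function(j) rank_with_ties(runif(8)), numeric(8))
    rownames(Rr) <- paste0("f", 1:8)
    w <- runif(3)
    out <- weighted_borda(Rr, w)
    brute <- as.numeric((8 - Rr + 1) %*% w)
    expect_equal(out$score, sort(brute, decreasing = TRUE))
    # scale equivariance
    out2 <- weighted_borda(Rr, 3 * w)
    expect_equal(out2$score, 3 * out$score)
    expect_equal(out2$feature, out$feature)
    # rank reversal antisymmetry: per-feature scores mirror around (n+1) sum(w),
    # so the consensus ordering is exactly reversed
    rev_out <- weighted_borda(9 - Rr, w)
    s_fwd <- out$score[match(rownames(Rr), out$feature)]
    s_rev <- rev_out$score[match(rownames(Rr), rev_out$feature)]
    expect_equal(s_fwd + s_rev, rep(9 * sum(w), 8))
  }
  # unanimous top feature attains n * sum(w)
  Ru <- rbind(f1 = c(1, 1), f2 = c(2, 2), f3 = c(3, 3))
  expect_equal(weighted_borda(Ru, c(0.5, 0.25))$score[1], 3 * 0.75)
  expect_error(weighted_borda(Ru, 1), "one weight per model")
  expect_error(weighted_borda(rbind(c(0.5, 1)), 1:2), "ranks must lie")
})
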