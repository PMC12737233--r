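# Per-model feature attributions toward the fall class, tie-averaged ranks,
# and accuracy-weighted Borda consensus.

# ---- tree structure extraction --------------------------------------------
# Common node-table format: per tree a list of root-to-leaf paths ("leaves"),
# each with the edge conditions (feature index, threshold, strict flag,
# go-left flag) and the leaf value.

tree_leaf_paths <- function(nodes) {
  # nodes: data.frame with left, right (row index or NA), var, point, strict,
  # go_left_on_true (condition true sends LEFT), value
  leaves <- list()
  walk <- function(i, vars, pts, strict, pass_left) {
    nd <- nodes[i, ]
    if (is.na(nd$left)) {
      leaves[[length(leaves) + 1]] <<- list(
        vars = vars, pts = pts, strict = strict, pass_left = pass_left,
        value = nd$value)
      return(invisible())
    }
    walk(nd$left, c(vars, nd$var), c(pts, nd$point), c(strict, nd$strict),
         c(pass_left, TRUE))
    walk(nd$right, c(vars, nd$var), c(pts, nd$point), c(strict, nd$strict),
         c(pass_left, FALSE))
  }
  walk(1L, integer(), numeric(), logical(), logical())
  leaves
}

# edge pass indicator for a value matrix V (rows x features): does each row's
# value satisfy this leaf's edge conditions?
leaf_edge_pass <- function(leaf, V) {
  ne <- length(leaf$vars)
  out <- matrix(FALSE, nrow(V), ne)
  for (e in seq_len(ne)) {
    v <- V[, leaf$vars[e]]
    left <- if (leaf$strict[e]) v < leaf$pts[e] else v <= leaf$pts[e]
    out[, e] <- if (leaf$pass_left[e]) left else !left
  }
  out
}

# per-feature aggregation: a feature passes iff all its edges pass
leaf_feature_pass <- function(leaf, edge_pass) {
  u <- unique(leaf$vars)
  ok <- matrix(TRUE, nrow(edge_pass), length(u))
  for (j in seq_along(u)) {
    cols <- which(leaf$vars == u[j])
    ok[, j] <- rowSums(edge_pass[, cols, drop = FALSE]) == length(cols)
  }
  list(u = u, ok = ok)
}

rf_tree_nodes <- function(fit, k) {
  tr <- randomForest::getTree(fit, k, labelVar = FALSE)
  data.frame(
    left = ifelse(tr[, "left daughter"] == 0, NA, tr[, "left daughter"]),
    right = ifelse(tr[, "right daughter"] == 0, NA, tr[, "right daughter"]),
    var = tr[, "split var"],
    point = tr[, "split point"],
    strict = FALSE,           # randomForest: x <= point goes left
    value = ifelse(tr[, "status"] == -1, tr[, "prediction"] - 1, NA)
  )
}

rpart_tree_nodes <- function(fit, feature_names) {
  fr <- fit$frame
  nums <- as.integer(row.names(fr))
  is_leaf <- fr$var == "<leaf>"
  # with maxcompete = maxsurrogate = 0, splits rows align with non-leaf
  # frame rows in order
  sp <- fit$splits
  split_row <- cumsum(!is_leaf)
  nodes <- data.frame(left = NA_integer_, right = NA_integer_,
                      var = NA_integer_, point = NA_real_,
                      strict = FALSE, value = NA_real_)[rep(1, nrow(fr)), ]
  rownames(nodes) <- NULL
  nclass <- (ncol(fr$yval2) - 2) / 2
  for (i in seq_len(nrow(fr))) {
    if (is_leaf[i]) {
      nodes$value[i] <- fr$yval2[i, 1 + nclass + 2]  # P(second class = faller)
    } else {
      nodes$left[i] <- match(2L * nums[i], nums)
      nodes$right[i] <- match(2L * nums[i] + 1L, nums)
      r <- split_row[i]
      nodes$var[i] <- match(rownames(sp)[r], feature_names)
      nodes$point[i] <- sp[r, "index"]
      ncat <- sp[r, "ncat"]
      if (ncat < 0) {
        nodes$strict[i] <- TRUE          # x < point goes left
      } else {
        # reversed continuous split: x >= point goes left
        nodes$strict[i] <- TRUE
        nodes[i, c("left", "right")] <- nodes[i, c("right", "left")]
      }
    }
  }
  nodes
}

# ---- exact interventional Shapley values on trees -------------------------

# For one tree, each leaf's reachability under a coalition S (features in S
# read from the foreground x, the rest from a background row z) is a
# unanimity-style game: the leaf is reached iff A subset of S and B disjoint
# from S, where A are features only x passes and B features only z passes.
# Its Shapley values are closed-form, so the exact attribution is a sum over
# leaves, averaged over the background set.
tree_shapley <- function(leaves, X, Z) {
  n <- nrow(X); d <- ncol(X); B <- nrow(Z)
  phi <- matrix(0, n, d)
  base <- 0
  maxf <- max(vapply(leaves, function(l) length(unique(l$vars)), 0L)) + 1L
  lf <- lgamma(seq_len(maxf + 1))  # lf[k+1] = log(k!)
  for (leaf in leaves) {
    ep_x <- leaf_edge_pass(leaf, X)
    ep_z <- leaf_edge_pass(leaf, Z)
    fx <- leaf_feature_pass(leaf, ep_x)
    fz <- leaf_feature_pass(leaf, ep_z)
    u <- fx$u
    nu <- length(u)
    v <- leaf$value
    for (i in seq_len(n)) {
      xok <- fx$ok[i, ]
      Xok <- matrix(xok, B, nu, byrow = TRUE)
      Am <- Xok & !fz$ok
      Bm <- !Xok & fz$ok
      dead <- rowSums(!Xok & !fz$ok) > 0
      a <- rowSums(Am); b <- rowSums(Bm)
      live <- !dead
      coefA <- ifelse(live & a > 0,
                      exp(lf[pmax(a, 1)] + lf[b + 1] - lf[a + b + 1]), 0)
      coefB <- ifelse(live & b > 0,
                      exp(lf[a + 1] + lf[pmax(b, 1)] - lf[a + b + 1]), 0)
      if (any(coefA > 0)) {
        inc <- colSums(Am * coefA)
        phi[i, u] <- phi[i, u] + v * inc / B
      }
      if (any(coefB > 0)) {
        dec <- colSums(Bm * coefB)
        phi[i, u] <- phi[i, u] - v * dec / B
      }
    }
    # base value: leaves the background rows reach
    z_reach <- rowSums(fz$ok) == nu
    base <- base + v * sum(z_reach) / B
  }
  list(phi = phi, base = base)
}

# ---- permutation-sampling Shapley (model-agnostic) ------------------------

sampling_shapley <- function(predict_fn, X, Z, n_perm = 32L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(X); d <- ncol(X); B <- nrow(Z)
  phi <- matrix(0, n, d)
  # rows: for each foreground x, B background copies
  Zrep <- Z[rep(seq_len(B), times = n), , drop = FALSE]
  xrow <- rep(seq_len(n), each = B)
  group_means <- function(p) {
    as.numeric(tapply(p, xrow, mean))
  }
  for (s in seq_len(n_perm)) {
    perm <- sample.int(d)
    M <- Zrep
    prev <- group_means(predict_fn(M))
    for (j in perm) {
      M[, j] <- X[xrow, j]
      cur <- group_means(predict_fn(M))
      phi[, j] <- phi[, j] + (cur - prev)
      prev <- cur
    }
  }
  list(phi = phi / n_perm, base = mean(predict_fn(Z)))
}

# ---- public attribution surface -------------------------------------------

#' Positive-class feature attributions for a fitted faller model
#'
#' Additive per-subject, per-feature attributions toward the fall (positive)
#' class, with global importance as the mean absolute attribution per
#' feature. Tree families use exact methods: the boosted model its built-in
#' TreeSHAP decomposition (log-odds scale), random forest and decision tree
#' an exact interventional tree-Shapley with a fixed background subset
#' (probability scale). The neural net uses permutation-sampling Shapley
#' values against the same background (probability scale). In every case the
#' attributions satisfy local accuracy: base value + row sum = the model's
#' positive-class output for that subject (exactly for the closed-form
#' methods; the sampling method is exact in the same sense by telescoping).
#'
#' @param result A [tune_and_crossvalidate()] result (fitted model).
#' @param subjects Subject feature data frame the model was trained on.
#' @param features Feature columns (default [gait_feature_names()]).
#' @param background_n Background subset size (default 25 rows).
#' @param n_perm Permutations for the sampling method (neural net only).
#' @param seed Seed for the background draw and permutation sampling.
#' @return An object of class `attribution_matrix`: list with `values`
#'   (subjects x features), `base`, `global_importance` (named, mean
#'   absolute attribution) and `family`.
#' @export
positive_class_attributions <- function(result, subjects,
                                        features = gait_feature_names(),
                                        background_n = 25L, n_perm = 32L,
                                        seed = 1L) {
  if (!inherits(result, "model_result")) stop("`result` must be a fitted model_result")
  Xraw <- as.matrix(subjects[, features])
  X <- preproc_apply(result$record, Xraw)
  colnames(X) <- features
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bg_idx <- sample.int(nrow(X), min(background_n, nrow(X)))
  Z <- X[bg_idx, , drop = FALSE]
  family <- result$family
  if (family == "gradient_boosted_trees") {
    contrib <- predict(result$model, xgboost::xgb.DMatrix(X, nthread = 1),
                       predcontrib = TRUE)
    phi <- contrib[, seq_along(features), drop = FALSE]
    base <- unname(contrib[1, ncol(contrib)])
  } else if (family == "random_forest") {
    ntree <- result$model$ntree
    leaves <- unlist(lapply(seq_len(ntree), function(k) {
      tree_leaf_paths(rf_tree_nodes(result$model, k))
    }), recursive = FALSE)
    out <- tree_shapley(leaves, X, Z)
    phi <- out$phi / ntree
    base <- out$base / ntree
  } else if (family == "decision_tree") {
    leaves <- tree_leaf_paths(rpart_tree_nodes(result$model, features))
    out <- tree_shapley(leaves, X, Z)
    phi <- out$phi
    base <- out$base
  } else if (family == "feedforward_nn") {
    pf <- function(M) predict_family(result$model, family, M)
    out <- sampling_shapley(pf, X, Z, n_perm = n_perm, seed = seed)
    phi <- out$phi
    base <- out$base
  } else stop("unknown family: ", family)
  colnames(phi) <- features
  structure(list(values = phi, base = base,
                 global_importance = colMeans(abs(phi)),
                 family = family),
            class = "attribution_matrix")
}

#' Descending ranks with average ties
#'
#' Rank 1 is the most important feature; equal importances share the average
#' of the positions they span (half-integer ranks possible).
#'
#' @param importances Nonnegative per-feature importance values.
#' @return Numeric rank vector (names preserved).
#' @export
rank_with_ties <- function(importances) {
  if (length(importances) < 1) stop("need at least one importance")
  if (any(importances < 0)) stop("importances must be nonnegative")
  rank(-importances, ties.method = "average")
}

#' Accuracy-weighted Borda consensus over model rankings
#'
#' Each model's rank `r_ij` becomes a Borda point `s_ij = n - r_ij + 1`
#' (`n` features); the overall score is `S_i = sum_j w_j s_ij` with model
#' weights `w_j` (the models' mean CV accuracies, unnormalized). Features are
#' ordered by descending score, ties broken by the first model's rank.
#'
#' @param R Numeric matrix of ranks, features in rows, models in columns;
#'   half-integer (tie-averaged) ranks allowed.
#' @param w Nonnegative model weights, one per column.
#' @return An object of class `borda_result`: data frame of features (row
#'   names of `R`), per-model ranks, `score`, and (when `n = 25`) a
#'   `strong_consensus` flag for scores above 60, sorted by descending score.
#' @export
weighted_borda <- function(R, w) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (length(w) != ncol(R)) stop("one weight per model is required")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(R < 1 | R > n)) stop("ranks must lie in [1, n]")
  s <- n - R + 1
  score <- as.numeric(s %*% w)
  out <- data.frame(feature = rownames(R) %||% paste0("feature_", seq_len(n)),
                    R, score = score, check.names = FALSE)
  if (n == 25) out$strong_consensus <- score > 60
  out <- out[order(-score, R[, 1]), ]
  rownames(out) <- NULL
  structure(out, class = c("borda_result", "data.frame"))
}

#' Fit all four families and build the Borda consensus for one phenotype
#'
#' @param subjects Subject data frame of one phenotype (with `fell`).
#' @param grids Named list of hyperparameter grids (default
#'   [compact_model_grids()]).
#' @param seed Shared seed (fold assignment is identical across families).
#' @param features Feature columns.
#' @param n_perm,background_n Attribution controls (see
#'   [positive_class_attributions()]).
#' @return List with `models` (per-family results), `attributions`,
#'   `weights` (mean CV accuracies) and `borda` (a [weighted_borda()]
#'   result).
#' @export
phenotype_consensus <- function(subjects, grids = compact_model_grids(),
                                seed = 1L, features = gait_feature_names(),
                                n_perm = 32L, background_n = 25L) {
  X <- as.matrix(subjects[, features])
  y <- as.integer(subjects$fell)
  models <- list()
  attributions <- list()
  for (family in model_families) {
    spec <- model_spec(family, grid = grids[[family]], seed = seed)
    models[[family]] <- tune_and_crossvalidate(X, y, spec)
    attributions[[family]] <- positive_class_attributions(
      models[[family]], subjects, features = features,
      background_n = background_n, n_perm = n_perm,
      seed = child_seed(seed, family))
  }
  R <- vapply(attributions, function(a) rank_with_ties(a$global_importance),
              numeric(length(features)))
  rownames(R) <- features
  w <- vapply(models, model_accuracy, 0)
  list(models = models, attributions = attributions, weights = w,
       borda = weighted_borda(R, w))
}
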