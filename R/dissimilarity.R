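# Channel reduction, multivariate DTW dissimilarity, and MDS embedding.

#' Reducer configuration
#'
#' @param method `"pca"` (the supported reducer: a linear projection of the 3
#'   channels fitted on the pooled sample matrix) or `"tsne"`, accepted for
#'   interface compatibility but not available in this build (a t-SNE map of
#'   whole subjects is not a time series, so dynamic time warping over it is
#'   undefined; no t-SNE backend is bundled).
#' @param variance_target Cumulative explained-variance proportion that fixes
#'   the number of retained components (default 0.80).
#' @param random_seed Seed for stochastic reducers.
#' @return An object of class `reducer_config`.
#' @export
reducer_config <- function(method = c("pca", "tsne"), variance_target = 0.80,
                           random_seed = 1L) {
  method <- match.arg(method)
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must lie in (0, 1]")
  }
  structure(list(method = method, variance_target = variance_target,
                 random_seed = as.integer(random_seed)),
            class = "reducer_config")
}

#' Reduce the three IMU channels to principal-component channels
#'
#' Fits one linear projection across the three channels on the pooled
#' `(subjects x L, 3)` sample matrix, retains the smallest number of
#' components `m` whose cumulative explained variance reaches the target, and
#' projects every subject's curve onto them. Each subject thus keeps a
#' length-`L` time series with `m` channels, on which multivariate DTW is
#' well defined.
#'
#' @param curves Named list of `representative_gait` objects (or bare
#'   `L x 3` matrices).
#' @param config A [reducer_config()].
#' @return List with `series` (named list of `L x m` matrices), `m`,
#'   `explained` (per-component variance shares), `center` and `rotation`.
#' @export
reduce_channels <- function(curves, config = reducer_config()) {
  if (length(curves) < 2) stop("need at least 2 subjects")
  if (config$method == "tsne") {
    stop("the t-SNE reducer is not available in this build; use method = \"pca\"")
  }
  mats <- lapply(curves, function(x) if (inherits(x, "representative_gait")) x$curves else x)
  pooled <- do.call(rbind, mats)
  if (all(apply(pooled, 2, var) < 1e-12)) stop("zero-variance input: nothing to reduce")
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(shares) >= config$variance_target - 1e-12)[1]
  series <- lapply(mats, function(x) {
    sc <- sweep(x, 2, pc$center) %*% pc$rotation[, seq_len(m), drop = FALSE]
    colnames(sc) <- paste0("pc", seq_len(m))
    sc
  })
  list(series = series, m = m, explained = shares,
       center = pc$center, rotation = pc$rotation)
}

#' Dynamic time warping distance between two multichannel series
#'
#' Classic dynamic-programming DTW with steps match/insert/delete, local cost
#' equal to the Euclidean distance across channels, and no warping-window
#' constraint. Handles series of different lengths.
#'
#' @param a,b Numeric matrices (time x channel) with the same channel count;
#'   vectors are treated as single-channel series.
#' @return The optimal cumulative alignment cost (nonnegative scalar).
#' @export
dtw_distance <- function(a, b) {
  a <- as_series_matrix(a); b <- as_series_matrix(b)
  if (ncol(a) != ncol(b)) stop("series have different channel counts")
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty series")
  .dtw_cost(a, b)
}

as_series_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
}

#' Pairwise inter-subject dissimilarity matrix
#'
#' Computes the DTW distance between every subject pair. In fused mode the
#' waveform block is combined with a Euclidean distance on cohort-standardized
#' age and height: both blocks are max-min rescaled to `[0, 1]` over their
#' off-diagonal entries, then `D = rescale(D_wave) + lambda * rescale(D_basic)`.
#'
#' @param series Named list of per-subject (time x channel) matrices (e.g.
#'   `reduce_channels(...)$series`).
#' @param basic Data frame with columns `age` and `height`, one row per
#'   subject in the same order; required for the fused mode.
#' @param mode `"waveform_only"` or `"waveform_plus_basic"`.
#' @param lambda Nonnegative fusion weight (default 1: equal block weight).
#' @return An object of class `dissimilarity_matrix`: list with `D` (symmetric,
#'   zero diagonal), `n`, `mode`, `lambda` and `subject_ids`.
#' @export
pairwise_dissimilarity <- function(series, basic = NULL,
                                   mode = c("waveform_only", "waveform_plus_basic"),
                                   lambda = 1) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be nonnegative")
  n <- length(series)
  ids <- names(series) %||% as.character(seq_len(n))
  D_wave <- .dtw_pairwise(lapply(series, as_series_matrix))
  if (mode == "waveform_plus_basic") {
    if (is.null(basic) || !all(c("age", "height") %in% names(basic))) {
      stop("fused mode requires a `basic` table with age and height")
    }
    if (nrow(basic) != n || anyNA(basic[, c("age", "height")])) {
      stop("fused mode requires complete age/height for every subject")
    }
    Z <- scale(as.matrix(basic[, c("age", "height")]))
    Z[is.nan(Z)] <- 0  # constant column
    D_basic <- as.matrix(dist(Z))
    D <- maxmin_rescale(D_wave) + lambda * maxmin_rescale(D_basic)
  } else {
    D <- D_wave
  }
  dimnames(D) <- list(ids, ids)
  structure(list(D = D, n = n, mode = mode, lambda = lambda, subject_ids = ids),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d subjects, mode %s (lambda %g)\n",
              x$n, x$mode, x$lambda))
  invisible(x)
}

#' Metric MDS embedding of a dissimilarity matrix
#'
#' Metric least-squares multidimensional scaling by iterative stress
#' majorization (the SMACOF update), initialized from the classical-scaling
#' solution plus a small seeded perturbation. Reports normalized stress
#' (Kruskal stress-1).
#'
#' @param D A `dissimilarity_matrix` or a symmetric matrix with zero diagonal.
#' @param d Embedding dimension (default 5).
#' @param seed Seed for the start perturbation.
#' @param max_iter,tol Majorization iteration controls.
#' @return An object of class `mds_embedding`: list with `coordinates`
#'   (`n x d`), `stress` and `d`.
#' @export
mds_embed <- function(D, d = 5L, seed = 1L, max_iter = 500L, tol = 1e-10) {
  M <- if (inherits(D, "dissimilarity_matrix")) D$D else as.matrix(D)
  if (d < 2) stop("embedding dimension must be >= 2")
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) stop("D must be symmetric")
  n <- nrow(M)
  d <- min(as.integer(d), n - 1L)
  if (all(M < 1e-15)) {
    return(structure(list(coordinates = matrix(0, n, d), stress = 0, d = d),
                     class = "mds_embedding"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  X <- cmdscale(M, k = d)
  if (ncol(X) < d) X <- cbind(X, matrix(0, n, d - ncol(X)))
  X <- X + rnorm(n * d, 0, 1e-6 * (max(M) + 1))
  stress_raw <- function(X) {
    dx <- as.matrix(dist(X))
    sum((dx[upper.tri(dx)] - M[upper.tri(M)])^2)
  }
  s_prev <- stress_raw(X)
  for (it in seq_len(max_iter)) {
    dx <- as.matrix(dist(X))
    ratio <- ifelse(dx > 1e-12, M / dx, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n  # Guttman transform (V = n * centering for full weights)
    s_new <- stress_raw(X)
    if (s_prev - s_new < tol * max(s_prev, 1e-300)) break
    s_prev <- s_new
  }
  dx <- as.matrix(dist(X))
  denom <- sum(M[upper.tri(M)]^2)
  stress1 <- if (denom > 0) sqrt(stress_raw(X) / denom) else 0
  rownames(X) <- rownames(M)
  structure(list(coordinates = X, stress = stress1, d = d),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %d dimensions, stress-1 %.4g\n",
              nrow(x$coordinates), x$d, x$stress))
  invisible(x)
}
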