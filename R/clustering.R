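# Candidate clustering conditions, internal validation, effect-size gating and
# composite method selection.

#' Enumerate candidate clustering conditions
#'
#' @param reducers,algorithms,ks,modes Candidate values; defaults span the
#'   full search: four algorithms, k in 3..5, waveform-only and fused
#'   dissimilarities.
#' @return Data frame of conditions, one per row.
#' @export
cluster_conditions <- function(reducers = "pca",
                               algorithms = c("kmeans_pp", "kmedoids_pp",
                                              "fuzzy_cmeans", "hierarchical"),
                               ks = 3:5,
                               modes = c("waveform_only", "waveform_plus_basic")) {
  expand.grid(reducer = reducers, algorithm = algorithms, k = ks, mode = modes,
              stringsAsFactors = FALSE)
}

# kmeans++-style careful seeding: D2 sampling from a coordinate matrix
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j + 1], ])^2))
  }
  centers
}

# careful seeding on a precomputed distance matrix (for k-medoids)
medoidpp_init <- function(D, k) {
  n <- nrow(D)
  med <- integer(k)
  med[1] <- sample.int(n, 1)
  d2 <- D[, med[1]]^2
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    med[j + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, D[, med[j + 1]]^2)
  }
  med
}

#' Cluster subjects under one condition
#'
#' `kmeans_pp` and `fuzzy_cmeans` operate on the MDS embedding coordinates
#' with careful (D^2-sampling) seeding; `kmedoids_pp` operates directly on the
#' dissimilarity matrix (careful seeding, then PAM swap refinement);
#' `hierarchical` is average-linkage agglomeration on the dissimilarity
#' matrix cut at `k`. Stochastic algorithms use `restarts` seeded restarts and
#' keep the best-objective solution; a collapsed (empty-cluster) restart is
#' re-seeded.
#'
#' @param D A `dissimilarity_matrix` (or square matrix).
#' @param E An `mds_embedding` (or coordinate matrix).
#' @param condition One-row data frame (or list) with `algorithm` and `k`.
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts for the stochastic algorithms.
#' @return An object of class `cluster_solution`: list with `labels`
#'   (integers 1..k), `sizes`, `condition` and `medoids` (k-medoids only).
#' @export
run_clustering <- function(D, E, condition, seed = 1L, restarts = 10L) {
  M <- if (inherits(D, "dissimilarity_matrix")) D$D else as.matrix(D)
  X <- if (inherits(E, "mds_embedding")) E$coordinates else as.matrix(E)
  k <- as.integer(condition$k)
  algorithm <- as.character(condition$algorithm)
  n <- nrow(M)
  if (k > n) stop("k cannot exceed the number of subjects")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  labels <- NULL; medoids <- NULL
  if (algorithm == "kmeans_pp") {
    best <- Inf
    for (r in seq_len(restarts)) {
      for (try in 1:20) {
        init <- X[kmeanspp_init(X, k), , drop = FALSE]
        fit <- tryCatch(kmeans(X, centers = init, iter.max = 100L),
                        error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) stop("k-means failed to find a non-degenerate solution")
      if (fit$tot.withinss < best) {
        best <- fit$tot.withinss
        labels <- fit$cluster
      }
    }
  } else if (algorithm == "fuzzy_cmeans") {
    best <- Inf
    for (r in seq_len(restarts)) {
      for (try in 1:20) {
        init <- X[kmeanspp_init(X, k), , drop = FALSE]
        fit <- tryCatch(e1071::cmeans(X, centers = init, m = 2, iter.max = 300L,
                                      method = "cmeans"),
                        error = function(e) NULL)
        lab <- if (!is.null(fit)) apply(fit$membership, 1, which.max) else NULL
        if (!is.null(lab) && length(unique(lab)) == k) break
        fit <- NULL
      }
      if (is.null(fit)) stop("fuzzy c-means failed to find a non-degenerate solution")
      if (fit$withinerror < best) {
        best <- fit$withinerror
        labels <- apply(fit$membership, 1, which.max)
      }
    }
  } else if (algorithm == "kmedoids_pp") {
    if (k == n) {
      labels <- seq_len(n); medoids <- seq_len(n)
    } else {
      best <- Inf
      for (r in seq_len(restarts)) {
        init <- medoidpp_init(M, k)
        fit <- cluster::pam(as.dist(M), k = k, medoids = init)
        if (fit$objective["swap"] < best) {
          best <- fit$objective["swap"]
          labels <- fit$clustering
          medoids <- as.integer(fit$id.med)
        }
      }
    }
  } else if (algorithm == "hierarchical") {
    labels <- cutree(hclust(as.dist(M), method = "average"), k = k)
  } else {
    stop("unknown clustering algorithm: ", algorithm)
  }
  labels <- as.integer(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0)) stop("clustering produced an empty cluster")
  structure(list(labels = labels, sizes = sizes, k = k,
                 condition = condition, medoids = medoids),
            class = "cluster_solution")
}

#' Gate configuration for the effect-size screen
#'
#' @param key_parameters Parameters tested for between-cluster effects
#'   (default: the seven key fall-related parameters).
#' @param effect_threshold Minimum clinically meaningful effect size
#'   (default 0.14); a condition passes a parameter only if its effect
#'   strictly exceeds this.
#' @param min_passing Minimum number of key parameters that must exceed the
#'   threshold (default 4).
#' @param normality_alpha Shapiro-Wilk alpha for choosing between the ANOVA
#'   and rank branches (default 0.05).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(key_parameters = key_gate_parameters(),
                        effect_threshold = 0.14, min_passing = 4L,
                        normality_alpha = 0.05) {
  if (effect_threshold <= 0) stop("effect_threshold must be positive")
  if (min_passing > length(key_parameters)) {
    stop("min_passing cannot exceed the number of key parameters")
  }
  structure(list(key_parameters = key_parameters,
                 effect_threshold = effect_threshold,
                 min_passing = as.integer(min_passing),
                 normality_alpha = normality_alpha),
            class = "gate_config")
}

#' Between-cluster effect size of one parameter
#'
#' If the Shapiro-Wilk test retains normality in every cluster (and every
#' cluster has at least 3 members with nonzero spread), a one-way ANOVA is
#' used and eta-squared (`SS_between / SS_total`) reported; otherwise the
#' Kruskal-Wallis test is used with epsilon-squared
#' `H * (N + 1) / (N^2 - 1)` (algebraically `H / (N - 1)`).
#'
#' @param values Per-subject parameter values.
#' @param labels Cluster labels.
#' @param alpha Shapiro-Wilk alpha.
#' @param parameter Parameter name carried into the result.
#' @return An object of class `effect_size_result`: list with `parameter`,
#'   `test_used` (`"anova_eta2"` or `"kruskal_epsilon2"`), `statistic`,
#'   `p_value` and `effect` in `[0, 1]`.
#' @export
effect_size <- function(values, labels, alpha = 0.05, parameter = NA_character_) {
  keep <- is.finite(values)
  values <- values[keep]; labels <- labels[keep]
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 clusters")
  counts <- table(g)
  normal <- all(counts >= 3) && all(vapply(levels(g), function(l) {
    v <- values[g == l]
    if (length(unique(v)) < 3 || sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }, TRUE))
  if (normal) {
    grand <- mean(values)
    ssb <- sum(tapply(values, g, function(v) length(v) * (mean(v) - grand)^2))
    sst <- sum((values - grand)^2)
    eff <- if (sst > 0) ssb / sst else 0
    fit <- aov(values ~ g)
    stat <- summary(fit)[[1]][["F value"]][1]
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    res <- list(parameter = parameter, test_used = "anova_eta2",
                statistic = stat, p_value = p, effect = min(max(eff, 0), 1))
  } else {
    kt <- kruskal.test(values, g)
    N <- length(values)
    eff <- unname(kt$statistic) * (N + 1) / (N^2 - 1)
    res <- list(parameter = parameter, test_used = "kruskal_epsilon2",
                statistic = unname(kt$statistic), p_value = kt$p.value,
                effect = min(max(eff, 0), 1))
  }
  structure(res, class = "effect_size_result")
}

#' Apply the effect-size gate to a condition
#'
#' Passes if and only if the effect size strictly exceeds the threshold for
#' at least `min_passing` of the key parameters.
#'
#' @param effects List of [effect_size()] results, one per key parameter.
#' @param gate A [gate_config()].
#' @return Logical scalar.
#' @export
gate_condition <- function(effects, gate = gate_config()) {
  got <- vapply(effects, `[[`, "", "parameter")
  missing <- setdiff(gate$key_parameters, got)
  if (length(missing) > 0) {
    stop("missing effect sizes for key parameters: ", paste(missing, collapse = ", "))
  }
  eff <- vapply(effects[match(gate$key_parameters, got)], `[[`, 0, "effect")
  sum(eff > gate$effect_threshold) >= gate$min_passing
}

#' Internal cluster quality indices
#'
#' Silhouette coefficient from the precomputed dissimilarity matrix,
#' Davies-Bouldin score from the embedding coordinates, and cluster balance
#' (largest minus smallest cluster size; lower is better).
#'
#' @param D A `dissimilarity_matrix` (or square matrix).
#' @param E An `mds_embedding` (or coordinate matrix).
#' @param solution A [run_clustering()] solution (or a label vector).
#' @return An object of class `quality_indices`: list with `silhouette`,
#'   `davies_bouldin` and `balance`.
#' @export
quality_indices <- function(D, E, solution) {
  M <- if (inherits(D, "dissimilarity_matrix")) D$D else as.matrix(D)
  X <- if (inherits(E, "mds_embedding")) E$coordinates else as.matrix(E)
  labels <- if (inherits(solution, "cluster_solution")) solution$labels else as.integer(solution)
  k <- length(unique(labels))
  if (k < 2) stop("quality indices need at least 2 clusters")
  sizes <- as.integer(table(labels))
  if (all(sizes == 1)) stop("silhouette undefined for singleton-only clusterings")
  sil <- cluster::silhouette(labels, dmatrix = M)
  silhouette <- mean(sil[, "sil_width"])
  centroids <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(X[labels == l, , drop = FALSE])
  }))
  scatter <- vapply(seq_len(k), function(j) {
    mean(sqrt(rowSums(sweep(X[labels == sort(unique(labels))[j], , drop = FALSE],
                            2, centroids[j, ])^2)))
  }, 0)
  cd <- as.matrix(dist(centroids))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      if (cd[i, j] > 0) (scatter[i] + scatter[j]) / cd[i, j] else Inf
    }, 0))
  }, 0))
  structure(list(silhouette = silhouette, davies_bouldin = db,
                 balance = max(sizes) - min(sizes)),
            class = "quality_indices")
}

#' Select the best clustering condition
#'
#' Over the gate-passing evaluations, each quality index is max-min
#' normalized across the passing set (a degenerate index, constant across
#' conditions, contributes 0.5) and directions aligned so larger is better:
#' `composite = norm(silhouette) + (1 - norm(davies_bouldin)) +
#' (1 - norm(balance))`. The highest composite wins; ties break on raw
#' silhouette.
#'
#' @param evaluations List of `method_evaluation` objects (see
#'   [evaluate_conditions()]).
#' @return The winning evaluation, with `composite` filled in for all passing
#'   evaluations in the `all` attribute.
#' @export
select_best <- function(evaluations) {
  passing <- Filter(function(e) isTRUE(e$gate_passed), evaluations)
  if (length(passing) == 0) {
    stop("no admissible method: no condition passed the effect-size gate")
  }
  norm01 <- function(v) {
    if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else rep(0.5, length(v))
  }
  sil <- vapply(passing, function(e) e$indices$silhouette, 0)
  db <- vapply(passing, function(e) e$indices$davies_bouldin, 0)
  bal <- vapply(passing, function(e) e$indices$balance, 0)
  composite <- norm01(sil) + (1 - norm01(db)) + (1 - norm01(bal))
  for (i in seq_along(passing)) passing[[i]]$composite <- composite[i]
  ord <- order(-composite, -sil)
  best <- passing[[ord[1]]]
  attr(best, "all") <- passing
  best
}

#' Evaluate every clustering condition and pick the winner
#'
#' Runs each condition's clustering, computes the seven key-parameter effect
#' sizes against its labels, applies the effect-size gate, computes quality
#' indices for gate-passing conditions, and selects the best by the composite
#' score.
#'
#' @param subjects Subject feature data frame (key gate parameters as
#'   columns).
#' @param dissimilarities Named list of `dissimilarity_matrix` objects, one
#'   per mode appearing in `conditions`.
#' @param embeddings Named list of `mds_embedding` objects, matching
#'   `dissimilarities`.
#' @param conditions Data frame from [cluster_conditions()].
#' @param gate A [gate_config()].
#' @param seed Master seed; each condition gets a deterministic child seed.
#' @return List with `best` (winning evaluation), `evaluations` (all), and
#'   `table` (one row per condition: gate flag, indices, composite).
#' @export
evaluate_conditions <- function(subjects, dissimilarities, embeddings,
                                conditions = cluster_conditions(),
                                gate = gate_config(), seed = 1L) {
  evaluations <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, , drop = FALSE]
    D <- dissimilarities[[cond$mode]]
    E <- embeddings[[cond$mode]]
    if (is.null(D) || is.null(E)) {
      stop("no dissimilarity/embedding supplied for mode ", cond$mode)
    }
    sol <- run_clustering(D, E, cond,
                          seed = child_seed(seed, paste0("clust", i)))
    effects <- lapply(gate$key_parameters, function(p) {
      effect_size(subjects[[p]], sol$labels, alpha = gate$normality_alpha,
                  parameter = p)
    })
    passed <- gate_condition(effects, gate)
    idx <- if (passed) quality_indices(D, E, sol) else NULL
    evaluations[[i]] <- structure(
      list(condition = cond, solution = sol, effect_sizes = effects,
           gate_passed = passed, indices = idx, composite = NA_real_),
      class = "method_evaluation")
  }
  best <- select_best(evaluations)
  # pull composites back into the full list
  for (p in attr(best, "all")) {
    j <- which(vapply(evaluations, function(e) {
      identical(e$condition, p$condition)
    }, TRUE))
    evaluations[[j]]$composite <- p$composite
  }
  tab <- do.call(rbind, lapply(evaluations, function(e) {
    data.frame(e$condition,
               gate_passed = e$gate_passed,
               n_effects_passing = sum(vapply(e$effect_sizes, `[[`, 0, "effect") >
                                         gate$effect_threshold),
               silhouette = if (is.null(e$indices)) NA_real_ else e$indices$silhouette,
               davies_bouldin = if (is.null(e$indices)) NA_real_ else e$indices$davies_bouldin,
               balance = if (is.null(e$indices)) NA_real_ else e$indices$balance,
               composite = e$composite)
  }))
  list(best = best, evaluations = evaluations, table = tab)
}
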