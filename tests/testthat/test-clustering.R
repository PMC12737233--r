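# Clustering algorithms, effect-size gate, quality indices, method selection.

make_triplets <- function() {
  # 3 well-separated triplets in 2-D
  X <- rbind(matrix(rnorm(6, 0, 0.05), 3, 2),
             matrix(rnorm(6, 10, 0.05), 3, 2),
             cbind(rnorm(3, 0, 0.05), rnorm(3, 20, 0.05)))
  list(X = X, D = as.matrix(dist(X)), truth = rep(1:3, each = 3))
}

test_that("every algorithm recovers trivially separable groups", {
  set.seed(21)
  fx <- make_triplets()
  for (alg in c("kmeans_pp", "kmedoids_pp", "fuzzy_cmeans", "hierarchical")) {
    sol <- run_clustering(fx$D, fx$X, list(algorithm = alg, k = 3), seed = 1)
    expect_equal(length(unique(sol$labels[fx$truth == 1])), 1, info = alg)
    expect_equal(length(unique(sol$labels[fx$truth == 2])), 1, info = alg)
    expect_equal(length(unique(sol$labels[fx$truth == 3])), 1, info = alg)
    expect_equal(sort(sol$sizes), c(3, 3, 3), info = alg)
  }
})

test_that("k equal to n gives singleton medoid clusters", {
  set.seed(22)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  sol <- run_clustering(D, X, list(algorithm = "kmedoids_pp", k = 6), seed = 1)
  expect_equal(sort(sol$labels), 1:6)
  expect_error(run_clustering(D, X, list(algorithm = "kmeans_pp", k = 7), seed = 1),
               "exceed")
})

test_that("k-medoids attains the exhaustive-search optimum on a small instance", {
  set.seed(23)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  sol <- run_clustering(D, X, list(algorithm = "kmedoids_pp", k = 2), seed = 3)
  cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  best <- min(apply(utils::combn(6, 2), 2, cost))
  got <- cost(sol$medoids)
  expect_equal(got, best)
})

test_that("effect sizes match the SS-decomposition and rank-test identities", {
  # no between-group variance
  r0 <- effect_size(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(r0$effect, 0)
  # essentially all variance between groups
  set.seed(24)
  r1 <- effect_size(c(rnorm(5, 0, 1e-3), rnorm(5, 10, 1e-3)), rep(1:2, each = 5))
  expect_gt(r1$effect, 0.95)

  for (i in 1:20) {
    v <- rnorm(30)
    g <- sample(rep(1:3, each = 10))
    r <- effect_size(v, g, parameter = "x")
    if (r$test_used == "anova_eta2") {
      grand <- mean(v)
      ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
      expect_equal(r$effect, ssb / sum((v - grand)^2))
    } else {
      H <- unname(kruskal.test(v, factor(g))$statistic)
      expect_equal(r$effect, H / (length(v) - 1))
      expect_equal(r$effect, H * (length(v) + 1) / (length(v)^2 - 1))
    }
  }
})

test_that("non-normal data and tiny clusters take the rank-based branch", {
  set.seed(25)
  v <- exp(rnorm(40, 0, 2))  # heavily skewed
  g <- rep(1:2, each = 20)
  expect_equal(effect_size(v, g)$test_used, "kruskal_epsilon2")
  # a cluster with < 3 members cannot be tested for normality
  r2 <- effect_size(rnorm(22), c(rep(1, 20), rep(2, 2)))
  expect_equal(r2$test_used, "kruskal_epsilon2")
})

test_that("the gate counts strict exceedances of the 0.14 threshold", {
  mk <- function(effects) {
    mapply(function(e, p) structure(list(parameter = p, effect = e),
                                    class = "effect_size_result"),
           effects, key_gate_parameters(), SIMPLIFY = FALSE)
  }
  expect_true(gate_condition(mk(c(0.2, 0.2, 0.2, 0.2, 0.05, 0.05, 0.05))))
  expect_false(gate_condition(mk(rep(0.14, 7))))
  set.seed(26)
  for (i in 1:50) {
    e <- runif(7, 0, 0.4)
    expect_equal(gate_condition(mk(e)), sum(e > 0.14) >= 4)
    # monotonicity: raising any effect never flips pass -> fail
    j <- sample(7, 1)
    e2 <- e; e2[j] <- e2[j] + 0.2
    if (gate_condition(mk(e))) expect_true(gate_condition(mk(e2)))
  }
  expect_error(gate_condition(mk(runif(7))[1:2]), "missing effect sizes")
})

test_that("cluster balance is the size range and silhouettes match hand computation", {
  set.seed(27)
  labels <- rep(1:4, times = c(39, 34, 40, 33))
  X <- matrix(rnorm(2 * length(labels)), ncol = 2) +
    10 * cbind(labels %% 2, labels %/% 2)
  D <- as.matrix(dist(X))
  qi <- quality_indices(D, X, labels)
  expect_equal(qi$balance, 7)
  expect_equal(quality_indices(D, X, rep(1:2, 73))$balance, 0)

  # 8-point toy: silhouette by direct a/b computation
  X8 <- matrix(c(0, 0, 0, 1, 1, 0, 5, 5, 5, 6, 6, 5, 0, 6, 6, 0), ncol = 2,
               byrow = TRUE)
  lab8 <- c(1, 1, 1, 2, 2, 2, 1, 2)
  D8 <- as.matrix(dist(X8))
  qi8 <- quality_indices(D8, X8, lab8)
  sil_manual <- vapply(1:8, function(i) {
    a <- mean(D8[i, lab8 == lab8[i] & seq_len(8) != i])
    b <- mean(D8[i, lab8 != lab8[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_equal(qi8$silhouette, mean(sil_manual))
  expect_error(quality_indices(D8, X8, 1:8), "singleton")
})

test_that("composite selection honours dominance, degeneracy and recomputation", {
  mk_eval <- function(sil, db, bal, passed = TRUE, id = 1) {
    structure(list(condition = data.frame(id = id),
                   gate_passed = passed,
                   indices = list(silhouette = sil, davies_bouldin = db,
                                  balance = bal),
                   composite = NA_real_),
              class = "method_evaluation")
  }
  # dominance
  best <- select_best(list(mk_eval(0.5, 0.8, 2, id = 1), mk_eval(0.2, 1.5, 9, id = 2)))
  expect_equal(best$condition$id, 1)
  # single passing condition: all three indices degenerate at 0.5 each
  single <- select_best(list(mk_eval(0.3, 1.1, 4, id = 1),
                             mk_eval(0.5, 0.9, 2, passed = FALSE, id = 2)))
  expect_equal(single$composite, 1.5)
  expect_error(select_best(list(mk_eval(0.5, 1, 1, passed = FALSE))),
               "no admissible method")

  set.seed(28)
  for (rep in 1:10) {
    sil <- runif(5, -0.2, 0.8); db <- runif(5, 0.3, 3); bal <- sample(0:30, 5)
    evals <- lapply(1:5, function(i) mk_eval(sil[i], db[i], bal[i], id = i))
    norm01 <- function(v) if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else rep(0.5, length(v))
    comp <- norm01(sil) + (1 - norm01(db)) + (1 - norm01(bal))
    expect_equal(select_best(evals)$condition$id, order(-comp, -sil)[1])
    # invariance to positive affine rescaling of an index across conditions
    evals2 <- lapply(1:5, function(i) mk_eval(sil[i], 10 + 4 * db[i], bal[i], id = i))
    expect_equal(select_best(evals2)$condition$id, select_best(evals)$condition$id)
  }
})
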