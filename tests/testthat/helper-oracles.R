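# Independent oracles and small fixtures used across the test files.

# full-table dynamic-programming DTW, written independently of the package's
# kernel (no rolling rows, plain R)
dtw_dp_oracle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  cost <- matrix(Inf, n + 1, m + 1)
  cost[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      lc <- sqrt(sum((a[i, ] - b[j, ])^2))
      cost[i + 1, j + 1] <- lc + min(cost[i, j], cost[i, j + 1], cost[i + 1, j])
    }
  }
  cost[n + 1, m + 1]
}

# exhaustive-enumeration Shapley values for a prediction function under the
# interventional value function v(S) = mean_z f(x_S, z_{S^c})
shapley_enum_oracle <- function(predict_fn, x, Z, d) {
  subsets <- lapply(0:(2^d - 1), function(mask) which(bitwAnd(mask, 2^(0:(d - 1))) > 0))
  v <- vapply(subsets, function(S) {
    M <- Z
    if (length(S) > 0) M[, S] <- matrix(x[S], nrow(Z), length(S), byrow = TRUE)
    mean(predict_fn(M))
  }, 0)
  names(v) <- vapply(subsets, function(S) paste(S, collapse = ","), "")
  phi <- numeric(d)
  for (i in seq_len(d)) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (i %in% S) next
      Si <- sort(c(S, i))
      s <- length(S)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      phi[i] <- phi[i] + w * (v[[paste(Si, collapse = ",")]] - v[[si]])
    }
  }
  phi
}

# small two-blob binary classification fixture; the signal columns take a few
# repeated discrete values so every fold's training data spans the class
# extremes (split-threshold conventions at empty regions then cannot flip
# boundary points)
make_blobs <- function(n = 60, gap = 6, seed = 1, prop_pos = 0.5) {
  set.seed(seed)
  n1 <- round(n * prop_pos); n0 <- n - n1
  jit <- function(m) sample(rep_len(c(-0.5, 0, 0.5), m))
  X <- rbind(cbind(jit(n0), jit(n0)),
             cbind(gap + jit(n1), gap + jit(n1)))
  list(X = cbind(X, matrix(rnorm(n * 3), n, 3)),  # 3 noise features
       y = c(rep(0L, n0), rep(1L, n1)))
}

# a small deterministic stride for signal tests
toy_stride <- function(n = 50, seed = 1) {
  set.seed(seed)
  stride_waveform("T01", acc_y = sin(seq(0, 2 * pi, length.out = n)),
                  acc_z = cos(seq(0, 2 * pi, length.out = n)),
                  gyro_x = seq_len(n) / n)
}
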