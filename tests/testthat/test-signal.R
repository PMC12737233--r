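# Waveform preprocessing: filtering, segmentation, normalization, averaging.

test_that("low-pass filter preserves DC and has the expected frequency response", {
  cfg <- signal_config()
  x <- rep(3.7, 300)
  expect_equal(lowpass_filter(x, cfg), x, tolerance = 1e-8)

  t <- seq(0, 3, by = 1 / 104)
  slow <- sin(2 * pi * 1 * t)
  fast <- sin(2 * pi * 20 * t)
  mid <- 100:250  # avoid edge transients when measuring amplitude
  expect_gt(max(abs(lowpass_filter(slow, cfg)[mid])), 0.95)
  expect_lt(max(abs(lowpass_filter(fast, cfg)[mid])), 0.10)
})

test_that("low-pass filter is zero-phase and keeps length", {
  cfg <- signal_config()
  x <- exp(-((seq_len(301) - 151)^2) / (2 * 20^2))  # symmetric bump
  y <- lowpass_filter(x, cfg)
  expect_length(y, length(x))
  expect_equal(which.max(y), 151)
  expect_error(lowpass_filter(rnorm(10), cfg), "too short")
})

test_that("stride segmentation follows the half-open start-to-start convention", {
  rec <- data.frame(acc_y = 1:30, acc_z = 31:60, gyro_x = 61:90)
  st <- suppressMessages(segment_strides(rec, c(1, 11, 21)))
  expect_length(st, 2)
  expect_equal(st[[1]]$acc_y, 1:10)
  expect_equal(st[[2]]$acc_y, 11:20)
  expect_warning(out <- segment_strides(rec, integer()), "empty")
  expect_length(out, 0)
  expect_error(segment_strides(rec, c(10, 5)), "increasing")
  expect_error(segment_strides(rec, c(1, 40)), "outside")
})

test_that("segments plus tail reconstruct the recording", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    rec <- data.frame(acc_y = rnorm(n), acc_z = rnorm(n), gyro_x = rnorm(n))
    ev <- sort(sample(seq_len(n - 1), sample(2:6, 1)))
    st <- suppressMessages(segment_strides(rec, ev))
    kept <- unlist(lapply(st, `[[`, "acc_y"))
    # dropped short strides and the tail account for the remainder
    full <- rec$acc_y[ev[1]:(ev[length(ev)] - 1)]
    expect_true(all(kept %in% full))
    if (all(diff(ev) >= 2)) expect_equal(kept, full)
  }
})

test_that("filtering and segmenting commute", {
  cfg <- signal_config()
  set.seed(6)
  n <- 200
  rec <- data.frame(acc_y = rnorm(n), acc_z = rnorm(n), gyro_x = rnorm(n))
  filtered <- as.data.frame(lowpass_filter(rec, cfg))
  ev <- c(1, 81, 161)
  a <- suppressMessages(segment_strides(filtered, ev))
  b <- suppressMessages(segment_strides(rec, ev))
  # segmenting the filtered recording = segmenting then slicing the filtered series
  expect_equal(a[[1]]$acc_z, lowpass_filter(rec$acc_z, cfg)[1:80])
  expect_equal(b[[2]]$acc_y, rec$acc_y[81:160])
})

test_that("time normalization interpolates linearly and is idempotent", {
  ramp <- stride_waveform("x", seq(0, 9, length.out = 10), rep(2, 10), 1:10)
  out <- time_normalize_stride(ramp, 100)
  expect_equal(out[, "acc_y"], seq(0, 9, length.out = 100))
  expect_equal(out[, "acc_z"], rep(2, 100))
  expect_equal(unname(out[1, "acc_y"]), 0)
  expect_equal(unname(out[100, "acc_y"]), 9)
  # identity when L equals the original length
  s <- toy_stride(40)
  expect_equal(time_normalize_stride(s, 40)[, "gyro_x"], s$gyro_x)
  # idempotence on an already normalized curve
  curve <- time_normalize_stride(s, 100)
  again <- time_normalize_stride(
    stride_waveform("x", curve[, 1], curve[, 2], curve[, 3]), 100)
  expect_equal(again, curve)
  expect_error(stride_waveform("x", 1, 1, 1), "at least 2 samples")
})

test_that("representative curve is the pointwise mean of normalized strides", {
  cfg <- signal_config(normalized_length = 60)
  s <- toy_stride(50)
  one <- representative_curves(list(s), cfg)
  expect_equal(one$curves, time_normalize_stride(s, 60))
  expect_equal(one$n_strides_used, 1)
  two <- representative_curves(list(s, s), cfg)
  expect_equal(two$curves, time_normalize_stride(s, 60))

  s50 <- toy_stride(50, seed = 2)
  s150 <- toy_stride(150, seed = 3)
  got <- representative_curves(list(s50, s150), cfg, outlier_filter = FALSE)
  manual <- (time_normalize_stride(s50, 60) + time_normalize_stride(s150, 60)) / 2
  expect_equal(got$curves, manual)
  expect_error(representative_curves(list(), cfg), "no valid strides")
})

test_that("representative curve lies within the pointwise stride envelope", {
  cfg <- signal_config(normalized_length = 50)
  set.seed(7)
  strides <- lapply(1:6, function(i) toy_stride(sample(30:80, 1), seed = i))
  rep_curve <- representative_curves(strides, cfg, outlier_filter = FALSE)$curves
  norm <- lapply(strides, time_normalize_stride, L = 50)
  lo <- Reduce(pmin, norm); hi <- Reduce(pmax, norm)
  expect_true(all(rep_curve >= lo - 1e-12 & rep_curve <= hi + 1e-12))
})

test_that("duration outliers are excluded from the average by default", {
  cfg <- signal_config(normalized_length = 40)
  normal <- lapply(1:6, function(i) toy_stride(95 + 2 * i, seed = i))
  outlier <- toy_stride(1000, seed = 99)
  normal <- lapply(normal, function(s) { s$duration_s <- s$n_samples / 104; s })
  outlier$duration_s <- outlier$n_samples / 104
  res <- representative_curves(c(normal, list(outlier)), cfg)
  expect_equal(res$n_strides_used, 6)
  res_off <- representative_curves(c(normal, list(outlier)), cfg, outlier_filter = FALSE)
  expect_equal(res_off$n_strides_used, 7)
})
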