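# Waveform preprocessing: filtering, stride segmentation, time normalization,
# and per-subject representative curves.

#' Signal configuration
#'
#' @param sampling_rate_hz IMU sampling rate (default 104 Hz).
#' @param lowpass_cutoff_hz Low-pass cutoff (default 4 Hz); must lie below the
#'   Nyquist frequency.
#' @param normalized_length Number of samples per time-normalized stride
#'   (default 100, i.e. percent-gait-cycle resolution).
#' @return An object of class `signal_config`.
#' @export
signal_config <- function(sampling_rate_hz = 104, lowpass_cutoff_hz = 4,
                          normalized_length = 100L) {
  if (lowpass_cutoff_hz <= 0 || lowpass_cutoff_hz >= sampling_rate_hz / 2) {
    stop("lowpass_cutoff_hz must lie in (0, sampling_rate_hz / 2)")
  }
  if (normalized_length < 10) stop("normalized_length must be >= 10")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 normalized_length = as.integer(normalized_length)),
            class = "signal_config")
}

#' Construct a stride waveform
#'
#' One stride's 3-channel IMU samples: progression acceleration (`acc_y`),
#' vertical acceleration (`acc_z`) and sagittal angular velocity (`gyro_x`).
#'
#' @param subject_id Subject identifier.
#' @param acc_y,acc_z Accelerations, m/s^2.
#' @param gyro_x Angular velocity, deg/s.
#' @param ... Additional per-stride scalars (e.g. `duration_s`).
#' @return An object of class `stride_waveform`.
#' @export
stride_waveform <- function(subject_id, acc_y, acc_z, gyro_x, ...) {
  n <- length(acc_y)
  if (length(acc_z) != n || length(gyro_x) != n) {
    stop("the three channels must have equal length")
  }
  if (n < 2) stop("a stride needs at least 2 samples")
  if (!all(is.finite(acc_y)) || !all(is.finite(acc_z)) || !all(is.finite(gyro_x))) {
    stop("stride samples must be finite")
  }
  structure(list(subject_id = subject_id, acc_y = acc_y, acc_z = acc_z,
                 gyro_x = gyro_x, n_samples = n, ...),
            class = "stride_waveform")
}

stride_channels <- c("acc_y", "acc_z", "gyro_x")

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase), so waveform landmarks are not shifted in time and the DC
#' component is preserved.
#'
#' @param x Numeric vector, or a matrix/data frame whose columns are channels.
#' @param config A [signal_config()].
#' @return Filtered series of the same shape.
#' @export
lowpass_filter <- function(x, config = signal_config()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass_filter, config = config))
  }
  order <- 4L
  n <- length(x)
  if (n <= 3 * order) {
    stop("series too short for the filter warm-up (need > ", 3 * order, " samples)")
  }
  bf <- signal::butter(order, config$lowpass_cutoff_hz / (config$sampling_rate_hz / 2),
                       type = "low")
  # odd-reflection padding suppresses the start-up transients of the
  # forward-backward pass (filtfilt itself assumes zero initial conditions)
  np <- min(n - 1L, 9L * ceiling(config$sampling_rate_hz / config$lowpass_cutoff_hz))
  front <- 2 * x[1] - x[(np + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(front, x, back))
  as.numeric(y[(np + 1):(np + n)])
}

#' Segment a recording into strides
#'
#' Cuts a continuous 3-channel recording at stride-start events, one stride
#' per consecutive event pair under the half-open convention
#' `[start, next_start)`. Samples after the last event (the tail) are not a
#' stride; strides shorter than 2 samples are dropped. Both counts are
#' reported via a message.
#'
#' @param recording Data frame or matrix with columns `acc_y`, `acc_z`,
#'   `gyro_x` (a `time_s` column is ignored).
#' @param events Integer vector of 1-based stride-start sample indices,
#'   strictly increasing and within the recording.
#' @param subject_id Identifier attached to the strides.
#' @return List of [stride_waveform()] objects.
#' @export
segment_strides <- function(recording, events, subject_id = NA_character_) {
  rec <- as.data.frame(recording)
  if (!all(stride_channels %in% names(rec))) {
    stop("recording must have columns acc_y, acc_z, gyro_x")
  }
  n <- nrow(rec)
  events <- as.integer(events)
  if (length(events) == 0) {
    warning("empty stride-event table: no strides segmented")
    return(list())
  }
  if (any(diff(events) <= 0)) stop("stride events must be strictly increasing")
  if (events[1] < 1 || events[length(events)] > n) {
    stop("stride events outside the recording")
  }
  starts <- events[-length(events)]
  ends <- events[-1] - 1L  # half-open [start, next_start)
  keep <- (ends - starts + 1L) >= 2L
  dropped <- sum(!keep)
  strides <- mapply(function(s, e) {
    stride_waveform(subject_id, rec$acc_y[s:e], rec$acc_z[s:e], rec$gyro_x[s:e])
  }, starts[keep], ends[keep], SIMPLIFY = FALSE)
  tail_n <- n - events[length(events)] + 1L
  message(sprintf("segmented %d strides (%d short strides dropped, %d tail samples ignored)",
                  length(strides), dropped, tail_n))
  strides
}

#' Time-normalize a stride to a uniform length
#'
#' Resamples each channel to exactly `L` points by linear interpolation over
#' normalized time `[0, 1]`; endpoints are preserved, and a stride already of
#' length `L` is returned unchanged.
#'
#' @param stride A [stride_waveform()] (or a list with the three channels).
#' @param L Target length.
#' @return `L x 3` numeric matrix with columns `acc_y`, `acc_z`, `gyro_x`.
#' @export
time_normalize_stride <- function(stride, L = 100L) {
  n <- length(stride$acc_y)
  if (n < 2) stop("cannot normalize a stride with fewer than 2 samples")
  t0 <- seq(0, 1, length.out = n)
  t1 <- seq(0, 1, length.out = L)
  out <- vapply(stride_channels,
                function(ch) approx(t0, stride[[ch]], xout = t1)$y,
                numeric(L))
  colnames(out) <- stride_channels
  out
}

#' Per-subject representative gait curves
#'
#' Averages a subject's time-normalized strides pointwise per channel into a
#' single representative 3-channel curve. Strides whose duration falls
#' outside median +/- 3 MAD are excluded first (configurable off); durations
#' are taken from each stride's `duration_s` if present, else its sample
#' count.
#'
#' @param strides List of [stride_waveform()] objects for one subject.
#' @param config A [signal_config()]; `normalized_length` sets the curve
#'   length `L`.
#' @param outlier_filter Exclude duration outliers before averaging?
#' @return An object of class `representative_gait`: list with `subject_id`,
#'   `curves` (`L x 3` matrix) and `n_strides_used`.
#' @export
representative_curves <- function(strides, config = signal_config(),
                                  outlier_filter = TRUE) {
  if (length(strides) == 0) stop("no valid strides to average")
  sid <- strides[[1]]$subject_id
  if (outlier_filter && length(strides) >= 4) {
    dur <- vapply(strides, function(s) s$duration_s %||% s$n_samples, 0)
    md <- median(dur)
    tol <- 3 * mad(dur)
    keep <- if (tol > 0) abs(dur - md) <= tol else rep(TRUE, length(dur))
    if (any(keep)) strides <- strides[keep]
  }
  if (length(strides) == 0) {
    stop("no strides left after outlier filtering for subject ", sid)
  }
  L <- config$normalized_length
  acc <- matrix(0, L, 3, dimnames = list(NULL, stride_channels))
  for (s in strides) acc <- acc + time_normalize_stride(s, L)
  structure(list(subject_id = sid, curves = acc / length(strides),
                 n_strides_used = length(strides)),
            class = "representative_gait")
}

#' Representative curves for every subject of a cohort
#'
#' @param cohort A `gait_cohort` (or any list with a `strides` element).
#' @param config A [signal_config()].
#' @param ... Passed to [representative_curves()].
#' @return Named list of `representative_gait` objects.
#' @export
cohort_representative_curves <- function(cohort, config = cohort$signal %||% signal_config(),
                                         ...) {
  lapply(cohort$strides, representative_curves, config = config, ...)
}

#' @export
print.representative_gait <- function(x, ...) {
  cat(sprintf("<representative_gait> subject %s: %d x 3 curve from %d strides\n",
              x$subject_id, nrow(x$curves), x$n_strides_used))
  invisible(x)
}
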