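# Internal helpers shared across modules.

#' Names of the gait and clinical features used throughout the pipeline
#'
#' The 25 per-subject features consumed by the faller classifiers and the
#' consensus ranking: stride-derived gait parameters (means and, where defined,
#' standard deviations across a subject's strides), free-walk totals, and
#' clinical test scores. Age and height are deliberately excluded: they enter
#' only the optional anthropometric block of the dissimilarity matrix.
#'
#' @return Character vector of 25 feature names.
#' @export
gait_feature_names <- function() {
  c(
    "cadence", "step_speed", "stride_length", "clearance",
    "total_distance", "total_time", "total_strides",
    "swing_pct", "load_pct", "foot_flat_pct", "push_pct",
    "stride_time", "toe_off_angle", "heel_strike_angle",
    "stride_time_std", "stride_length_std", "clearance_std",
    "path_3d", "path_2d",
    "gds", "frailty", "short_fes_i", "sppb", "gait_speed_4m", "tug_s"
  )
}

#' Key fall-related parameters used by the effect-size gate
#'
#' @return Character vector of the seven gate parameters.
#' @export
key_gate_parameters <- function() {
  c("cadence", "step_speed", "stride_length", "clearance",
    "swing_pct", "sppb", "tug_s")
}

# max-min rescale the off-diagonal entries of a square matrix to [0, 1];
# constant matrices map to all zeros (diagonal forced to 0).
maxmin_rescale <- function(M) {
  off <- M[row(M) != col(M)]
  lo <- min(off)
  hi <- max(off)
  out <- if (hi > lo) (M - lo) / (hi - lo) else M * 0
  diag(out) <- 0
  out
}

# deterministic child seed from a master seed and a stage label
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483562L
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
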