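# Synthetic cohort generator: phenotype-structured stride waveforms, correlated
# gait/clinical feature tables, and phenotype-specific fall-label mechanisms.

#' Generate a synthetic gait cohort
#'
#' Draws subjects from phenotype archetypes (near-equal split), synthesizes
#' stride-segmented 3-channel IMU waveforms per subject, derives the gait
#' parameter table from those strides, draws clinical scores, and assigns
#' 12-month fall labels through each archetype's planted mechanism.
#'
#' @param archetypes List of [gait_archetype()] objects.
#' @param n_subjects Cohort size; must be at least `4 * length(archetypes)`.
#' @param signal A [signal_config()].
#' @param seed Integer seed; identical calls with the same seed return an
#'   identical cohort.
#' @param n_strides_range Integer range from which each subject's stride count
#'   is drawn uniformly (free-walk lengths vary per subject).
#' @param missing_rate Proportion of clinical score fields masked to `NA`, to
#'   exercise the classifiers' imputation paths. Default 0 (complete data).
#'
#' @return An object of class `gait_cohort`: a list with `subjects` (wide
#'   feature data frame, one row per subject, including `fell` and, synthetic
#'   only, `true_phenotype`), `strides` (named list of per-subject stride
#'   waveform lists), `archetypes`, `signal` and `seed`.
#' @export
generate_cohort <- function(archetypes, n_subjects, signal = signal_config(),
                            seed = 1L, n_strides_range = c(20L, 60L),
                            missing_rate = 0) {
  if (length(archetypes) == 0) stop("at least one archetype is required")
  if (!all(vapply(archetypes, inherits, TRUE, "gait_archetype"))) {
    stop("`archetypes` must be a list of gait_archetype objects")
  }
  stopifnot_scalar_count(n_subjects, "n_subjects", min = 1L)
  if (n_subjects < 4L * length(archetypes)) {
    stop("n_subjects must be >= 4 per archetype")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  k <- length(archetypes)
  assign_idx <- rep_len(seq_len(k), n_subjects)  # near-equal split
  ids <- sprintf("S%03d", seq_len(n_subjects))

  subjects <- vector("list", n_subjects)
  strides <- vector("list", n_subjects)
  names(strides) <- ids
  for (i in seq_len(n_subjects)) {
    a <- archetypes[[assign_idx[i]]]
    eff <- draw_subject_effects(a)
    n_str <- sample(seq(n_strides_range[1], n_strides_range[2]), 1L)
    st <- generate_subject_strides(a, eff, n_str, signal)
    for (j in seq_along(st)) st[[j]]$subject_id <- ids[i]
    strides[[i]] <- st
    subjects[[i]] <- derive_subject_record(ids[i], a, eff, st)
  }
  subjects <- do.call(rbind, subjects)
  subjects$true_phenotype <- vapply(archetypes, `[[`, "", "name")[assign_idx]

  if (missing_rate > 0) {
    clin <- c("gds", "frailty", "short_fes_i", "sppb", "gait_speed_4m", "tug_s")
    for (cl in clin) {
      mask <- runif(n_subjects) < missing_rate
      subjects[[cl]][mask] <- NA_real_
    }
  }

  cohort <- structure(
    list(subjects = subjects, strides = strides,
         true_phenotype = setNames(subjects$true_phenotype, ids),
         archetypes = archetypes, signal = signal, seed = as.integer(seed)),
    class = "gait_cohort"
  )
  assign_fall_labels(cohort, archetypes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# subject-level deviations from the archetype means
draw_subject_effects <- function(a) {
  s <- a$within_phenotype_sd
  ph <- rnorm(4, a$phase_fractions, s[c("load", "foot_flat", "push", "swing")])
  ph <- pmax(ph, 0.02); ph <- ph / sum(ph)
  list(
    cadence = max(rnorm(1, a$cadence_mean, s["cadence"]), 10),
    step_speed = max(rnorm(1, a$step_speed_mean, s["step_speed"]), 0.05),
    stride_length = max(rnorm(1, a$stride_length_mean, s["stride_length"]), 0.05),
    clearance = max(rnorm(1, a$clearance_mean, s["clearance"]), 0.01),
    phase_fractions = setNames(ph, c("load", "foot_flat", "push", "swing")),
    stride_time_cv = max(rnorm(1, a$stride_time_cv, 0.2 * a$stride_time_cv), 0.005),
    age = rnorm(1, a$age_mean, s["age"]),
    height = max(rnorm(1, a$height_mean, s["height"]), 1.0),
    gds = clamp_int(rnorm(1, a$clinical_means["gds"], s["gds"]), 1, 7),
    frailty = clamp_int(rnorm(1, a$clinical_means["frailty"], s["frailty"]), 0, 5),
    short_fes_i = clamp_int(rnorm(1, a$clinical_means["short_fes_i"], s["short_fes_i"]), 7, 28),
    sppb = clamp_int(rnorm(1, a$clinical_means["sppb"], s["sppb"]), 0, 12),
    gait_speed_4m = max(rnorm(1, a$clinical_means["gait_speed_4m"], s["gait_speed_4m"]), 0.05),
    tug_s = max(rnorm(1, a$clinical_means["tug_s"], s["tug_s"]), 3)
  )
}

clamp_int <- function(x, lo, hi) min(max(round(x), lo), hi)

#' Synthesize the stride waveforms of one subject
#'
#' Each stride is a 3-channel series (progression acceleration `acc_y`,
#' vertical acceleration `acc_z`, sagittal angular velocity `gyro_x`) built
#' from event-locked smooth bumps: a heel-strike impact in the vertical
#' channel at the start of the load phase, a push-off peak in the progression
#' channel centred in the push phase, and a swing lobe in the angular-velocity
#' channel centred mid-swing. Bump positions follow the subject's gait-cycle
#' phase fractions; amplitudes scale with speed and clearance; white noise and
#' per-stride timing jitter are added, so strides differ in duration.
#'
#' Uses R's global random number stream (seed it, or call through
#' [generate_cohort()] which does).
#'
#' @param archetype A [gait_archetype()].
#' @param subject_effects Subject-level parameter list (overrides the
#'   archetype means); any of `cadence`, `step_speed`, `stride_length`,
#'   `clearance`, `phase_fractions`, `stride_time_cv`, plus optional
#'   `noise_sd` (m/s^2; default 0.25) and `jitter` (overrides the stride-time
#'   CV).
#' @param n_strides Number of strides to generate.
#' @param signal A [signal_config()].
#'
#' @return List of `stride_waveform` objects, each carrying the realized
#'   per-stride scalars (`duration_s`, `stride_length`, `clearance`) used to
#'   derive the subject's gait parameter table.
#' @export
generate_subject_strides <- function(archetype, subject_effects = list(),
                                     n_strides, signal = signal_config()) {
  stopifnot_scalar_count(n_strides, "n_strides", min = 1L)
  eff <- subject_effects
  cadence <- eff$cadence %||% archetype$cadence_mean
  if (cadence <= 0) stop("cadence must be positive")
  speed <- eff$step_speed %||% archetype$step_speed_mean
  slen <- eff$stride_length %||% archetype$stride_length_mean
  clear <- eff$clearance %||% archetype$clearance_mean
  ph <- eff$phase_fractions %||% archetype$phase_fractions
  cv <- eff$jitter %||% (eff$stride_time_cv %||% archetype$stride_time_cv)
  noise_sd <- eff$noise_sd %||% 0.25

  fs <- signal$sampling_rate_hz
  base_dur <- 60 / cadence  # one stride per gait cycle
  out <- vector("list", n_strides)
  for (s in seq_len(n_strides)) {
    dur <- base_dur * max(1 + if (cv > 0) rnorm(1, 0, cv) else 0, 0.3)
    n <- max(round(dur * fs), 4L)
    t01 <- seq(0, 1, length.out = n)  # normalized gait-cycle time

    load_c <- ph["load"] / 2
    push_c <- ph["load"] + ph["foot_flat"] + ph["push"] / 2
    swing_c <- 1 - ph["swing"] / 2

    bump <- function(center, width, amp) amp * exp(-((t01 - center)^2) / (2 * width^2))

    # accelerations scale with cycle frequency squared (a ~ omega^2 * amplitude),
    # angular rate with cycle frequency; the heel-strike impact transient has a
    # fixed real-time width, so its percent-cycle width shrinks as cadence rises
    omega <- cadence / 50
    impact_w <- 0.055 / dur
    t_hs <- pmax(t01 - load_c, 0) * dur  # seconds since heel strike
    ringing <- 2.5 * speed * omega^2 *
      exp(-t_hs / 0.08) * sin(2 * pi * 7 * t_hs) * (t01 > load_c)

    acc_z <- bump(load_c, impact_w, 8 * speed * omega^2) + ringing -
      bump(load_c + ph["load"], 0.03, 2 * speed * omega^2) +
      bump(swing_c, ph["swing"] / 5, 30 * clear * omega^2)
    acc_y <- bump(push_c, ph["push"] / 4, 6 * speed * omega^2) -
      bump(load_c, impact_w, 3 * speed * omega^2)
    gyro_x <- bump(swing_c, ph["swing"] / 4, (250 * clear + 60 * speed) * omega) -
      bump(push_c + ph["push"] / 2, 0.04, 80 * speed * omega)

    if (noise_sd > 0) {
      acc_y <- acc_y + rnorm(n, 0, noise_sd)
      acc_z <- acc_z + rnorm(n, 0, noise_sd)
      gyro_x <- gyro_x + rnorm(n, 0, noise_sd * 8)
    }
    len_s <- if (cv > 0) max(slen * (1 + rnorm(1, 0, cv)), 0.01) else slen
    cl_s <- if (cv > 0) max(clear * (1 + rnorm(1, 0, 0.5 * cv)), 0.005) else clear
    out[[s]] <- stride_waveform(NA_character_, acc_y, acc_z, gyro_x,
                                duration_s = n / fs, stride_length = len_s,
                                clearance = cl_s)
  }
  out
}

# Table-1-style parameter derivation from the generated strides
derive_subject_record <- function(id, a, eff, st) {
  dur <- vapply(st, `[[`, 0, "duration_s")
  len <- vapply(st, `[[`, 0, "stride_length")
  cl <- vapply(st, `[[`, 0, "clearance")
  ph <- eff$phase_fractions
  speed <- mean(len / dur)
  data.frame(
    id = id,
    age = round(eff$age, 1),
    height = round(eff$height, 2),
    cadence = 60 / mean(dur),
    step_speed = speed,
    stride_length = mean(len),
    clearance = mean(cl),
    total_distance = sum(len),
    total_time = sum(dur),
    total_strides = length(st),
    swing_pct = 100 * ph["swing"],
    load_pct = 100 * ph["load"],
    foot_flat_pct = 100 * ph["foot_flat"],
    push_pct = 100 * ph["push"],
    stride_time = mean(dur),
    toe_off_angle = 18 + 14 * speed + rnorm(1, 0, 2),
    heel_strike_angle = 8 + 10 * speed + rnorm(1, 0, 2),
    stride_time_std = sd(dur),
    stride_length_std = sd(len),
    clearance_std = sd(cl),
    path_3d = mean(len) * 1.05 + 2 * mean(cl),
    path_2d = mean(len) * 1.03,
    gds = eff$gds,
    frailty = eff$frailty,
    short_fes_i = eff$short_fes_i,
    sppb = eff$sppb,
    gait_speed_4m = eff$gait_speed_4m,
    tug_s = eff$tug_s,
    fell = NA_integer_,
    row.names = NULL
  )
}

#' Assign fall labels through each archetype's planted mechanism
#'
#' Within each phenotype group the fall probability is
#' `plogis(intercept + driver_coefficient * z)`, where `z` is the driver
#' feature standardized within the group and the intercept is calibrated (by
#' root finding) so the expected prevalence over the group equals the
#' archetype's `base_prevalence`. Labels are then drawn Bernoulli.
#'
#' Called by [generate_cohort()]; exposed for re-labelling a cohort under a
#' different mechanism. Uses R's global random number stream.
#'
#' @param cohort A `gait_cohort`.
#' @param archetypes The archetype list that generated it.
#' @return The cohort with `subjects$fell` filled in.
#' @export
assign_fall_labels <- function(cohort, archetypes) {
  subj <- cohort$subjects
  for (a in archetypes) {
    rows <- which(subj$true_phenotype == a$name)
    if (length(rows) == 0) next
    if (!a$fall_driver %in% names(subj)) {
      stop("unknown fall driver feature: ", a$fall_driver)
    }
    x <- subj[[a$fall_driver]][rows]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mu) / s
    z[is.na(z)] <- 0
    beta <- a$driver_coefficient
    target <- a$base_prevalence
    f <- function(c0) mean(plogis(c0 + beta * z)) - target
    c0 <- if (target <= 0) -Inf else if (target >= 1) Inf else {
      uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
    }
    p <- plogis(c0 + beta * z)
    subj$fell[rows] <- rbinom(length(rows), 1L, p)
  }
  cohort$subjects <- subj
  cohort
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects, %d phenotypes, seed %d\n",
              nrow(x$subjects), length(unique(x$subjects$true_phenotype)), x$seed))
  tab <- table(x$subjects$true_phenotype)
  for (nm in names(tab)) {
    rows <- x$subjects$true_phenotype == nm
    cat(sprintf("  %-13s n = %2d, fall prevalence %2.0f%%\n", nm, tab[[nm]],
                100 * mean(x$subjects$fell[rows], na.rm = TRUE)))
  }
  cat(sprintf("  strides/subject: %d-%d at %g Hz\n",
              min(lengths(x$strides)), max(lengths(x$strides)),
              x$signal$sampling_rate_hz))
  invisible(x)
}
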