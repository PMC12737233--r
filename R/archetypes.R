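# Phenotype archetypes: the latent gait profiles the synthetic cohort plants.

#' Construct a phenotype archetype
#'
#' An archetype is the latent profile a synthetic subject is drawn from: mean
#' gait parameters, gait-cycle phase composition, clinical score means, the
#' within-phenotype standard deviations, and the phenotype's fall mechanism
#' (driver feature, logistic slope per standard deviation, and target fall
#' prevalence).
#'
#' @param name Archetype label.
#' @param cadence_mean Strides per minute (stride cadence; one stride = one
#'   full gait cycle of one foot).
#' @param step_speed_mean Walking speed in m/s.
#' @param stride_length_mean Stride length in m.
#' @param clearance_mean Maximum swing-phase foot elevation in m.
#' @param phase_fractions Named numeric of gait-cycle proportions
#'   `c(load, foot_flat, push, swing)`; must sum to 1.
#' @param clinical_means Named numeric of clinical score means; must contain
#'   `gds`, `frailty`, `short_fes_i`, `sppb`, `gait_speed_4m`, `tug_s`.
#' @param age_mean,height_mean Demographic means (years, m).
#' @param within_phenotype_sd Named numeric of within-phenotype SDs for any of
#'   the generated features (missing entries fall back to defaults).
#' @param stride_time_cv Coefficient of variation of stride duration across a
#'   subject's strides (drives stride-time variability).
#' @param fall_driver Feature name whose standardized value drives the fall
#'   probability within this phenotype.
#' @param driver_coefficient Signed logistic slope per within-phenotype SD of
#'   the driver.
#' @param base_prevalence Target 12-month fall prevalence, in `[0, 1]`.
#'
#' @return An object of class `gait_archetype`.
#' @seealso [default_archetypes()]
#' @export
gait_archetype <- function(name,
                           cadence_mean, step_speed_mean, stride_length_mean,
                           clearance_mean, phase_fractions, clinical_means,
                           age_mean = 82.6, height_mean = 1.60,
                           within_phenotype_sd = numeric(),
                           stride_time_cv = 0.05,
                           fall_driver = "gait_speed_4m",
                           driver_coefficient = -1,
                           base_prevalence = 0.4) {
  phases <- c("load", "foot_flat", "push", "swing")
  if (!all(phases %in% names(phase_fractions))) {
    stop("`phase_fractions` must be named with: ", paste(phases, collapse = ", "))
  }
  phase_fractions <- phase_fractions[phases]
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    stop("phase fractions must sum to 1 (got ", sum(phase_fractions), ")")
  }
  need <- c("gds", "frailty", "short_fes_i", "sppb", "gait_speed_4m", "tug_s")
  if (!all(need %in% names(clinical_means))) {
    stop("`clinical_means` must contain: ", paste(need, collapse = ", "))
  }
  if (cadence_mean <= 0) stop("cadence must be positive")
  if (any(within_phenotype_sd < 0)) stop("SDs must be nonnegative")
  if (base_prevalence < 0 || base_prevalence > 1) {
    stop("base_prevalence must lie in [0, 1]")
  }
  sd_full <- default_feature_sd()
  sd_full[names(within_phenotype_sd)] <- within_phenotype_sd
  structure(
    list(
      name = name,
      cadence_mean = cadence_mean,
      step_speed_mean = step_speed_mean,
      stride_length_mean = stride_length_mean,
      clearance_mean = clearance_mean,
      phase_fractions = phase_fractions,
      clinical_means = clinical_means[need],
      age_mean = age_mean,
      height_mean = height_mean,
      within_phenotype_sd = sd_full,
      stride_time_cv = stride_time_cv,
      fall_driver = fall_driver,
      driver_coefficient = driver_coefficient,
      base_prevalence = base_prevalence
    ),
    class = "gait_archetype"
  )
}

# baseline within-phenotype SDs for every generated feature
default_feature_sd <- function() {
  c(
    cadence = 5.5, step_speed = 0.25, stride_length = 0.21, clearance = 0.03,
    load = 0.012, foot_flat = 0.02, push = 0.012, swing = 0.015,
    gds = 1.1, frailty = 1.0, short_fes_i = 4.6, sppb = 2.4,
    gait_speed_4m = 0.25, tug_s = 6.0, age = 6.2, height = 0.07
  )
}

#' Default phenotype archetypes
#'
#' Four archetypes spanning the functional spectrum observed in community
#' cohorts of older adults: a high-cadence compensator, a frail cautious
#' walker, an intermediate group with a propulsion (push-phase) deficit, and a
#' robust group whose residual fall risk is psychological (fear of falling).
#' Mean gait and clinical parameters sit in the numeric range reported for
#' foot-worn-IMU cohorts of community-dwelling older adults; each archetype
#' carries a distinct fall mechanism: fear of falling (Short FES-I) in the
#' high-functioning archetypes, 4 m gait speed in the frail archetype, and the
#' push-phase share in the intermediate archetype.
#'
#' @param separation Scalar multiplier on between-archetype differences.
#'   Every archetype mean is moved along `grand_mean + separation * (mean -
#'   grand_mean)`; 0 collapses all archetypes onto their common mean
#'   (phenotypes unrecoverable by construction), 1 keeps the defaults, values
#'   above 1 exaggerate the contrast.
#'
#' @return List of four `gait_archetype` objects.
#' @export
default_archetypes <- function(separation = 1) {
  arch <- list(
    gait_archetype(
      name = "high_cadence",
      cadence_mean = 53.7, step_speed_mean = 0.84, stride_length_mean = 0.87,
      clearance_mean = 0.16,
      phase_fractions = c(load = 0.11, foot_flat = 0.42, push = 0.15, swing = 0.32),
      clinical_means = c(gds = 3.2, frailty = 2.0, short_fes_i = 11.2,
                         sppb = 8.49, gait_speed_4m = 0.85, tug_s = 15.9),
      age_mean = 82.5, height_mean = 1.58,
      within_phenotype_sd = c(cadence = 4.55, step_speed = 0.24,
                              stride_length = 0.23, sppb = 2.43,
                              short_fes_i = 4.57, tug_s = 5.58),
      stride_time_cv = 0.045,
      fall_driver = "short_fes_i", driver_coefficient = 2.0,
      base_prevalence = 0.56
    ),
    gait_archetype(
      name = "cautious",
      cadence_mean = 46.5, step_speed_mean = 0.67, stride_length_mean = 0.78,
      clearance_mean = 0.12,
      phase_fractions = c(load = 0.14, foot_flat = 0.48, push = 0.12, swing = 0.26),
      clinical_means = c(gds = 4.0, frailty = 3.2, short_fes_i = 11.4,
                         sppb = 7.00, gait_speed_4m = 0.67, tug_s = 19.8),
      age_mean = 85.0, height_mean = 1.55,
      within_phenotype_sd = c(cadence = 5.86, step_speed = 0.22,
                              stride_length = 0.19, sppb = 3.14,
                              short_fes_i = 6.17, tug_s = 9.84),
      stride_time_cv = 0.09,
      fall_driver = "gait_speed_4m", driver_coefficient = -2.5,
      base_prevalence = 0.68
    ),
    gait_archetype(
      name = "intermediate",
      cadence_mean = 48.3, step_speed_mean = 0.85, stride_length_mean = 0.95,
      clearance_mean = 0.15,
      phase_fractions = c(load = 0.11, foot_flat = 0.44, push = 0.15, swing = 0.30),
      clinical_means = c(gds = 3.0, frailty = 1.8, short_fes_i = 9.86,
                         sppb = 9.15, gait_speed_4m = 0.87, tug_s = 13.0),
      age_mean = 82.0, height_mean = 1.60,
      within_phenotype_sd = c(cadence = 6.34, step_speed = 0.28,
                              stride_length = 0.25, sppb = 2.23,
                              short_fes_i = 3.99, tug_s = 5.04),
      stride_time_cv = 0.055,
      fall_driver = "push_pct", driver_coefficient = -2.0,
      base_prevalence = 0.48
    ),
    gait_archetype(
      name = "robust",
      cadence_mean = 51.9, step_speed_mean = 1.10, stride_length_mean = 1.14,
      clearance_mean = 0.19,
      phase_fractions = c(load = 0.09, foot_flat = 0.40, push = 0.17, swing = 0.34),
      clinical_means = c(gds = 2.5, frailty = 1.0, short_fes_i = 9.58,
                         sppb = 10.1, gait_speed_4m = 1.05, tug_s = 11.1),
      age_mean = 80.0, height_mean = 1.63,
      within_phenotype_sd = c(cadence = 6.06, step_speed = 0.31,
                              stride_length = 0.22, sppb = 1.85,
                              short_fes_i = 4.01, tug_s = 4.19),
      stride_time_cv = 0.05,
      fall_driver = "short_fes_i", driver_coefficient = 2.0,
      base_prevalence = 0.27
    )
  )
  apply_separation(arch, separation)
}

# move every archetype mean along grand_mean + s * (mean - grand_mean)
apply_separation <- function(archetypes, separation) {
  if (separation == 1) return(archetypes)
  if (separation < 0) stop("separation must be nonnegative")
  blend <- function(get, set) {
    vals <- do.call(rbind, lapply(archetypes, get))
    gm <- colMeans(vals)
    for (i in seq_along(archetypes)) {
      v <- gm + separation * (vals[i, ] - gm)
      archetypes[[i]] <<- set(archetypes[[i]], v)
    }
  }
  blend(function(a) c(a$cadence_mean, a$step_speed_mean, a$stride_length_mean,
                      a$clearance_mean, a$age_mean, a$height_mean),
        function(a, v) {
          a$cadence_mean <- max(v[1], 1)
          a$step_speed_mean <- max(v[2], 0.05)
          a$stride_length_mean <- max(v[3], 0.05)
          a$clearance_mean <- max(v[4], 0.01)
          a$age_mean <- v[5]; a$height_mean <- max(v[6], 1)
          a
        })
  blend(function(a) a$phase_fractions,
        function(a, v) {
          v <- pmax(v, 0.02)
          a$phase_fractions <- v / sum(v)
          a
        })
  blend(function(a) a$clinical_means,
        function(a, v) {
          a$clinical_means <- pmax(v, 0)
          a
        })
  archetypes
}

#' @export
print.gait_archetype <- function(x, ...) {
  cat(sprintf("<gait_archetype> %s\n", x$name))
  cat(sprintf("  cadence %.1f strides/min, speed %.2f m/s, stride %.2f m, clearance %.2f m\n",
              x$cadence_mean, x$step_speed_mean, x$stride_length_mean, x$clearance_mean))
  cat(sprintf("  phases (load/flat/push/swing): %s\n",
              paste(sprintf("%.0f%%", 100 * x$phase_fractions), collapse = "/")))
  cat(sprintf("  fall driver: %s (slope %+.1f), target prevalence %.0f%%\n",
              x$fall_driver, x$driver_coefficient, 100 * x$base_prevalence))
  invisible(x)
}
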