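# Cohort readers and writers: wide subject-feature CSV plus per-subject raw
# sample and stride-event CSVs.

mandatory_columns <- function() c("id", "age", "height", gait_feature_names(), "fell")

#' Write a cohort in the on-disk layout the readers consume
#'
#' `subjects.csv` holds the wide per-subject feature table (plus, for
#' synthetic cohorts, the `true_phenotype` column); `raw/<id>.csv` holds one
#' subject's concatenated samples (`time_s`, `acc_y`, `acc_z`, `gyro_x`) and
#' `raw/<id>_events.csv` the stride-event table (1-based `stride_start_idx`,
#' `foot_flat_idx`).
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if needed).
#' @param raw Also write the per-subject raw signals? (default TRUE)
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, raw = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  if (raw) {
    rawdir <- file.path(dir, "raw")
    dir.create(rawdir, showWarnings = FALSE)
    fs <- cohort$signal$sampling_rate_hz
    for (id in names(cohort$strides)) {
      strides <- cohort$strides[[id]]
      lens <- vapply(strides, `[[`, 0L, "n_samples")
      starts <- cumsum(c(1L, lens[-length(lens)]))
      samples <- data.frame(
        time_s = (seq_len(sum(lens)) - 1L) / fs,
        acc_y = unlist(lapply(strides, `[[`, "acc_y")),
        acc_z = unlist(lapply(strides, `[[`, "acc_z")),
        gyro_x = unlist(lapply(strides, `[[`, "gyro_x"))
      )
      # foot-flat onset approximated at the end of the load phase
      load_frac <- cohort$subjects$load_pct[cohort$subjects$id == id] / 100
      events <- data.frame(
        stride_start_idx = starts,
        foot_flat_idx = starts + pmax(round(lens * load_frac), 1L)
      )
      write.csv(samples, file.path(rawdir, paste0(id, ".csv")), row.names = FALSE)
      write.csv(events, file.path(rawdir, paste0(id, "_events.csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read cohort tables from disk
#'
#' Reads the wide subject-feature table and, when present, the per-subject
#' raw signal and stride-event files, re-segmenting the strides. Performs
#' name-based parsing (column order is irrelevant), validates mandatory
#' columns and duplicate ids, and raises unit sanity warnings (TUG expected
#' in seconds, gait speed in m/s).
#'
#' @param dir Directory written by [write_cohort()] (or a path to a single
#'   subjects CSV file).
#' @return A `gait_cohort`-like list with `subjects`, `strides` (empty when
#'   no raw files are present) and `true_phenotype` (when the column
#'   exists).
#' @export
read_cohort_tables <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "subjects.csv") else dir
  if (!file.exists(path)) stop("subject table not found: ", path)
  subjects <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(mandatory_columns(), names(subjects))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(subjects$id)) {
    stop("duplicate subject id(s): ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  }
  if (median(subjects$tug_s, na.rm = TRUE) < 1) {
    warning("TUG values look too small for seconds; check units (minutes?)")
  }
  if (median(subjects$gait_speed_4m, na.rm = TRUE) > 4) {
    warning("4 m gait speed values look too large for m/s; check units")
  }
  strides <- list()
  rawdir <- if (dir.exists(dir)) file.path(dir, "raw") else ""
  if (nzchar(rawdir) && dir.exists(rawdir)) {
    for (id in subjects$id) {
      f <- file.path(rawdir, paste0(id, ".csv"))
      fe <- file.path(rawdir, paste0(id, "_events.csv"))
      if (file.exists(f) && file.exists(fe)) {
        rec <- read.csv(f)
        ev <- read.csv(fe)
        st <- suppressMessages(
          segment_strides(rec, ev$stride_start_idx, subject_id = id))
        # the recording ends at the last stride's end: recover the tail stride
        last <- ev$stride_start_idx[nrow(ev)]
        if (nrow(rec) - last + 1L >= 2L) {
          idx <- last:nrow(rec)
          st[[length(st) + 1L]] <- stride_waveform(id, rec$acc_y[idx],
                                                   rec$acc_z[idx], rec$gyro_x[idx])
        }
        strides[[id]] <- st
      }
    }
  }
  out <- list(subjects = subjects, strides = strides)
  if ("true_phenotype" %in% names(subjects)) {
    out$true_phenotype <- setNames(subjects$true_phenotype, subjects$id)
  }
  out
}
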