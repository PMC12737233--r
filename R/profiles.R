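# Per-phenotype profiles and within-phenotype faller vs non-faller contrasts.

#' Faller vs non-faller contrast for one variable
#'
#' Two-group Kruskal-Wallis test (rank-based, so invariant to monotone
#' transforms of the values) with fall history as the grouping axis. P-values
#' are reported uncorrected; see [cluster_summary()] for the optional FDR
#' switch.
#'
#' @param values Numeric variable.
#' @param fall_labels 0/1 fall history.
#' @return List with `p_value`, `statistic` and `direction` (sign of
#'   faller-minus-non-faller mean difference); all `NA` when either group is
#'   empty.
#' @export
faller_contrast <- function(values, fall_labels) {
  keep <- is.finite(values) & !is.na(fall_labels)
  values <- values[keep]; fall_labels <- fall_labels[keep]
  if (length(unique(fall_labels)) < 2) {
    return(list(p_value = NA_real_, statistic = NA_real_, direction = NA_real_))
  }
  kt <- kruskal.test(values, factor(fall_labels))
  dir <- sign(mean(values[fall_labels == 1]) - mean(values[fall_labels == 0]))
  list(p_value = kt$p.value, statistic = unname(kt$statistic), direction = dir)
}

#' Summarize clusters and contrast fallers within each
#'
#' For every cluster: size, fall prevalence (integer percent), and per
#' variable the mean and SD for all members, fallers and non-fallers, plus
#' the within-cluster faller contrast p-value.
#'
#' @param subjects Subject feature data frame with a `fell` column.
#' @param labels Cluster labels (one per subject).
#' @param variables Variables to summarize (default: the 25 gait/clinical
#'   features).
#' @param p_adjust Multiple-testing correction applied per cluster across
#'   variables; `"none"` (default, per-variable alpha as reported) or any
#'   [stats::p.adjust] method.
#' @return An object of class `cluster_profiles`: list of per-cluster
#'   profiles plus a long-format `table` data frame.
#' @export
cluster_summary <- function(subjects, labels, variables = gait_feature_names(),
                            p_adjust = "none") {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(subjects))
  profiles <- list()
  rows <- list()
  for (cl in sort(unique(labels))) {
    idx <- labels == cl
    if (!any(idx)) stop("empty cluster ", cl)
    sub <- subjects[idx, , drop = FALSE]
    fell <- sub$fell
    n <- nrow(sub)
    n_f <- sum(fell == 1, na.rm = TRUE)
    prevalence <- round(100 * n_f / n)
    var_rows <- lapply(variables, function(v) {
      x <- sub[[v]]
      ct <- faller_contrast(x, fell)
      data.frame(
        cluster = cl, variable = v, n = n,
        mean_all = mean(x, na.rm = TRUE), sd_all = sd(x, na.rm = TRUE),
        mean_nonfaller = mean(x[fell == 0], na.rm = TRUE),
        sd_nonfaller = sd(x[fell == 0], na.rm = TRUE),
        mean_faller = mean(x[fell == 1], na.rm = TRUE),
        sd_faller = sd(x[fell == 1], na.rm = TRUE),
        p_value = ct$p_value, direction = ct$direction
      )
    })
    tab <- do.call(rbind, var_rows)
    tab$p_value <- p.adjust(tab$p_value, method = p_adjust)
    tab$significant <- !is.na(tab$p_value) & tab$p_value < 0.05
    profiles[[as.character(cl)]] <- list(
      cluster = cl, n = n, n_fallers = n_f, n_nonfallers = n - n_f,
      fall_prevalence = prevalence, table = tab
    )
    rows[[as.character(cl)]] <- tab
  }
  structure(list(profiles = profiles, table = do.call(rbind, rows)),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("<cluster_profiles>\n")
  for (p in x$profiles) {
    cat(sprintf("  cluster %d: n = %d, fall prevalence %d%% (%d F / %d NF), %d/%d variables p < 0.05\n",
                p$cluster, p$n, p$fall_prevalence, p$n_fallers, p$n_nonfallers,
                sum(p$table$significant, na.rm = TRUE), nrow(p$table)))
  }
  invisible(x)
}
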