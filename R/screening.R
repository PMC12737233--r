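# Per-phenotype TUG screening: Youden-optimal cutoff and comparison against
# the conventional 13.50 s standard. Cutoffs derived here are exploratory
# reference values, not definitive clinical thresholds.

#' Youden-optimal TUG cutoff
#'
#' Scans candidate thresholds — midpoints between consecutive distinct sorted
#' TUG values, plus a below-minimum and an above-maximum sentinel — under the
#' decision rule "predict faller iff TUG >= cutoff", and returns the cutoff
#' maximizing the Youden index `J = sensitivity + specificity - 1`. Ties in
#' `J` break toward higher sensitivity (screening favours not missing
#' fallers), then toward the lower cutoff.
#'
#' @param tug TUG times in seconds (all positive).
#' @param fell 0/1 fall history; both classes must be present.
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `J` (per threshold), `chosen_cutoff`, and
#'   the sensitivity/specificity/J attained at it.
#' @export
youden_threshold <- function(tug, fell) {
  keep <- is.finite(tug) & !is.na(fell)
  tug <- tug[keep]; fell <- as.integer(fell[keep])
  if (any(tug <= 0)) stop("TUG times must be positive")
  if (length(unique(fell)) < 2) stop("both fallers and non-fallers are required")
  v <- sort(unique(tug))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  n_pos <- sum(fell == 1); n_neg <- sum(fell == 0)
  sens <- vapply(cand, function(ct) sum(tug >= ct & fell == 1) / n_pos, 0)
  spec <- vapply(cand, function(ct) sum(tug < ct & fell == 0) / n_neg, 0)
  J <- sens + spec - 1
  ord <- order(-J, -sens, cand)
  best <- ord[1]
  structure(list(thresholds = cand, sensitivity = sens, specificity = spec,
                 J = J, chosen_cutoff = cand[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best],
                 J_at_cutoff = J[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> cutoff %.2f s: sensitivity %.2f, specificity %.2f, J %.2f\n",
              x$chosen_cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff,
              x$J_at_cutoff))
  invisible(x)
}

#' Screening metrics at a customized vs the conventional cutoff
#'
#' Confusion-matrix metrics (precision, recall, F1, accuracy) under the
#' "TUG >= cutoff" rule for both the phenotype-customized cutoff and the
#' conventional fixed standard (13.50 s).
#'
#' @param tug TUG times in seconds.
#' @param fell 0/1 fall history.
#' @param custom_cutoff Customized cutoff in seconds (e.g. from
#'   [youden_threshold()]).
#' @param fixed_cutoff Conventional cutoff (default 13.50 s).
#' @return An object of class `screening_comparison`: data frame with one row
#'   per cutoff and columns `cutoff`, `precision`, `recall`, `f1`,
#'   `accuracy`.
#' @export
screening_report <- function(tug, fell, custom_cutoff, fixed_cutoff = 13.50) {
  if (custom_cutoff <= 0 || fixed_cutoff <= 0) stop("cutoffs must be positive")
  keep <- is.finite(tug) & !is.na(fell)
  tug <- tug[keep]; fell <- as.integer(fell[keep])
  one <- function(ct, label) {
    m <- confusion_metrics(confusion_counts(fell, as.integer(tug >= ct)))
    data.frame(rule = label, cutoff = round(ct, 2),
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], accuracy = m[["accuracy"]])
  }
  out <- rbind(one(fixed_cutoff, "fixed"), one(custom_cutoff, "customized"))
  rownames(out) <- NULL
  structure(out, class = c("screening_comparison", "data.frame"))
}
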