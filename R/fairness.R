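#' Per-group confusion counts and rates
#'
#' Exact integer confusion counts and the derived rates for each level of
#' a binary protected attribute. Group 0 is labelled "female" and group 1
#' "male", matching the cohort encoding. A group with no true positives
#' has an undefined TPR, flagged as NA (never silently 0); the
#' disparity functions below turn that into an explicit error.
#'
#' @param y_true 0/1 vector of observed outcomes.
#' @param y_pred 0/1 vector of predicted classes.
#' @param group 0/1 vector of the protected attribute (0 = female,
#'   1 = male).
#' @return A \code{group_metrics} data.frame with one row per group:
#'   group, n, TP, FP, TN, FN, selection_rate, TPR, FPR.
#' @export
group_confusion <- function(y_true, y_pred, group) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(group),
            all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)),
            all(group %in% c(0, 1)))
  rows <- lapply(sort(unique(group)), function(g) {
    yt <- y_true[group == g]; yp <- y_pred[group == g]
    tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
    tn <- sum(yt == 0 & yp == 0); fn <- sum(yt == 1 & yp == 0)
    data.frame(group = if (g == 0) "female" else "male",
               n = length(yt), TP = tp, FP = fp, TN = tn, FN = fn,
               selection_rate = (tp + fp) / length(yt),
               TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("group_metrics", "data.frame"))
}

metric_by_group <- function(metrics, metric) {
  for (g in c("female", "male")) {
    if (!g %in% metrics$group) stop(sprintf("group '%s' is missing", g))
  }
  stats::setNames(metrics[[metric]], metrics$group)
}

#' Demographic parity difference (female minus male)
#'
#' Difference in selection rates between the female and male groups.
#' Positive values mean female patients are flagged high-risk more often.
#'
#' @param y_true,y_pred,group as in \code{\link{group_confusion}}; or pass
#'   a precomputed \code{group_metrics} as the only argument.
#' @return DPD in [-1, 1].
#' @export
demographic_parity_difference <- function(y_true, y_pred = NULL, group = NULL) {
  m <- if (inherits(y_true, "group_metrics")) y_true
       else group_confusion(y_true, y_pred, group)
  s <- metric_by_group(m, "selection_rate")
  unname(s["female"] - s["male"])
}

#' Equal opportunity difference (female minus male)
#'
#' Difference in true positive rates between the female and male groups.
#' Errors if either group has no true positives (TPR undefined).
#'
#' @inheritParams demographic_parity_difference
#' @return EOD in [-1, 1].
#' @export
equal_opportunity_difference <- function(y_true, y_pred = NULL, group = NULL) {
  m <- if (inherits(y_true, "group_metrics")) y_true
       else group_confusion(y_true, y_pred, group)
  tpr <- metric_by_group(m, "TPR")
  if (any(is.na(tpr))) {
    stop("EOD undefined: a group has no true positives (undefined TPR)")
  }
  unname(tpr["female"] - tpr["male"])
}

#' Group-fairness report at a classification threshold
#'
#' Thresholds predicted probabilities (class 1 iff p >= threshold),
#' computes per-group confusion rates, and the two headline disparities
#' DPD and EOD with the fixed female-minus-male sign convention.
#'
#' @param y_true 0/1 observed outcomes.
#' @param prob predicted probabilities (or already-thresholded 0/1
#'   classes, with \code{threshold} then only recorded).
#' @param group 0/1 protected attribute (0 = female, 1 = male).
#' @param threshold classification threshold (default 0.5; ties go to the
#'   positive class).
#' @return A \code{fairness_report}: group metrics, DPD, EOD (NA with a
#'   reason if undefined), threshold, n.
#' @export
fairness_report <- function(y_true, prob, group, threshold = 0.5) {
  y_pred <- as.integer(prob >= threshold)
  m <- group_confusion(y_true, y_pred, group)
  dpd <- demographic_parity_difference(m)
  eod <- tryCatch(equal_opportunity_difference(m), error = function(e) NA_real_)
  structure(list(groups = m, DPD = dpd, EOD = eod,
                 eod_defined = !is.na(eod),
                 threshold = threshold, n = length(y_true)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("Fairness report (n = %d, threshold %.2f)\n", x$n, x$threshold))
  print(transform(x$groups,
                  selection_rate = round(selection_rate, 3),
                  TPR = round(TPR, 3), FPR = round(FPR, 3)))
  cat(sprintf("  DPD (female - male): %+.3f\n", x$DPD))
  if (x$eod_defined) cat(sprintf("  EOD (female - male): %+.3f\n", x$EOD))
  else cat("  EOD: undefined (a group has no true positives)\n")
  invisible(x)
}

#' Convert a fairness report to plain lists for JSON embedding
#' @param x a \code{fairness_report}.
#' @return nested list mirroring the report.
#' @export
as_afpr_block <- function(x) UseMethod("as_afpr_block")

#' @export
as_afpr_block.fairness_report <- function(x) {
  groups <- lapply(seq_len(nrow(x$groups)), function(i) {
    r <- x$groups[i, ]
    list(group = r$group, n = r$n, TP = r$TP, FP = r$FP, TN = r$TN,
         FN = r$FN, selection_rate = r$selection_rate,
         TPR = if (is.na(r$TPR)) NULL else r$TPR,
         FPR = if (is.na(r$FPR)) NULL else r$FPR)
  })
  list(kind = "fairness_report", n = x$n, threshold = x$threshold,
       groups = groups, DPD = x$DPD,
       EOD = if (x$eod_defined) x$EOD else NULL)
}
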