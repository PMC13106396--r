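#' Area under the ROC curve
#'
#' Thin wrapper over \pkg{pROC} with the orientation fixed so that higher
#' scores for positives give AUC > 0.5.
#'
#' @param y_true 0/1 outcomes.
#' @param score predicted probabilities or scores.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(y_true, score) {
  as.numeric(pROC::auc(pROC::roc(response = y_true, predictor = as.numeric(score),
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Permutation significance test for the equal opportunity difference
#'
#' Tests gender-label exchangeability: the gender vector is permuted
#' uniformly at random N times with predictions and true labels fixed,
#' |EOD| is recomputed under each permutation, and the p-value is the
#' add-one estimator (k + 1) / (N + 1) where k counts permutations with
#' |EOD| >= the observed value. Permutations under which EOD is undefined
#' (a group draws zero true positives) are counted as exceedances, a
#' conservative choice.
#'
#' @param y_true,y_pred,group as in \code{\link{group_confusion}}.
#' @param n_perm number of permutations N (default 1000).
#' @param seed integer seed for the permutation substream.
#' @return A \code{permutation_result}: observed |EOD|, N, exceedance
#'   count, p_value, significance label, seed.
#' @export
permutation_test_eod <- function(y_true, y_pred, group, n_perm = 1000L,
                                 seed = 42L) {
  observed <- abs(equal_opportunity_difference(y_true, y_pred, group))
  pos <- which(y_true == 1)
  tp <- y_pred[pos] # among true positives, prediction = 1 counts toward TPR
  exceed <- with_seed(as.integer(seed %% .Machine$integer.max), {
    sum(vapply(seq_len(n_perm), function(i) {
      g <- sample(group) # uniform random permutation of the group vector
      gp <- g[pos]
      n_f <- sum(gp == 0); n_m <- sum(gp == 1)
      if (n_f == 0 || n_m == 0) return(TRUE) # undefined EOD: conservative
      abs(sum(tp[gp == 0]) / n_f - sum(tp[gp == 1]) / n_m) >= observed
    }, logical(1)))
  })
  p <- (exceed + 1) / (n_perm + 1)
  structure(list(observed_abs_eod = observed, n_permutations = as.integer(n_perm),
                 exceedances = as.integer(exceed), p_value = p,
                 label = significance_label(p),
                 seed = as.integer(seed %% .Machine$integer.max)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test of |EOD| (N = %d): observed %.4f, p = %.4f %s\n",
              x$n_permutations, x$observed_abs_eod, x$p_value, x$label))
  invisible(x)
}

#' Significance label for a p-value
#'
#' Strict-inequality banding: "***" for p < 0.001, "**" for p < 0.01,
#' "*" for p < 0.05, otherwise "ns".
#'
#' @param p p-value in (0, 1].
#' @return A character label.
#' @examples
#' significance_label(0.0080) # "**"
#' significance_label(0.05)   # "ns"
#' @export
significance_label <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Cross-validated performance and fairness audit
#'
#' Outcome-stratified k-fold cross-validation of one model family on a
#' cohort. Each fold is held out once; the model is fit on the remaining
#' folds and accuracy, ROC-AUC, DPD and EOD are evaluated on the held-out
#' fold at threshold 0.5. Summaries are mean, sample SD and the t-based
#' 95% confidence interval mean +/- t(0.975, df = k - 1) * SD / sqrt(k).
#' Folds whose held-out part lacks an outcome class, a gender group, or a
#' true positive in either gender are flagged and excluded from the
#' fairness summaries (df adjusts), with a warning.
#'
#' @param cohort a \code{cohort} (or data.frame with the model columns).
#' @param model "logistic" or "forest".
#' @param k number of folds (default 5).
#' @param seed master seed; fold assignment and forest fits use
#'   substreams.
#' @param features,outcome model columns.
#' @param ... passed to the fitting function.
#' @return A \code{cv_result}: per-fold metrics, per-metric mean, SD and
#'   CI bounds, the t critical value used, k, seed.
#' @export
cv_audit <- function(cohort, model = c("logistic", "forest"), k = 5L,
                     seed = 42L,
                     features = c("age_std", "bmi_std", "comorbidity", "gender"),
                     outcome = "outcome", ...) {
  model <- match.arg(model)
  y <- cohort[[outcome]]
  folds <- make_stratified_folds(y, k, substream_seed(seed, "cv_folds"))
  per <- data.frame(fold = seq_len(k), accuracy = NA_real_, auc = NA_real_,
                    dpd = NA_real_, eod = NA_real_, flagged = FALSE)
  for (f in seq_len(k)) {
    tr <- cohort[folds != f, , drop = FALSE]
    te <- cohort[folds == f, , drop = FALSE]
    fit <- if (model == "logistic") {
      fit_logistic(tr, features = features, outcome = outcome, ...)
    } else {
      fit_forest(tr, features = features, outcome = outcome,
                 seed = substream_seed(seed, "cv_fit", f), ...)
    }
    prob <- predict(fit, te)
    pred <- as.integer(prob >= 0.5)
    per$accuracy[f] <- mean(pred == te[[outcome]])
    per$auc[f] <- if (length(unique(te[[outcome]])) < 2L) NA_real_
                  else auc_score(te[[outcome]], prob)
    ok <- length(unique(te[[outcome]])) == 2L &&
      all(c(0, 1) %in% te$gender) &&
      sum(te[[outcome]] == 1 & te$gender == 0) > 0 &&
      sum(te[[outcome]] == 1 & te$gender == 1) > 0
    if (ok) {
      per$dpd[f] <- demographic_parity_difference(te[[outcome]], pred, te$gender)
      per$eod[f] <- equal_opportunity_difference(te[[outcome]], pred, te$gender)
    } else {
      per$flagged[f] <- TRUE
      warning(sprintf("cv_audit: fold %d flagged (missing class, gender or true positive); excluded from fairness summaries", f))
    }
  }
  summ <- lapply(c(accuracy = "accuracy", auc = "auc", dpd = "dpd", eod = "eod"),
                 function(mcol) {
    v <- per[[mcol]][!is.na(per[[mcol]])]
    ci_t_summary(v)
  })
  structure(list(model = model, k = as.integer(k), folds = per,
                 summary = summ, t_crit = ci_t_summary(per$accuracy)$t_crit,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' t-based summary of fold-level values
#'
#' Mean, sample SD, and the 95% CI mean +/- t(0.975, df = n - 1) * SD /
#' sqrt(n), with the t critical value computed at runtime from the t
#' distribution (2.776 for df = 4).
#'
#' @param v numeric vector of fold values.
#' @return list(mean, sd, n, t_crit, ci_lower, ci_upper).
#' @export
ci_t_summary <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1) stats::sd(v) else NA_real_
  tc <- if (n > 1) stats::qt(0.975, df = n - 1) else NA_real_
  half <- if (n > 1) tc * s / sqrt(n) else NA_real_
  list(mean = m, sd = s, n = n, t_crit = tc,
       ci_lower = m - half, ci_upper = m + half)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV audit of the %s model (seed %d)\n",
              x$k, x$model, x$seed))
  for (mname in names(x$summary)) {
    s <- x$summary[[mname]]
    cat(sprintf("  %-8s %.3f +/- %.3f  [%.3f, %.3f] (t = %.3f, n = %d folds)\n",
                mname, s$mean, s$sd, s$ci_lower, s$ci_upper, s$t_crit, s$n))
  }
  if (any(x$folds$flagged)) {
    cat("  flagged folds:", paste(x$folds$fold[x$folds$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as_afpr_block.permutation_result <- function(x) {
  list(kind = "permutation_test", statistic = "abs_eod",
       observed = x$observed_abs_eod, n_permutations = x$n_permutations,
       exceedances = x$exceedances, p_value = x$p_value, label = x$label,
       seed = x$seed)
}

#' @export
as_afpr_block.cv_result <- function(x) {
  list(kind = "cv_audit", model = x$model, k = x$k, seed = x$seed,
       t_crit = x$t_crit,
       folds = lapply(seq_len(nrow(x$folds)), function(i) {
         r <- x$folds[i, ]
         list(fold = r$fold,
              accuracy = r$accuracy,
              auc = if (is.na(r$auc)) NULL else r$auc,
              dpd = if (is.na(r$dpd)) NULL else r$dpd,
              eod = if (is.na(r$eod)) NULL else r$eod,
              flagged = r$flagged)
       }),
       summary = lapply(x$summary, function(s) {
         s[vapply(s, function(v) !is.na(v), logical(1))]
       }))
}
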