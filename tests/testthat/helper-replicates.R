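# Replicate study: the single-split and cross-validated audit quantities
# recomputed over many master seeds, cached once per test session.
# Mirrors the protocol of the main experiment (n = 1000, 70/30 split,
# 5-fold CV, 1000 permutations, 18-candidate forest grid).

replicate_audit_metrics <- function(n_seeds = 50L, base_seed = 42L) {
  key <- sprintf("rep_%d_%d", n_seeds, base_seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- substream_seed(base_seed, "replicate", i)
    cohort <- generate_cohort(cohort_spec(seed = s))
    split <- stratified_split(cohort, 0.3, seed = substream_seed(s, "split"))
    tr <- cohort[cohort$patient_id %in% split$train_ids, ]
    te <- cohort[cohort$patient_id %in% split$test_ids, ]

    lr <- fit_logistic(tr)
    p_lr <- predict(lr, te)
    pred_lr <- as.integer(p_lr >= 0.5)
    fr_lr <- fairness_report(te$outcome, p_lr, te$gender)
    perm_lr <- permutation_test_eod(te$outcome, pred_lr, te$gender,
                                    seed = substream_seed(s, "perm_lr"))
    cf_lr <- gender_flip_audit(lr, te)
    lr_ng <- refit_without_feature(lr, tr, "gender")
    dpd_ng <- demographic_parity_difference(
      te$outcome, predict(lr_ng, te, type = "class"), te$gender)

    rf <- fit_forest(tr, seed = substream_seed(s, "forest"))
    p_rf <- predict(rf, te)
    pred_rf <- as.integer(p_rf >= 0.5)
    fr_rf <- fairness_report(te$outcome, p_rf, te$gender)
    perm_rf <- permutation_test_eod(te$outcome, pred_rf, te$gender,
                                    seed = substream_seed(s, "perm_rf"))

    cv_lr <- suppressWarnings(cv_audit(cohort, "logistic",
                                       seed = substream_seed(s, "cv_lr")))
    cv_rf <- suppressWarnings(cv_audit(cohort, "forest",
                                       seed = substream_seed(s, "cv_rf")))

    gs <- suppressWarnings(tune_forest(tr, seed = substream_seed(s, "tune")))
    sel <- gs$selected
    rf_t <- fit_forest(tr, n_trees = sel$n_trees,
                       max_depth = if (sel$max_depth == 0) NULL else sel$max_depth,
                       min_samples_split = sel$min_samples_split,
                       seed = substream_seed(s, "forest_tuned"))
    acc_t <- mean(predict(rf_t, te, type = "class") == te$outcome)

    data.frame(seed = s,
               lr_eod = fr_lr$EOD, lr_dpd = fr_lr$DPD,
               lr_p = perm_lr$p_value,
               lr_flip = cf_lr$flip_fraction,
               lr_dpd_no_gender = dpd_ng,
               lr_w_gender = unname(coef(lr)["gender"]),
               rf_eod = fr_rf$EOD, rf_p = perm_rf$p_value,
               rf_gender_importance = unname(coef(rf)["gender"]),
               lr_cv_acc = cv_lr$summary$accuracy$mean,
               lr_cv_auc = cv_lr$summary$auc$mean,
               rf_cv_acc = cv_rf$summary$accuracy$mean,
               rf_cv_auc = cv_rf$summary$auc$mean,
               tuned_acc = acc_t)
  })
  .fx[[key]] <- do.call(rbind, rows)
  .fx[[key]]
}
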