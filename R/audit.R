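#' Configuration for a full fairness audit run
#'
#' Validates every parameter up front; the whole config is serialized
#' into the resulting AFPR's data-provenance section.
#'
#' @param n cohort size.
#' @param seed master seed (default 42); every stochastic stage uses a
#'   named substream of it.
#' @param beta_gender injected gender log-odds.
#' @param model "logistic", "forest" or "both".
#' @param test_fraction held-out fraction for the single split.
#' @param cv_folds folds for the CV audit.
#' @param n_permutations permutation count for significance testing.
#' @param margin counterfactual boundary half-width.
#' @param sweep_grid beta grid for the sensitivity sweep, or NULL to skip.
#' @param tune run the forest grid search (default TRUE when the forest
#'   is audited).
#' @param log_inference which model's test-set predictions to hash-chain
#'   into the inference log: "logistic" (default; forest provenance
#'   entries are large), "both", or "none".
#' @param out_dir optional output directory for the AFPR JSON, Markdown
#'   report and CSV tables.
#' @return An \code{audit_config} list.
#' @export
audit_config <- function(n = 1000L, seed = 42L, beta_gender = -0.30,
                         model = c("both", "logistic", "forest"),
                         test_fraction = 0.3, cv_folds = 5L,
                         n_permutations = 1000L, margin = 0.15,
                         sweep_grid = c(-0.10, -0.20, -0.30, -0.50, -0.80),
                         tune = TRUE,
                         log_inference = c("logistic", "both", "none"),
                         out_dir = NULL) {
  model <- match.arg(model)
  log_inference <- match.arg(log_inference)
  stopifnot(n >= 10, test_fraction > 0, test_fraction < 1,
            cv_folds >= 2, n_permutations >= 1, margin >= 0,
            is.null(sweep_grid) || length(sweep_grid) >= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 beta_gender = beta_gender, model = model,
                 test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 n_permutations = as.integer(n_permutations), margin = margin,
                 sweep_grid = sweep_grid, tune = tune,
                 log_inference = log_inference, out_dir = out_dir),
            class = "audit_config")
}

audit_log <- function(stage, ...) {
  message(sprintf("[fairaudit] %s: %s", stage, sprintf(...)))
}

#' Run the complete provenance-based fairness audit
#'
#' End-to-end pipeline: generate the cohort, split it 70/30 stratified by
#' outcome, fit the audited models (with optional forest grid-search
#' tuning), compute single-split fairness metrics with permutation
#' significance, run the counterfactual gender-flip analysis, the k-fold
#' CV audit, the gender-excluded ablation and the bias-magnitude sweep,
#' then assemble everything into a validated, hash-chained AFPR document
#' and a Markdown report, with CSV tables of the headline results.
#'
#' @param config an \code{\link{audit_config}}.
#' @param clock timestamp source (inject a fixed clock for fully
#'   deterministic documents).
#' @return list(document, report, tables, models, results); when
#'   \code{config$out_dir} is set the AFPR JSON, report and tables are
#'   also written there.
#' @export
run_full_audit <- function(config = audit_config(), clock = afpr_clock()) {
  stopifnot(inherits(config, "audit_config"))
  seed <- config$seed
  audit_log("simulate", "generating cohort n = %d (seed %d, beta_gender %g)",
            config$n, seed, config$beta_gender)
  spec <- cohort_spec(n_patients = config$n, beta_gender = config$beta_gender,
                      seed = seed)
  cohort <- generate_cohort(spec)
  split <- stratified_split(cohort, config$test_fraction,
                            seed = substream_seed(seed, "split"))
  train <- cohort[cohort$patient_id %in% split$train_ids, ]
  test <- cohort[cohort$patient_id %in% split$test_ids, ]

  doc <- afpr_document(afpr_data_provenance(cohort), clock = clock)
  doc$data_provenance$run_config <- unclass(config)[setdiff(names(config), "out_dir")]

  use_lr <- config$model %in% c("both", "logistic")
  use_rf <- config$model %in% c("both", "forest")
  models <- list(); results <- list(); tables <- list()

  if (use_lr) {
    audit_log("fit", "logistic model on %d training patients", nrow(train))
    lr <- fit_logistic(train)
    models$logistic <- lr
    p_lr <- predict(lr, test)
    acc_lr <- mean((p_lr >= 0.5) == test$outcome)
    doc <- afpr_log_development(doc, lr$config,
      metrics = list(test_accuracy = acc_lr,
                     test_auc = auc_score(test$outcome, p_lr)),
      rationale = "transparent linear baseline; weights expose the gender pathway directly",
      clock = clock)
    results$fairness_logistic <- fairness_report(test$outcome, p_lr, test$gender)
    results$permutation_logistic <- permutation_test_eod(
      test$outcome, as.integer(p_lr >= 0.5), test$gender,
      n_perm = config$n_permutations,
      seed = substream_seed(seed, "permutation_lr"))
    results$counterfactual_logistic <- gender_flip_audit(lr, test,
                                                         margin = config$margin)
    audit_log("cv", "%d-fold CV audit of the logistic model", config$cv_folds)
    results$cv_logistic <- cv_audit(cohort, "logistic", k = config$cv_folds,
                                    seed = substream_seed(seed, "cv_lr"))
    audit_log("ablation", "refit logistic without gender")
    lr_ng <- refit_without_feature(lr, train, "gender")
    models$logistic_no_gender <- lr_ng
    results$fairness_logistic_no_gender <-
      fairness_report(test$outcome, predict(lr_ng, test), test$gender)
  }

  if (use_rf) {
    audit_log("fit", "random forest (100 trees) on %d training patients", nrow(train))
    rf <- fit_forest(train, seed = substream_seed(seed, "forest"))
    models$forest <- rf
    p_rf <- predict(rf, test)
    acc_rf <- mean((p_rf >= 0.5) == test$outcome)
    doc <- afpr_log_development(doc, rf$config,
      metrics = list(test_accuracy = acc_rf,
                     test_auc = auc_score(test$outcome, p_rf)),
      rationale = "non-linear ensemble contrast; per-tree paths expose distributed gender influence",
      clock = clock)
    results$fairness_forest <- fairness_report(test$outcome, p_rf, test$gender)
    results$permutation_forest <- permutation_test_eod(
      test$outcome, as.integer(p_rf >= 0.5), test$gender,
      n_perm = config$n_permutations,
      seed = substream_seed(seed, "permutation_rf"))
    results$counterfactual_forest <- gender_flip_audit(rf, test,
                                                       margin = config$margin)
    audit_log("cv", "%d-fold CV audit of the forest model", config$cv_folds)
    results$cv_forest <- cv_audit(cohort, "forest", k = config$cv_folds,
                                  seed = substream_seed(seed, "cv_rf"))
    if (isTRUE(config$tune)) {
      audit_log("tune", "grid search over %d candidates", nrow(default_forest_grid()))
      gs <- tune_forest(train, seed = substream_seed(seed, "tune"))
      results$grid_search <- gs
      sel <- gs$selected
      rf_tuned <- fit_forest(train, n_trees = sel$n_trees,
                             max_depth = if (sel$max_depth == 0) NULL else sel$max_depth,
                             min_samples_split = sel$min_samples_split,
                             seed = substream_seed(seed, "forest_tuned"))
      models$forest_tuned <- rf_tuned
      p_rft <- predict(rf_tuned, test)
      results$fairness_forest_tuned <- fairness_report(test$outcome, p_rft, test$gender)
      results$tuned_test_accuracy <- mean((p_rft >= 0.5) == test$outcome)
      doc <- afpr_log_development(doc, rf_tuned$config,
        metrics = list(test_accuracy = results$tuned_test_accuracy,
                       cv_auc = gs$best_score),
        rationale = "grid-search selected forest configuration (3-fold CV on ROC-AUC)",
        clock = clock)
    }
  }

  if (!is.null(config$sweep_grid)) {
    audit_log("sweep", "bias sensitivity over %d grid points", length(config$sweep_grid))
    results$sweep <- bias_sweep(betas = config$sweep_grid, n = config$n,
                                seed = substream_seed(seed, "sweep_master"),
                                test_fraction = config$test_fraction,
                                n_perm = config$n_permutations)
  }

  if (config$log_inference != "none") {
    to_log <- c(if (use_lr) "logistic",
                if (config$log_inference == "both" && use_rf) "forest")
    for (mname in to_log) {
      audit_log("provenance", "hash-chaining %s inference log (%d patients)",
                mname, nrow(test))
      m <- models[[mname]]
      for (i in seq_len(nrow(test))) {
        pp <- predict_with_provenance(m, test[i, , drop = FALSE], clock = clock)
        doc <- afpr_append_entry(doc, pp$provenance, clock = clock)
      }
    }
  }

  primary <- if (use_lr) "logistic" else "forest"
  doc <- afpr_set_audit(doc,
    fairness = results[[paste0("fairness_", primary)]],
    permutation = results[[paste0("permutation_", primary)]],
    cv = results[[paste0("cv_", primary)]],
    counterfactual = results[[paste0("counterfactual_", primary)]],
    sensitivity = results$sweep)

  violations <- afpr_validate(doc)
  if (length(violations)) {
    stop("internal error: generated AFPR fails validation: ",
         paste(violations, collapse = "; "))
  }
  report <- render_report(doc)
  tables <- audit_tables(results, models)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_afpr(doc, file.path(config$out_dir, "afpr.json"))
    writeLines(report, file.path(config$out_dir, "report.md"))
    for (tn in names(tables)) {
      utils::write.csv(tables[[tn]],
                       file.path(config$out_dir, paste0(tn, ".csv")),
                       row.names = FALSE)
    }
    audit_log("write", "outputs in %s", config$out_dir)
  }
  list(document = doc, report = report, tables = tables,
       models = models, results = results)
}

# CSV tables mirroring the audit's headline outputs:
# single-split performance/fairness, CV summaries, model comparison with
# significance, and the sensitivity sweep.
audit_tables <- function(results, models) {
  tables <- list()
  row_single <- function(mname, fr, acc) {
    sel <- stats::setNames(fr$groups$selection_rate, fr$groups$group)
    tpr <- stats::setNames(fr$groups$TPR, fr$groups$group)
    data.frame(model = mname, accuracy = acc,
               selection_rate_female = sel[["female"]],
               selection_rate_male = sel[["male"]],
               DPD = fr$DPD,
               TPR_female = tpr[["female"]], TPR_male = tpr[["male"]],
               EOD = fr$EOD, stringsAsFactors = FALSE)
  }
  singles <- list()
  if (!is.null(results$fairness_logistic)) {
    fr <- results$fairness_logistic
    acc <- with(fr$groups, (sum(TP) + sum(TN)) / sum(n))
    singles$lr <- row_single("logistic", fr, acc)
  }
  if (!is.null(results$fairness_forest)) {
    fr <- results$fairness_forest
    acc <- with(fr$groups, (sum(TP) + sum(TN)) / sum(n))
    singles$rf <- row_single("forest", fr, acc)
  }
  if (length(singles)) tables$single_split_metrics <- do.call(rbind, singles)

  cvs <- list()
  for (mname in c("logistic", "forest")) {
    cv <- results[[paste0("cv_", mname)]]
    if (is.null(cv)) next
    cvs[[mname]] <- do.call(rbind, lapply(names(cv$summary), function(met) {
      s <- cv$summary[[met]]
      data.frame(model = mname, metric = met, mean = s$mean, sd = s$sd,
                 ci_lower = s$ci_lower, ci_upper = s$ci_upper,
                 stringsAsFactors = FALSE)
    }))
  }
  if (length(cvs)) tables$cv_summary <- do.call(rbind, cvs)

  comp <- list()
  add_comp <- function(mname, fr, cv, perm) {
    acc <- with(fr$groups, (sum(TP) + sum(TN)) / sum(n))
    data.frame(model = mname, accuracy_single = acc,
               accuracy_cv_mean = if (is.null(cv)) NA_real_ else cv$summary$accuracy$mean,
               eod_single = fr$EOD,
               p_value = if (is.null(perm)) NA_real_ else perm$p_value,
               significance = if (is.null(perm)) "" else perm$label,
               stringsAsFactors = FALSE)
  }
  if (!is.null(results$fairness_logistic)) {
    comp$lr <- add_comp("logistic", results$fairness_logistic,
                        results$cv_logistic, results$permutation_logistic)
  }
  if (!is.null(results$fairness_forest)) {
    comp$rf <- add_comp("forest", results$fairness_forest,
                        results$cv_forest, results$permutation_forest)
  }
  if (!is.null(results$fairness_forest_tuned)) {
    comp$rft <- add_comp("forest_tuned", results$fairness_forest_tuned,
                         NULL, NULL)
  }
  if (length(comp)) tables$model_comparison <- do.call(rbind, comp)

  if (!is.null(results$sweep)) {
    tables$sensitivity_sweep <- as.data.frame(results$sweep)
  }
  tables
}
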