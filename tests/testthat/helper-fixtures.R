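# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

# default 1000-patient cohort with its 70/30 split and both fitted models
default_audit_fixture <- function() {
  if (is.null(.fx$default)) {
    cohort <- generate_cohort(cohort_spec(seed = 42L))
    split <- stratified_split(cohort, 0.3, seed = substream_seed(42L, "split"))
    train <- cohort[cohort$patient_id %in% split$train_ids, ]
    test <- cohort[cohort$patient_id %in% split$test_ids, ]
    lr <- fit_logistic(train)
    rf <- fit_forest(train, seed = substream_seed(42L, "forest"))
    .fx$default <- list(cohort = cohort, split = split, train = train,
                        test = test, lr = lr, rf = rf)
  }
  .fx$default
}

# complete end-to-end audit document (deterministic clock), shared across
# the AFPR and acceptance tests
full_audit_fixture <- function() {
  if (is.null(.fx$full)) {
    cfg <- audit_config(out_dir = NULL)
    .fx$full <- suppressMessages(suppressWarnings(
      run_full_audit(cfg, clock = afpr_clock("2026-01-01T00:00:00.000Z"))))
  }
  .fx$full
}

# six-patient fairness fixture: true labels, groups (0 = female), predictions
six_patient_fixture <- function() {
  list(y_true = c(1, 1, 1, 1, 0, 0),
       group = c(0, 0, 1, 1, 0, 1),
       y_pred = c(1, 1, 0, 0, 0, 0))
}

# small deterministic table for logistic-fit oracle comparisons
tiny_logistic_fixture <- function() {
  data.frame(x1 = c(0.2, -1.1, 0.5, 1.4, -0.3, -0.9),
             x2 = c(1.0, 0.0, -0.5, 0.3, -1.2, 0.8),
             outcome = c(0L, 1L, 0L, 1L, 1L, 0L))
}
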