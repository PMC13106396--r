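test_that("a pure single-feature signal dominates the importances", {
  set.seed(41)
  d <- data.frame(signal = rbinom(400, 1, 0.5), noise = rnorm(400))
  d$outcome <- d$signal
  fit <- fit_forest(d, features = c("signal", "noise"), n_trees = 50L, seed = 1L)
  expect_gt(coef(fit)[["signal"]], 0.9)
})

test_that("a depth-1 stump finds the exhaustive impurity-optimal split", {
  # 4-row fixture with a unique best axis-aligned split (x1 <= 2.5)
  d <- data.frame(x1 = c(1, 2, 3, 4), x2 = c(5, 5, 5, 5),
                  outcome = c(0L, 0L, 1L, 1L))
  fit <- fit_forest(d, features = c("x1", "x2"), n_trees = 1L, max_depth = 1L,
                    mtry = 2L, bootstrap = FALSE, sample_fraction = 1,
                    seed = 2L)
  # oracle: enumerate every candidate split on both features and minimize
  # weighted Gini impurity
  gini <- function(y) { p <- mean(y); 2 * p * (1 - p) }
  best <- Inf; best_split <- NULL
  for (f in c("x1", "x2")) {
    for (thr in sort(unique(d[[f]]))) {
      left <- d$outcome[d[[f]] <= thr]; right <- d$outcome[d[[f]] > thr]
      if (length(left) == 0 || length(right) == 0) next # not a split
      imp <- (length(left) * gini(left) + length(right) * gini(right)) / 4
      if (imp < best - 1e-12) { best <- imp; best_split <- c(f, thr) }
    }
  }
  expect_equal(best_split[1], "x1")
  tree <- fit$trees[[1]]
  root <- tree[tree$node == 0, ]
  expect_false(root$terminal)
  expect_equal(root$feature, "x1")
  # the fitted threshold induces the same optimal partition
  expect_true(root$threshold >= 2 && root$threshold < 3)
  expect_equal(unname(predict(fit, d, type = "class")), d$outcome)
})

test_that("importances are a probability vector and gender ranks low", {
  fx <- default_audit_fixture()
  imp <- coef(fx$rf)
  expect_true(all(imp >= 0))
  expect_lt(abs(sum(imp) - 1), 1e-9)
  expect_lt(imp[["gender"]], imp[["age_std"]])
  expect_lt(imp[["gender"]], imp[["bmi_std"]])
})

test_that("replayed decision paths reproduce the backend's tree votes", {
  fx <- default_audit_fixture()
  sub <- fx$test[1:20, ]
  backend <- predict(fx$rf$ranger_fit, data = as.data.frame(sub),
                     predict.all = TRUE, num.threads = 1L)$predictions
  for (i in seq_len(nrow(sub))) {
    pp <- predict_with_provenance(fx$rf, sub[i, ],
                                  clock = afpr_clock("t"))
    replayed <- unlist(pp$provenance$mechanism$tree_probabilities)
    expect_equal(unname(replayed), unname(backend[i, "1", ]),
                 tolerance = 1e-12)
    expect_equal(pp$probability, mean(replayed))
  }
})

test_that("a JSON model archive replays identically without the backend", {
  fx <- default_audit_fixture()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model(fx$rf, path)
  back <- read_model(path)
  expect_null(back$ranger_fit)
  sub <- fx$test[1:15, ]
  expect_equal(predict(back, sub), predict(fx$rf, sub), tolerance = 1e-12)
  expect_identical(back$model_version, fx$rf$model_version)
})

test_that("forest fits are deterministic in the seed", {
  fx <- default_audit_fixture()
  again <- fit_forest(fx$train, seed = substream_seed(42L, "forest"))
  expect_equal(coef(again), coef(fx$rf))
  expect_identical(again$model_version, fx$rf$model_version)
  expect_equal(predict(again, fx$test), predict(fx$rf, fx$test))
})

test_that("tuning evaluates the full grid and selects the maximum", {
  grid <- default_forest_grid()
  expect_equal(nrow(grid), 18L)
  fx <- default_audit_fixture()
  small <- fx$train[1:200, ]
  one <- data.frame(n_trees = 25L, max_depth = 5L, min_samples_split = 2L)
  gs1 <- tune_forest(small, grid = one, cv_folds = 3L, seed = 1L)
  expect_equal(gs1$selected_index, 1L)
  sub_grid <- grid[c(1, 4, 7), ]
  gs <- tune_forest(small, grid = sub_grid, cv_folds = 3L, seed = 1L)
  expect_equal(nrow(gs$grid), 3L)
  expect_equal(gs$best_score, max(gs$grid$mean_cv_auc))
  expect_equal(gs$selected_index, which.max(gs$grid$mean_cv_auc))
})

test_that("refitting without gender removes it from the model everywhere", {
  fx <- default_audit_fixture()
  lr_ng <- refit_without_feature(fx$lr, fx$train, "gender")
  expect_false("gender" %in% lr_ng$features)
  expect_false("gender" %in% names(coef(lr_ng)))
  pp <- predict_with_provenance(lr_ng, fx$test[1, ], clock = afpr_clock("t"))
  expect_false("gender" %in% names(pp$provenance$mechanism$contributions))
  rf_ng <- refit_without_feature(fx$rf, fx$train, "gender")
  expect_false("gender" %in% rf_ng$features)
  feats_used <- unique(unlist(lapply(rf_ng$trees, function(t) t$feature)))
  expect_false("gender" %in% feats_used)
  expect_error(refit_without_feature(fx$lr, fx$train, "zz"), "zz")
})

test_that("ablating an outcome-independent attribute leaves DPD unchanged on average", {
  diffs <- sapply(1:50, function(i) {
    cohort <- generate_cohort(cohort_spec(n_patients = 600L, beta_gender = 0,
                                          seed = 7000L + i))
    split <- stratified_split(cohort, 0.3, seed = 7100L + i)
    tr <- cohort[cohort$patient_id %in% split$train_ids, ]
    te <- cohort[cohort$patient_id %in% split$test_ids, ]
    full <- fit_logistic(tr)
    ng <- refit_without_feature(full, tr, "gender")
    demographic_parity_difference(te$outcome, predict(full, te, type = "class"), te$gender) -
      demographic_parity_difference(te$outcome, predict(ng, te, type = "class"), te$gender)
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})
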