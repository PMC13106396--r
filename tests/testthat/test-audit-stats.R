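test_that("significance labels follow strict-inequality banding", {
  expect_equal(significance_label(0.0005), "***")
  expect_equal(significance_label(0.0080), "**")
  expect_equal(significance_label(0.03), "*")
  expect_equal(significance_label(0.05), "ns")
  expect_equal(significance_label(0.001), "**")
  expect_equal(significance_label(1), "ns")
  expect_error(significance_label(0))
})

test_that("degenerate all-positive predictions give p = 1", {
  y <- c(1, 0, 1, 0, 1, 0); g <- c(0, 0, 1, 1, 0, 1)
  res <- permutation_test_eod(y, rep(1, 6), g, n_perm = 200, seed = 1)
  expect_equal(res$observed_abs_eod, 0)
  expect_equal(res$p_value, 1)
})

test_that("permutation p matches the exhaustive-enumeration oracle", {
  fx <- six_patient_fixture()
  # oracle: enumerate all C(6,3) = 20 assignments of three female slots
  combos <- combn(6, 3)
  exceed <- sapply(seq_len(ncol(combos)), function(k) {
    g <- rep(1, 6); g[combos[, k]] <- 0
    pos <- fx$y_true == 1
    nf <- sum(g == 0 & pos); nm <- sum(g == 1 & pos)
    if (nf == 0 || nm == 0) return(TRUE)
    abs(sum(fx$y_pred[g == 0 & pos]) / nf -
        sum(fx$y_pred[g == 1 & pos]) / nm) >= 1.0
  })
  q <- mean(exceed)
  N <- 4000
  res <- permutation_test_eod(fx$y_true, fx$y_pred, fx$group,
                              n_perm = N, seed = 99)
  expected_p <- (q * N + 1) / (N + 1)
  mc_se <- sqrt(q * (1 - q) / N)
  expect_lt(abs(res$p_value - expected_p), 3 * mc_se)
  expect_gte(res$p_value, 1 / (N + 1))
  expect_lte(res$p_value, 1)
})

test_that("the p-value is reproducible from its seed", {
  fx <- default_audit_fixture()
  pred <- predict(fx$lr, fx$test, type = "class")
  a <- permutation_test_eod(fx$test$outcome, pred, fx$test$gender, seed = 5)
  b <- permutation_test_eod(fx$test$outcome, pred, fx$test$gender, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_value, (a$exceedances + 1) / (a$n_permutations + 1))
})

test_that("stronger injected bias stochastically lowers the p-value", {
  pvals <- sapply(1:15, function(i) {
    sapply(c(-0.2, -0.8), function(b) {
      cohort <- generate_cohort(cohort_spec(beta_gender = b, seed = 4000 + i))
      split <- stratified_split(cohort, 0.3, seed = 4100 + i)
      tr <- cohort[cohort$patient_id %in% split$train_ids, ]
      te <- cohort[cohort$patient_id %in% split$test_ids, ]
      fit <- fit_logistic(tr)
      permutation_test_eod(te$outcome, predict(fit, te, type = "class"),
                           te$gender, n_perm = 400, seed = 4200 + i)$p_value
    })
  })
  expect_lt(mean(pvals[2, ]), mean(pvals[1, ]))
})

test_that("t-based CI reproduces the hand computation on 1..5", {
  s <- ci_t_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))
  expect_lt(abs(s$t_crit - 2.776), 0.001)
  half <- 2.7764451 * sqrt(2.5) / sqrt(5)
  expect_equal(s$ci_lower, 3 - half, tolerance = 1e-6)
  expect_equal(s$ci_upper, 3 + half, tolerance = 1e-6)
  z <- ci_t_summary(rep(2.5, 5))
  expect_equal(z$ci_lower, 2.5)
  expect_equal(z$ci_upper, 2.5)
})

test_that("cv_audit summaries reproduce an independent recomputation", {
  fx <- default_audit_fixture()
  cv <- suppressWarnings(cv_audit(fx$cohort, "logistic", seed = 77))
  expect_equal(nrow(cv$folds), 5L)
  for (met in c("accuracy", "auc", "dpd", "eod")) {
    v <- cv$folds[[met]][!is.na(cv$folds[[met]])]
    expect_equal(cv$summary[[met]]$mean, mean(v))
    expect_equal(cv$summary[[met]]$sd, sd(v))
    expect_equal(cv$summary[[met]]$ci_upper - cv$summary[[met]]$ci_lower,
                 2 * qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v)))
  }
  # determinism
  cv2 <- suppressWarnings(cv_audit(fx$cohort, "logistic", seed = 77))
  expect_identical(cv$folds, cv2$folds)
})

test_that("auc_score agrees with the rank-statistic definition", {
  set.seed(71)
  y <- rbinom(200, 1, 0.4); sc <- rnorm(200) + y
  r <- rank(sc); n1 <- sum(y); n0 <- sum(1 - y)
  mann_whitney <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(auc_score(y, sc), mann_whitney, tolerance = 1e-12)
})
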