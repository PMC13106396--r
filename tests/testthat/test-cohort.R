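test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(comorbidity_prevalence = 1.2), "comorbidity_prevalence")
  expect_error(cohort_spec(age_range = c(85, 20)), "age_range")
  expect_error(cohort_spec(bmi_clip = c(45, 16)), "bmi_clip")
  expect_error(cohort_spec(bmi_sd = -1), "bmi_sd")
})

test_that("generated cohort satisfies its structural invariants", {
  spec <- cohort_spec(n_patients = 1000L, seed = 7L)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 1000L)
  expect_true(all(cohort$age >= 20 & cohort$age <= 85))
  expect_true(all(cohort$bmi >= 16 & cohort$bmi <= 45))
  expect_true(all(cohort$comorbidity %in% 0:1))
  expect_true(all(cohort$gender %in% 0:1))
  expect_true(all(cohort$outcome %in% 0:1))
  expect_lt(abs(mean(cohort$age_std)), 1e-9)
  expect_lt(abs(sd(cohort$age_std) - 1), 1e-9)
  expect_lt(abs(mean(cohort$bmi_std)), 1e-9)
  expect_lt(abs(sd(cohort$bmi_std) - 1), 1e-9)
  expect_equal(anyDuplicated(cohort$patient_id), 0L)
})

test_that("null model (all coefficients zero) gives prevalence 1/2", {
  spec <- cohort_spec(n_patients = 10000L, intercept = 0, beta_age = 0,
                      beta_bmi = 0, beta_comorbidity = 0, beta_gender = 0,
                      seed = 11L)
  cohort <- generate_cohort(spec)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(cohort$outcome) - 0.5), 3 * se)
})

test_that("default spec reproduces the stated comorbidity prevalence", {
  cohort <- generate_cohort(cohort_spec(seed = 3L))
  se <- sqrt(0.35 * 0.65 / 1000)
  expect_lt(abs(mean(cohort$comorbidity) - 0.35), 3 * se)
})

test_that("empirical prevalence matches an independent Monte-Carlo oracle", {
  # oracle: direct expectation of sigmoid(lp) over the stated feature
  # distributions, drawn independently of the generator's code path
  set.seed(424242)
  n_mc <- 400000
  age <- runif(n_mc, 20, 85)
  bmi <- pmin(pmax(rnorm(n_mc, 27, 5), 16), 45)
  com <- rbinom(n_mc, 1, 0.35)
  gen <- rbinom(n_mc, 1, 0.5)
  lp <- -1 + 0.5 * scale(age)[, 1] + 0.4 * scale(bmi)[, 1] + 1 * com - 0.3 * gen
  oracle_prev <- mean(1 / (1 + exp(-lp)))

  cohort <- generate_cohort(cohort_spec(n_patients = 100000L, seed = 5L))
  se <- sqrt(oracle_prev * (1 - oracle_prev) / 100000)
  expect_lt(abs(mean(cohort$outcome) - oracle_prev), 3 * se)
})

test_that("cohorts are reproducible from the seed and differ across seeds", {
  a <- generate_cohort(cohort_spec(n_patients = 200L, seed = 9L))
  b <- generate_cohort(cohort_spec(n_patients = 200L, seed = 9L))
  d <- generate_cohort(cohort_spec(n_patients = 200L, seed = 10L))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a)$age, as.data.frame(d)$age))
})

test_that("female-stratum prevalence is invariant to the injected gender bias", {
  # Monte-Carlo over replicate seeds: beta_gender acts on males only
  prev <- sapply(1:30, function(i) {
    c0 <- generate_cohort(cohort_spec(n_patients = 2000L, beta_gender = 0,
                                      seed = 100L + i))
    c8 <- generate_cohort(cohort_spec(n_patients = 2000L, beta_gender = -0.8,
                                      seed = 500L + i))
    c(f0 = mean(c0$outcome[c0$gender == 0]),
      m0 = mean(c0$outcome[c0$gender == 1]),
      f8 = mean(c8$outcome[c8$gender == 0]),
      m8 = mean(c8$outcome[c8$gender == 1]))
  })
  m <- rowMeans(prev)
  se <- apply(prev, 1, sd) / sqrt(ncol(prev))
  # female prevalence unchanged within 3 SEs of the difference
  expect_lt(abs(m["f0"] - m["f8"]), 3 * sqrt(se["f0"]^2 + se["f8"]^2))
  # male prevalence strictly reduced by the stronger penalty
  expect_gt(m["m0"] - m["m8"], 3 * sqrt(se["m0"]^2 + se["m8"]^2))
})

test_that("auditing an unbiased world yields mean EOD near zero", {
  eods <- sapply(1:50, function(i) {
    cohort <- generate_cohort(cohort_spec(beta_gender = 0, seed = 2000L + i))
    split <- stratified_split(cohort, 0.3, seed = 3000L + i)
    tr <- cohort[cohort$patient_id %in% split$train_ids, ]
    te <- cohort[cohort$patient_id %in% split$test_ids, ]
    fit <- fit_logistic(tr)
    equal_opportunity_difference(te$outcome, predict(fit, te, type = "class"),
                                 te$gender)
  })
  expect_lt(abs(mean(eods)), 3 * sd(eods) / sqrt(length(eods)))
})
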