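test_that("the end-to-end audit yields a valid, internally consistent bundle", {
  res <- full_audit_fixture()
  expect_s3_class(res$document, "afpr_document")
  expect_length(afpr_validate(res$document), 0L)
  expect_true(afpr_verify_chain(res$document)$ok)
  expect_equal(length(res$document$inference_log), 300L)
  expect_true(all(c("single_split_metrics", "cv_summary",
                    "model_comparison", "sensitivity_sweep") %in%
                  names(res$tables)))
  expect_equal(nrow(res$tables$sensitivity_sweep), 5L)
  expect_equal(nrow(res$tables$model_comparison), 3L)
  # comparison table is consistent with the underlying results
  expect_equal(res$tables$model_comparison$eod_single[1],
               res$results$fairness_logistic$EOD)
  expect_equal(res$tables$model_comparison$p_value[1],
               res$results$permutation_logistic$p_value)
  expect_type(res$report, "character")
  expect_match(res$report[1], "^# Fairness audit report$")
})

test_that("audit runs are reproducible given the seed and a fixed clock", {
  cfg <- audit_config(n = 400L, seed = 7L, sweep_grid = NULL, tune = FALSE,
                      n_permutations = 100L, model = "logistic")
  clock <- afpr_clock("2026-02-02T00:00:00.000Z")
  a <- suppressMessages(suppressWarnings(run_full_audit(cfg, clock = clock)))
  b <- suppressMessages(suppressWarnings(run_full_audit(cfg, clock = clock)))
  expect_identical(canonical_json(unclass(a$document)),
                   canonical_json(unclass(b$document)))
  expect_identical(a$report, b$report)
})

test_that("the sweep section is optional and the document still validates", {
  cfg <- audit_config(n = 400L, seed = 8L, sweep_grid = NULL, tune = FALSE,
                      n_permutations = 100L, model = "logistic")
  res <- suppressMessages(suppressWarnings(run_full_audit(cfg)))
  expect_null(res$document$audit$sensitivity)
  expect_length(afpr_validate(res$document), 0L)
  expect_false("sensitivity_sweep" %in% names(res$tables))
})

test_that("output files are written and re-readable", {
  out <- tempfile("auditrun")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- audit_config(n = 400L, seed = 9L, sweep_grid = NULL, tune = FALSE,
                      n_permutations = 100L, model = "logistic",
                      out_dir = out)
  res <- suppressMessages(suppressWarnings(run_full_audit(cfg)))
  expect_true(file.exists(file.path(out, "afpr.json")))
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "single_split_metrics.csv")))
  back <- read_afpr(file.path(out, "afpr.json"))
  expect_true(afpr_verify_chain(back)$ok)
  expect_identical(readLines(file.path(out, "report.md")), res$report)
})

test_that("the command-line interface runs its subcommands", {
  cli <- system.file("cli", "fairaudit.R", package = "fairaudit")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile("clirun")
  on.exit(unlink(out, recursive = TRUE))

  sim <- system2(rscript, c(cli, "simulate", "--n", "120", "--seed", "3",
                            "--out", out), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(sim, "status"), NULL)
  cohort <- read_cohort(file.path(out, "cohort.csv"))
  expect_equal(nrow(cohort), 120L)

  aud <- system2(rscript, c(cli, "audit", "--n", "300", "--seed", "4",
                            "--model", "logistic", "--permutations", "100",
                            "--no-sweep", "--no-tune", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(aud, "status"), NULL)
  expect_true(file.exists(file.path(out, "afpr.json")))

  ver <- system2(rscript, c(cli, "verify", file.path(out, "afpr.json")),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(ver, "status"), NULL)

  # tampering must be caught with a non-zero exit
  doc <- read_afpr(file.path(out, "afpr.json"))
  doc$inference_log[[1]]$payload$probability <- 0.42
  write_afpr(doc, file.path(out, "tampered.json"))
  bad <- suppressWarnings(
    system2(rscript, c(cli, "verify", file.path(out, "tampered.json")),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 1L)

  unknown <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(unknown, "status"), 1L)
})
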