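clk <- function() afpr_clock("2026-01-01T00:00:00.000Z")

make_doc <- function(n_entries = 5L) {
  fx <- default_audit_fixture()
  doc <- afpr_document(afpr_data_provenance(fx$cohort), clock = clk())
  for (i in seq_len(n_entries)) {
    pp <- predict_with_provenance(fx$lr, fx$test[i, ], clock = clk())
    doc <- afpr_append_entry(doc, pp$provenance, clock = clk())
  }
  doc
}

test_that("appending builds a well-formed chain from the genesis constant", {
  doc <- make_doc(2L)
  e1 <- doc$inference_log[[1]]
  e2 <- doc$inference_log[[2]]
  expect_equal(e1$sequence, 1L)
  expect_identical(e1$prev_hash, strrep("0", 64))
  expect_identical(e2$prev_hash, e1$entry_hash)
  expect_identical(doc$chain_head, e2$entry_hash)
  expect_match(e1$entry_hash, "^[0-9a-f]{64}$")
  expect_true(afpr_verify_chain(doc)$ok)
})

test_that("patient identifiers are stored as salted hashes, not raw", {
  doc <- make_doc(1L)
  e <- doc$inference_log[[1]]
  fx <- default_audit_fixture()
  pid <- fx$test$patient_id[1]
  expect_false(identical(e$patient_ref, pid))
  expect_identical(e$patient_ref, sha256_hex(paste0("fairaudit|", pid)))
  expect_null(e$payload$patient_id)
})

test_that("any single mutation is detected at the earliest bad entry", {
  doc <- make_doc(5L)
  tampered <- doc
  tampered$inference_log[[3]]$payload$probability <- 0.999
  v <- afpr_verify_chain(tampered)
  expect_false(v$ok)
  expect_equal(v$first_bad, 3L)

  reordered <- doc
  reordered$inference_log <- doc$inference_log[c(1, 3, 2, 4, 5)]
  expect_false(afpr_verify_chain(reordered)$ok)
  expect_equal(afpr_verify_chain(reordered)$first_bad, 2L)

  deleted <- doc
  deleted$inference_log <- doc$inference_log[-3]
  v <- afpr_verify_chain(deleted)
  expect_false(v$ok)
  expect_equal(v$first_bad, 3L)

  headless <- doc
  headless$chain_head <- strrep("f", 64)
  expect_false(afpr_verify_chain(headless)$ok)
})

test_that("every single-bit-level field mutation breaks verification", {
  doc <- make_doc(3L)
  mutations <- list(
    function(d) { d$inference_log[[2]]$timestamp <- "2030-01-01T00:00:00Z"; d },
    function(d) { d$inference_log[[2]]$model_version <- strrep("9", 64); d },
    function(d) { d$inference_log[[2]]$patient_ref <- strrep("8", 64); d },
    function(d) { d$inference_log[[2]]$payload$predicted_class <- 0L; d },
    function(d) { d$inference_log[[2]]$payload$inputs$gender <- 99; d })
  for (mut in mutations) {
    expect_false(afpr_verify_chain(mut(doc))$ok)
  }
})

test_that("rejected payloads leave the document unchanged", {
  doc <- make_doc(1L)
  before <- canonical_json(unclass(doc))
  expect_error(afpr_append_entry(doc, list(probability = 0.5), clock = clk()),
               "model_version")
  expect_identical(canonical_json(unclass(doc)), before)
})

test_that("schema validation passes on real documents and names violations", {
  doc <- make_doc(2L)
  expect_length(afpr_validate(doc), 0L)

  bad <- doc
  bad$data_provenance$known_limitations <- NULL
  v <- afpr_validate(bad)
  expect_true(any(grepl("known_limitations", v)))

  bad2 <- unclass(doc)
  bad2$inference_log[[1]]$timestamp <- 12345
  v2 <- afpr_validate(structure(bad2, class = "afpr_document"))
  expect_true(any(grepl("inference_log\\[1\\].timestamp", v2)))

  bad3 <- doc
  bad3$inference_log[[2]]$sequence <- 7L
  v3 <- afpr_validate(bad3)
  expect_true(any(grepl("sequence", v3)))
})

test_that("serialization round-trips losslessly and chains still verify", {
  res <- full_audit_fixture()
  doc <- res$document
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_afpr(doc, path)
  back <- read_afpr(path)
  expect_identical(canonical_json(unclass(back)), canonical_json(unclass(doc)))
  expect_true(afpr_verify_chain(back)$ok)
  expect_length(afpr_validate(back), 0L)
})

test_that("report rendering is deterministic with banded severities", {
  res <- full_audit_fixture()
  r1 <- render_report(res$document)
  r2 <- render_report(res$document)
  expect_identical(r1, r2)

  doc <- res$document
  doc$audit$permutation$p_value <- 0.0080
  doc$audit$permutation$label <- significance_label(0.0080)
  doc$audit$fairness$EOD <- 0.226
  txt <- paste(render_report(doc), collapse = "\n")
  expect_match(txt, "0\\.008\\*\\*")
  expect_match(txt, "\\+0\\.226 \\[high\\]")

  doc$audit$fairness$EOD <- 0.15
  expect_match(paste(render_report(doc), collapse = "\n"), "\\[moderate\\]")
  doc$audit$fairness$EOD <- 0.05
  expect_match(paste(render_report(doc), collapse = "\n"), "\\[low\\]")

  empty <- afpr_document(afpr_data_provenance(default_audit_fixture()$cohort),
                         clock = clk())
  expect_error(render_report(empty), "audit")
})

test_that("development log entries are ordered and rendered", {
  doc <- afpr_document(afpr_data_provenance(default_audit_fixture()$cohort),
                       clock = clk())
  doc <- afpr_log_development(doc, list(model = "logistic"),
                              metrics = list(acc = 0.75),
                              rationale = "baseline", clock = clk())
  doc <- afpr_log_development(doc, list(model = "forest"),
                              rationale = "contrast", clock = clk())
  expect_equal(sapply(doc$model_development, `[[`, "sequence"), 1:2)
  expect_length(afpr_validate(doc), 0L)
})
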