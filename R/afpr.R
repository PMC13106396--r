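#' Clock abstraction for timestamping records
#'
#' Returns a zero-argument function producing ISO 8601 UTC timestamps.
#' Pass a fixed string to obtain a deterministic clock for reproducible
#' documents and tests.
#'
#' @param fixed optional fixed timestamp string to return on every call.
#' @return A function() -> character timestamp.
#' @examples
#' clk <- afpr_clock("2026-01-01T00:00:00Z")
#' clk()
#' @export
afpr_clock <- function(fixed = NULL) {
  if (!is.null(fixed)) {
    force(fixed)
    function() fixed
  } else {
    function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  }
}

#' Genesis constant of the inference-log hash chain
#' @return 64 zero hex characters.
#' @export
afpr_genesis_hash <- function() strrep("0", 64)

#' Create an AI Fairness Provenance Record document
#'
#' The AFPR is a structured, hash-chained container with four sections:
#' data provenance (how the cohort came to be), a model development log
#' (ordered entries of configs, metrics and rationale), an append-only
#' inference log (per-prediction provenance, hash-chained for tamper
#' evidence), and the audit section (fairness, significance, CV,
#' counterfactual and sensitivity results).
#'
#' @param data_provenance list describing the data (see
#'   \code{\link{afpr_data_provenance}}).
#' @param clock timestamp source, see \code{\link{afpr_clock}}.
#' @return An \code{afpr_document}.
#' @export
afpr_document <- function(data_provenance, clock = afpr_clock()) {
  stopifnot(is.list(data_provenance))
  structure(list(schema_version = "1.0",
                 created = clock(),
                 data_provenance = data_provenance,
                 model_development = list(),
                 inference_log = list(),
                 audit = NULL,
                 chain_head = afpr_genesis_hash()),
            class = "afpr_document")
}

#' Build the data-provenance section from a cohort
#'
#' Records the generating spec and seed, feature descriptions, the
#' demographic composition of the generated cohort, and known
#' limitations of the synthetic data.
#'
#' @param cohort a \code{cohort}.
#' @return list for the \code{data_provenance} section.
#' @export
afpr_data_provenance <- function(cohort) {
  spec <- attr(cohort, "spec")
  list(
    source = "synthetic cohort generated by the fairaudit logistic data-generating process",
    cohort_spec = if (is.null(spec)) NULL else unclass(spec),
    seed = if (is.null(spec)) NULL else spec$seed,
    n_patients = nrow(cohort),
    feature_descriptions = list(
      age = "age in years, uniform over the spec range, z-scored for modelling",
      bmi = "body mass index kg/m^2, Gaussian then clipped, z-scored for modelling",
      comorbidity = "binary comorbidity status",
      gender = "protected attribute; 0 = female, 1 = male",
      outcome = "30-day readmission indicator"),
    demographic_composition = list(
      male_fraction = mean(cohort$gender),
      comorbidity_prevalence = mean(cohort$comorbidity),
      outcome_prevalence = mean(cohort$outcome)),
    known_limitations = list(
      "synthetic data: features are mutually independent by construction",
      "no missingness, measurement error or site effects are emulated",
      "injected gender effect is a single additive log-odds term"))
}

#' Append a model-development log entry
#'
#' @param doc an \code{afpr_document}.
#' @param config training configuration list.
#' @param metrics named list of evaluation metrics.
#' @param rationale free-text decision rationale.
#' @param clock timestamp source.
#' @return The updated document.
#' @export
afpr_log_development <- function(doc, config, metrics = list(),
                                 rationale = "", clock = afpr_clock()) {
  stopifnot(inherits(doc, "afpr_document"))
  doc$model_development[[length(doc$model_development) + 1L]] <-
    list(sequence = length(doc$model_development) + 1L,
         timestamp = clock(), config = config, metrics = metrics,
         rationale = rationale)
  doc
}

#' Append a prediction to the hash-chained inference log
#'
#' Adds one inference entry holding the prediction provenance payload.
#' The entry hash is SHA-256 over the previous entry's hash concatenated
#' with the canonical JSON serialization of the entry's other fields, so
#' any later alteration, reordering or removal is detectable by
#' \code{\link{afpr_verify_chain}}. Patient identifiers are stored as
#' salted hashes, never raw; the salt lives outside the document.
#'
#' @param doc an \code{afpr_document}.
#' @param payload a \code{prediction_provenance} (or equivalent list with
#'   fields model_version, probability, predicted_class).
#' @param salt character salt for patient-id hashing.
#' @param clock timestamp source.
#' @return The updated document; on payload validation failure the
#'   document is unchanged and an error is thrown.
#' @export
afpr_append_entry <- function(doc, payload, salt = "fairaudit",
                              clock = afpr_clock()) {
  stopifnot(inherits(doc, "afpr_document"))
  pl <- if (inherits(payload, "prediction_provenance")) unclass(payload) else payload
  req <- c("model_version", "probability", "predicted_class")
  miss <- req[!vapply(req, function(f) !is.null(pl[[f]]), logical(1))]
  if (length(miss)) {
    stop("inference payload rejected; missing field(s): ",
         paste(miss, collapse = ", "))
  }
  pid <- pl$patient_id
  patient_ref <- if (is.null(pid) || is.na(pid)) "unidentified"
                 else sha256_hex(paste0(salt, "|", pid))
  pl$patient_id <- NULL
  pl <- rapply(pl, function(v) v, how = "replace") # drop attributes
  seqno <- length(doc$inference_log) + 1L
  entry <- list(sequence = seqno,
                entry_id = sprintf("inf-%06d", seqno),
                timestamp = clock(),
                model_version = pl$model_version,
                patient_ref = patient_ref,
                payload = pl,
                prev_hash = doc$chain_head)
  entry$entry_hash <- entry_hash(entry)
  doc$inference_log[[seqno]] <- entry
  doc$chain_head <- entry$entry_hash
  doc
}

entry_hash <- function(entry) {
  body <- entry[setdiff(names(entry), c("prev_hash", "entry_hash"))]
  sha256_hex(paste0(entry$prev_hash, canonical_json(body)))
}

#' Verify the inference-log hash chain
#'
#' Recomputes every entry hash and checks sequence contiguity and
#' prev-hash linkage back to the genesis constant, plus the stored chain
#' head. Passes iff no entry was altered, reordered or removed.
#'
#' @param doc an \code{afpr_document}.
#' @return list(ok = logical, first_bad = earliest inconsistent sequence
#'   number, or NA when ok).
#' @export
afpr_verify_chain <- function(doc) {
  stopifnot(inherits(doc, "afpr_document"))
  prev <- afpr_genesis_hash()
  for (i in seq_along(doc$inference_log)) {
    e <- doc$inference_log[[i]]
    ok <- !is.null(e$sequence) && e$sequence == i &&
      identical(e$prev_hash, prev) &&
      identical(e$entry_hash, entry_hash(e))
    if (!ok) return(list(ok = FALSE, first_bad = i))
    prev <- e$entry_hash
  }
  if (!identical(doc$chain_head, prev)) {
    return(list(ok = FALSE, first_bad = length(doc$inference_log) + 1L))
  }
  list(ok = TRUE, first_bad = NA_integer_)
}

#' Attach the audit section
#'
#' @param doc an \code{afpr_document}.
#' @param fairness,permutation,cv,counterfactual,sensitivity audit result
#'   objects (converted via \code{\link{as_afpr_block}}) or NULL.
#' @return The updated document.
#' @export
afpr_set_audit <- function(doc, fairness = NULL, permutation = NULL,
                           cv = NULL, counterfactual = NULL,
                           sensitivity = NULL) {
  stopifnot(inherits(doc, "afpr_document"))
  blk <- function(x) {
    if (is.null(x)) NULL
    else if (inherits(x, c("fairness_report", "permutation_result",
                           "cv_result", "counterfactual_result",
                           "sensitivity_table"))) as_afpr_block(x)
    else x
  }
  audit <- list(fairness = blk(fairness), permutation = blk(permutation),
                cv = blk(cv), counterfactual = blk(counterfactual),
                sensitivity = blk(sensitivity))
  doc$audit <- audit[!vapply(audit, is.null, logical(1))]
  doc
}

#' Validate an AFPR document against the published schema
#'
#' Checks the document against the JSON-Schema-style definition shipped
#' at \code{inst/extdata/afpr-schema.json} (required fields, types,
#' array item shapes) plus the structural rules the schema cannot
#' express: strictly ordered inference sequence numbers and hex hash
#' formats.
#'
#' @param doc an \code{afpr_document} or a parsed equivalent list.
#' @return Character vector of violations naming JSON paths; empty iff
#'   fully conformant.
#' @export
afpr_validate <- function(doc) {
  schema <- jsonlite::fromJSON(system.file("extdata", "afpr-schema.json",
                                           package = "fairaudit"),
                               simplifyVector = FALSE)
  v <- validate_schema(unclass(doc), schema, "$")
  # structural rules beyond the schema subset
  seqs <- vapply(doc$inference_log, function(e) {
    if (is.null(e$sequence)) NA_integer_ else as.integer(e$sequence)
  }, integer(1))
  if (length(seqs) && (anyNA(seqs) || any(seqs != seq_along(seqs)))) {
    v <- c(v, "$.inference_log: sequence numbers must be 1..n in order")
  }
  v
}

validate_schema <- function(x, schema, path) {
  v <- character(0)
  type <- schema$type
  if (!is.null(type)) {
    ok <- switch(type,
                 object = is.list(x) && (length(x) == 0 || !is.null(names(x))),
                 array = is.list(x) && (length(x) == 0 || is.null(names(x)) || all(names(x) == "")),
                 string = is.character(x) && length(x) == 1L,
                 number = is.numeric(x) && length(x) == 1L,
                 integer = is.numeric(x) && length(x) == 1L && x == floor(x),
                 boolean = is.logical(x) && length(x) == 1L,
                 TRUE)
    if (!ok) {
      return(sprintf("%s: expected %s", path, type))
    }
  }
  if (!is.null(schema$pattern) && is.character(x) &&
      !grepl(schema$pattern, x)) {
    v <- c(v, sprintf("%s: does not match pattern %s", path, schema$pattern))
  }
  for (req in schema$required) {
    if (is.null(x[[req]])) v <- c(v, sprintf("%s.%s: required field missing", path, req))
  }
  if (!is.null(schema$properties)) {
    for (nm in names(schema$properties)) {
      if (!is.null(x[[nm]])) {
        v <- c(v, validate_schema(x[[nm]], schema$properties[[nm]],
                                  paste0(path, ".", nm)))
      }
    }
  }
  if (!is.null(schema$items) && is.list(x)) {
    for (i in seq_along(x)) {
      v <- c(v, validate_schema(x[[i]], schema$items,
                                sprintf("%s[%d]", path, i)))
    }
  }
  v
}

#' Write an AFPR document as canonical JSON
#'
#' @param doc an \code{afpr_document}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_afpr <- function(doc, path) {
  stopifnot(inherits(doc, "afpr_document"))
  writeLines(canonical_json(unclass(doc)), path, useBytes = TRUE)
  invisible(path)
}

#' Read an AFPR document
#'
#' @param path JSON path.
#' @return An \code{afpr_document}.
#' @export
read_afpr <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (is.null(doc$model_development)) doc$model_development <- list()
  if (is.null(doc$inference_log)) doc$inference_log <- list()
  structure(doc, class = "afpr_document")
}

#' @export
print.afpr_document <- function(x, ...) {
  cat(sprintf("AFPR document (schema %s, created %s)\n", x$schema_version, x$created))
  cat(sprintf("  development log: %d entries; inference log: %d entries\n",
              length(x$model_development), length(x$inference_log)))
  cat(sprintf("  audit sections: %s\n",
              if (is.null(x$audit)) "none" else paste(names(x$audit), collapse = ", ")))
  cat(sprintf("  chain head: %s...\n", substr(x$chain_head, 1, 16)))
  invisible(x)
}

disparity_band <- function(x) {
  a <- abs(x)
  if (a < 0.1) "low" else if (a <= 0.2) "moderate" else "high"
}

fmt3 <- function(x) formatC(x, digits = 3, format = "f")

#' Render a human-readable fairness audit report
#'
#' Deterministic Markdown rendering of an AFPR's audit section: per-group
#' metrics, the disparity statistics with significance labels and severity
#' bands (|disparity| < 0.1 low, 0.1-0.2 moderate, > 0.2 high), the CV
#' summary with t-based confidence intervals, the counterfactual summary,
#' the sensitivity table and the model development timeline. Numbers are
#' rounded to 3 decimals for display only.
#'
#' @param doc a valid \code{afpr_document} with an audit section.
#' @return Character vector of Markdown lines.
#' @export
render_report <- function(doc) {
  stopifnot(inherits(doc, "afpr_document"))
  if (is.null(doc$audit) || length(doc$audit) == 0) {
    stop("document has no audit section; nothing to report")
  }
  a <- doc$audit
  L <- c("# Fairness audit report", "",
         sprintf("Generated from AFPR schema %s (document created %s).",
                 doc$schema_version, doc$created), "")
  dp <- doc$data_provenance
  if (!is.null(dp$n_patients)) {
    L <- c(L, sprintf("Cohort: %d synthetic patients (seed %s); outcome prevalence %s.",
                      dp$n_patients,
                      if (is.null(dp$seed)) "unknown" else dp$seed,
                      fmt3(dp$demographic_composition$outcome_prevalence)), "")
  }
  if (!is.null(a$fairness)) {
    f <- a$fairness
    L <- c(L, "## Group metrics", "",
           "| group | n | selection rate | TPR | FPR |",
           "|---|---|---|---|---|")
    for (g in f$groups) {
      L <- c(L, sprintf("| %s | %d | %s | %s | %s |", g$group, g$n,
                        fmt3(g$selection_rate),
                        if (is.null(g$TPR)) "undefined" else fmt3(g$TPR),
                        if (is.null(g$FPR)) "undefined" else fmt3(g$FPR)))
    }
    plabel <- if (!is.null(a$permutation)) {
      sprintf(" (permutation p = %s%s)", fmt3(a$permutation$p_value),
              if (a$permutation$label == "ns") ", ns"
              else a$permutation$label)
    } else ""
    L <- c(L, "",
           sprintf("- DPD (female - male selection rate): %+.3f [%s]",
                   f$DPD, disparity_band(f$DPD)))
    if (!is.null(f$EOD)) {
      L <- c(L, sprintf("- EOD (female - male TPR): %+.3f [%s]%s",
                        f$EOD, disparity_band(f$EOD), plabel))
    }
    L <- c(L, "")
  }
  if (!is.null(a$cv)) {
    cv <- a$cv
    L <- c(L, sprintf("## %d-fold cross-validation (%s model)", cv$k, cv$model), "",
           "| metric | mean | SD | 95% CI |", "|---|---|---|---|")
    for (mname in names(cv$summary)) {
      s <- cv$summary[[mname]]
      L <- c(L, sprintf("| %s | %s | %s | [%s, %s] |", mname, fmt3(s$mean),
                        if (is.null(s$sd)) "-" else fmt3(s$sd),
                        if (is.null(s$ci_lower)) "-" else fmt3(s$ci_lower),
                        if (is.null(s$ci_upper)) "-" else fmt3(s$ci_upper)))
    }
    L <- c(L, "", sprintf("t critical value: %s (df = %d).",
                          fmt3(cv$t_crit), cv$k - 1L), "")
  }
  if (!is.null(a$counterfactual)) {
    cf <- a$counterfactual
    L <- c(L, "## Counterfactual gender-flip analysis", "",
           sprintf("Boundary cases (|p - %s| <= %s): %d; class changed after gender flip: %d (%s).",
                   fmt3(cf$threshold), fmt3(cf$margin), cf$n_boundary,
                   cf$n_flipped,
                   if (is.null(cf$flip_fraction)) "n/a"
                   else paste0(fmt3(100 * cf$flip_fraction), "%")), "")
  }
  if (!is.null(a$sensitivity)) {
    L <- c(L, "## Bias-magnitude sensitivity sweep", "",
           "| injected beta | learned coefficient | EOD | p | detected |",
           "|---|---|---|---|---|")
    for (r in a$sensitivity$rows) {
      L <- c(L, sprintf("| %+.2f | %+.3f | %+.3f | %s | %s |",
                        r$beta_true, r$learned_coefficient, r$eod,
                        fmt3(r$p_value), if (r$detected) "yes" else "no"))
    }
    L <- c(L, "")
  }
  if (length(doc$model_development)) {
    L <- c(L, "## Model development timeline", "")
    for (e in doc$model_development) {
      metr <- if (length(e$metrics)) {
        paste(vapply(names(e$metrics), function(n) {
          sprintf("%s = %s", n, fmt3(as.numeric(e$metrics[[n]])))
        }, character(1)), collapse = ", ")
      } else "no metrics"
      L <- c(L, sprintf("%d. [%s] %s (%s): %s", e$sequence, e$timestamp,
                        if (is.null(e$config$model)) "model" else e$config$model,
                        metr, e$rationale))
    }
    L <- c(L, "")
  }
  L <- c(L, sprintf("Inference log: %d hash-chained entries; chain head %s...",
                    length(doc$inference_log), substr(doc$chain_head, 1, 16)))
  L
}
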