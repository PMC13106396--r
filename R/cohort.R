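#' Specification of a synthetic readmission cohort
#'
#' Defines the logistic data-generating process for a synthetic 30-day
#' readmission cohort. Each patient has four clinical features: age
#' (uniform on \code{age_range}), BMI (Gaussian, then clipped to
#' \code{bmi_clip}), binary comorbidity status and binary gender
#' (0 = female, 1 = male). Age and BMI are z-scored over the generated
#' cohort, and the outcome is drawn Bernoulli with
#' \deqn{p = \sigma(\beta_0 + \beta_{age} \cdot age_z + \beta_{bmi} \cdot
#'   bmi_z + \beta_{com} \cdot comorbidity + \beta_{gender} \cdot gender).}
#'
#' The default \code{beta_gender = -0.30} injects a known gender bias:
#' male patients receive systematically lower readmission odds than
#' otherwise identical female patients, which downstream audits should
#' detect.
#'
#' @param n_patients number of patients (>= 1).
#' @param intercept intercept on the log-odds scale.
#' @param beta_age log-odds per SD of age.
#' @param beta_bmi log-odds per SD of BMI.
#' @param beta_comorbidity log-odds for comorbidity present.
#' @param beta_gender log-odds for male gender; negative values penalize
#'   male patients' readmission probability.
#' @param age_range length-2 numeric, years.
#' @param bmi_mean,bmi_sd Gaussian BMI parameters, kg/m^2.
#' @param bmi_clip length-2 numeric clip range for BMI, kg/m^2.
#' @param comorbidity_prevalence probability of comorbidity.
#' @param male_fraction probability of male gender.
#' @param seed master seed; all draws use named substreams derived from it.
#' @return An object of class \code{cohort_spec}.
#' @examples
#' spec <- cohort_spec(n_patients = 100, seed = 1)
#' cohort <- generate_cohort(spec)
#' @export
cohort_spec <- function(n_patients = 1000L,
                        intercept = -1.0,
                        beta_age = 0.50,
                        beta_bmi = 0.40,
                        beta_comorbidity = 1.00,
                        beta_gender = -0.30,
                        age_range = c(20, 85),
                        bmi_mean = 27,
                        bmi_sd = 5,
                        bmi_clip = c(16, 45),
                        comorbidity_prevalence = 0.35,
                        male_fraction = 0.5,
                        seed = 42L) {
  spec <- list(n_patients = n_patients, intercept = intercept,
               beta_age = beta_age, beta_bmi = beta_bmi,
               beta_comorbidity = beta_comorbidity, beta_gender = beta_gender,
               age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               bmi_clip = bmi_clip,
               comorbidity_prevalence = comorbidity_prevalence,
               male_fraction = male_fraction, seed = seed)
  validate_cohort_spec(spec)
  spec$n_patients <- as.integer(n_patients)
  spec$seed <- as.integer(seed)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why)
    stop(sprintf("invalid cohort spec field '%s': %s", field, why), call. = FALSE)
  num1 <- function(field) {
    x <- spec[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      fail(field, "must be a finite numeric scalar")
    }
    x
  }
  n <- num1("n_patients")
  if (n < 1 || n != floor(n)) fail("n_patients", "must be an integer >= 1")
  for (f in c("intercept", "beta_age", "beta_bmi", "beta_comorbidity",
              "beta_gender", "bmi_mean")) num1(f)
  if (num1("bmi_sd") <= 0) fail("bmi_sd", "must be > 0")
  for (f in c("comorbidity_prevalence", "male_fraction")) {
    p <- num1(f)
    if (p < 0 || p > 1) fail(f, "must be a probability in [0, 1]")
  }
  for (f in c("age_range", "bmi_clip")) {
    x <- spec[[f]]
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
      fail(f, "must be a finite numeric vector of length 2")
    }
    if (x[1] >= x[2]) fail(f, "lower bound must be below upper bound")
  }
  s <- num1("seed")
  if (s != floor(s)) fail("seed", "must be an integer")
  invisible(TRUE)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic readmission cohort spec\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  log-odds: intercept %.3g, age %.3g/SD, bmi %.3g/SD, comorbidity %.3g, gender(male) %.3g\n",
              x$intercept, x$beta_age, x$beta_bmi, x$beta_comorbidity, x$beta_gender))
  cat(sprintf("  age ~ U[%g, %g]; bmi ~ N(%g, %g^2) clipped to [%g, %g]\n",
              x$age_range[1], x$age_range[2], x$bmi_mean, x$bmi_sd,
              x$bmi_clip[1], x$bmi_clip[2]))
  cat(sprintf("  P(comorbidity) = %g; P(male) = %g\n",
              x$comorbidity_prevalence, x$male_fraction))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic patient cohort
#'
#' Draws features and the 30-day readmission outcome per the cohort spec's
#' logistic data-generating process. Age and BMI are standardized to
#' z-scores over the full generated cohort (post-clip for BMI) before the
#' outcome is generated, and models downstream are fit on the same
#' standardized columns. Feature draws, and outcome draws use separate
#' named substreams of \code{spec$seed}, so the same features are obtained
#' regardless of what is done with the outcomes.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A \code{cohort}: a data.frame with columns \code{patient_id},
#'   \code{age}, \code{bmi}, \code{comorbidity}, \code{gender},
#'   \code{age_std}, \code{bmi_std}, \code{outcome}, carrying the spec and
#'   standardization moments as attributes.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  n <- spec$n_patients
  feats <- with_seed(substream_seed(spec$seed, "features"), {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    bmi <- pmin(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd),
                     spec$bmi_clip[1]), spec$bmi_clip[2])
    comorbidity <- stats::rbinom(n, 1L, spec$comorbidity_prevalence)
    gender <- stats::rbinom(n, 1L, spec$male_fraction)
    list(age = age, bmi = bmi, comorbidity = comorbidity, gender = gender)
  })
  moments <- list(age_mean = mean(feats$age),
                  age_sd = if (n > 1) stats::sd(feats$age) else 1,
                  bmi_mean = mean(feats$bmi),
                  bmi_sd = if (n > 1) stats::sd(feats$bmi) else 1)
  age_std <- (feats$age - moments$age_mean) / moments$age_sd
  bmi_std <- (feats$bmi - moments$bmi_mean) / moments$bmi_sd
  lp <- spec$intercept + spec$beta_age * age_std + spec$beta_bmi * bmi_std +
    spec$beta_comorbidity * feats$comorbidity + spec$beta_gender * feats$gender
  outcome <- with_seed(substream_seed(spec$seed, "outcome"),
                       stats::rbinom(n, 1L, sigmoid(lp)))
  cohort <- data.frame(
    patient_id = sprintf("P%0*d", max(4L, nchar(n)), seq_len(n)),
    age = feats$age, bmi = feats$bmi,
    comorbidity = feats$comorbidity, gender = feats$gender,
    age_std = age_std, bmi_std = bmi_std, outcome = outcome,
    stringsAsFactors = FALSE)
  attr(cohort, "spec") <- spec
  attr(cohort, "moments") <- moments
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic readmission cohort: %d patients (seed %s)\n",
              nrow(x), if (is.null(spec)) "?" else spec$seed))
  cat(sprintf("  outcome prevalence: %.3f; male fraction: %.3f; comorbidity: %.3f\n",
              mean(x$outcome), mean(x$gender), mean(x$comorbidity)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Deterministic outcome-stratified train/test split
#'
#' Allocates each outcome class to the test set in proportion
#' \code{test_fraction} using largest-remainder rounding against the total
#' test size \code{round(n * test_fraction)}, then samples patients within
#' class. This preserves class balance: train and test prevalence differ
#' from the overall prevalence by at most one patient's worth.
#'
#' @param cohort a \code{cohort} (or data.frame with \code{patient_id} and
#'   the stratification column).
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed for the within-class sampling.
#' @param stratify_on column to stratify on (default "outcome").
#' @return A \code{split_indices} list with \code{train_ids},
#'   \code{test_ids}, \code{stratify_on}, \code{test_fraction}, \code{seed}.
#' @export
stratified_split <- function(cohort, test_fraction = 0.3, seed = 42L,
                             stratify_on = "outcome") {
  stopifnot(is.numeric(test_fraction), length(test_fraction) == 1L,
            test_fraction > 0, test_fraction < 1)
  if (!stratify_on %in% names(cohort)) {
    stop(sprintf("stratification column '%s' not found", stratify_on))
  }
  y <- cohort[[stratify_on]]
  ids <- cohort$patient_id
  if (is.null(ids)) ids <- as.character(seq_len(nrow(cohort)))
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(sizes < 2L)) {
    stop("cannot stratify: a class has fewer than 2 members")
  }
  n <- length(y)
  total_test <- as.integer(round(n * test_fraction))
  quota <- sizes * test_fraction
  base <- floor(quota)
  rem <- quota - base
  extra <- total_test - sum(base)
  take <- as.integer(base)
  if (extra > 0) {
    # largest remainders first; ties broken by class order for determinism
    ord <- order(-rem, seq_along(classes))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  }
  test_ids <- with_seed(as.integer(seed %% .Machine$integer.max), {
    unlist(lapply(seq_along(classes), function(i) {
      pool <- ids[y == classes[i]]
      pool[sample.int(length(pool), take[i])]
    }), use.names = FALSE)
  })
  structure(list(train_ids = sort(setdiff(ids, test_ids)),
                 test_ids = sort(test_ids),
                 stratify_on = stratify_on,
                 test_fraction = test_fraction,
                 seed = as.integer(seed %% .Machine$integer.max)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("Stratified split on '%s': %d train / %d test (test fraction %g, seed %d)\n",
              x$stratify_on, length(x$train_ids), length(x$test_ids),
              x$test_fraction, x$seed))
  invisible(x)
}

cohort_columns <- c("patient_id", "age", "bmi", "comorbidity", "gender",
                    "age_std", "bmi_std", "outcome")

#' Write a cohort to CSV with a JSON metadata sidecar
#'
#' Numeric columns are written with 17 significant digits so that
#' \code{read_cohort(write_cohort(x))} reproduces integers bit-exactly and
#' reals to full double precision. The generating spec and standardization
#' moments go to \code{<path>.meta.json}.
#'
#' @param cohort a \code{cohort}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  out <- as.data.frame(cohort)[cohort_columns]
  for (col in c("age", "bmi", "age_std", "bmi_std")) {
    out[[col]] <- vapply(out[[col]], shortest_double, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  spec <- attr(cohort, "spec")
  meta <- list(spec = if (is.null(spec)) NULL else unclass(spec),
               moments = attr(cohort, "moments"),
               n_patients = nrow(cohort))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a cohort written by \code{write_cohort}
#'
#' @param path CSV path; the sidecar \code{<path>.meta.json} is read if
#'   present.
#' @return A \code{cohort}.
#' @export
read_cohort <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing <- setdiff(cohort_columns, header)
  if (length(missing)) {
    stop(sprintf("malformed cohort file: missing column(s) %s",
                 paste(sQuote(missing), collapse = ", ")))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  x <- raw[cohort_columns]
  for (col in setdiff(cohort_columns, "patient_id")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad)) {
      stop(sprintf("parse error in column '%s' at data row %d: %s",
                   col, bad[1], sQuote(x[[col]][bad[1]])))
    }
    x[[col]] <- v
  }
  for (col in c("comorbidity", "gender", "outcome")) x[[col]] <- as.integer(x[[col]])
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::fromJSON(metapath, simplifyVector = TRUE)
    if (!is.null(meta$spec)) {
      attr(x, "spec") <- structure(meta$spec, class = "cohort_spec")
    }
    attr(x, "moments") <- meta$moments
  }
  class(x) <- c("cohort", "data.frame")
  x
}
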