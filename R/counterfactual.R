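#' Decision-boundary cases
#'
#' Cases whose predicted probability lies within \code{margin} of the 0.5
#' classification threshold, inclusive on both sides: the band
#' [0.5 - margin, 0.5 + margin].
#'
#' @param model a fitted audit model.
#' @param data cases to score (data.frame with model features; a
#'   \code{patient_id} column is used for ids when present).
#' @param margin half-width of the boundary band (default 0.15).
#' @return Integer row indices of boundary cases within \code{data}, with
#'   the scored probabilities attached as attribute "prob".
#' @export
boundary_cases <- function(model, data, margin = 0.15) {
  stopifnot(is.numeric(margin), length(margin) == 1L, margin >= 0)
  prob <- predict(model, data)
  idx <- which(prob >= 0.5 - margin & prob <= 0.5 + margin)
  attr(idx, "prob") <- prob
  idx
}

#' Counterfactual gender-flip audit of boundary cases
#'
#' Measures gender's direct influence on borderline decisions: for every
#' boundary case the gender bit is inverted (both directions, female to
#' male and male to female), all other features are left untouched, the
#' model is re-scored, and class changes at threshold 0.5 are counted.
#' Refuses models that do not use gender as an input.
#'
#' @param model a fitted audit model with "gender" among its features.
#' @param data cases to audit.
#' @param margin boundary band half-width (default 0.15); ignored when
#'   \code{case_idx} is supplied.
#' @param case_idx optional row indices to audit instead of the computed
#'   boundary set.
#' @return A \code{counterfactual_result}: threshold, margin, n_boundary,
#'   n_flipped, flip_fraction and per-case records.
#' @export
gender_flip_audit <- function(model, data, margin = 0.15, case_idx = NULL) {
  if (!"gender" %in% model$features) {
    stop("model was fit without 'gender'; counterfactual gender flips are undefined")
  }
  prob_all <- predict(model, data)
  if (is.null(case_idx)) {
    case_idx <- which(prob_all >= 0.5 - margin & prob_all <= 0.5 + margin)
  }
  n_b <- length(case_idx)
  ids <- if ("patient_id" %in% names(data)) data$patient_id[case_idx]
         else as.character(case_idx)
  if (n_b == 0) {
    cases <- data.frame(patient_id = character(0), original_prob = numeric(0),
                        flipped_prob = numeric(0), original_class = integer(0),
                        flipped_class = integer(0), flipped = logical(0))
  } else {
    flipped_data <- as.data.frame(data)[case_idx, , drop = FALSE]
    flipped_data$gender <- 1 - flipped_data$gender
    prob_flip <- predict(model, flipped_data)
    cases <- data.frame(patient_id = ids,
                        original_prob = unname(prob_all[case_idx]),
                        flipped_prob = unname(prob_flip),
                        original_class = as.integer(prob_all[case_idx] >= 0.5),
                        flipped_class = as.integer(prob_flip >= 0.5),
                        stringsAsFactors = FALSE)
    cases$flipped <- cases$original_class != cases$flipped_class
  }
  structure(list(threshold = 0.5, margin = margin,
                 n_boundary = n_b, n_flipped = sum(cases$flipped),
                 flip_fraction = if (n_b > 0) mean(cases$flipped) else NA_real_,
                 cases = cases),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat(sprintf("Counterfactual gender-flip audit (|p - 0.5| <= %.2f): %d of %d boundary cases flipped class (%.1f%%)\n",
              x$margin, x$n_flipped, x$n_boundary,
              100 * x$flip_fraction))
  invisible(x)
}

#' @export
as_afpr_block.counterfactual_result <- function(x) {
  list(kind = "counterfactual_gender_flip", threshold = x$threshold,
       margin = x$margin, n_boundary = x$n_boundary,
       n_flipped = x$n_flipped,
       flip_fraction = if (is.na(x$flip_fraction)) NULL else x$flip_fraction,
       cases = lapply(seq_len(nrow(x$cases)), function(i) {
         r <- x$cases[i, ]
         list(patient_id = r$patient_id, original_prob = r$original_prob,
              flipped_prob = r$flipped_prob,
              original_class = r$original_class,
              flipped_class = r$flipped_class)
       }))
}
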