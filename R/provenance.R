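#' Score one patient and log the full decision mechanism
#'
#' Produces the prediction together with a provenance record describing
#' exactly how the model arrived at it. For the logistic model the record
#' holds the intercept term, every per-feature contribution
#' \eqn{c_j = w_j x_j} and the logit, which satisfy
#' \eqn{w_0 + \sum_j c_j = logit} to machine precision. For the forest it
#' holds every tree's decision path (node, feature, threshold, branch),
#' each tree's leaf probability and vote at threshold 0.5, the
#' positive-vote fraction, and a snapshot of the global importances.
#' Class is 1 iff probability >= 0.5.
#'
#' @param model a \code{logistic_audit} or \code{forest_audit}.
#' @param patient a one-row data.frame (or coercible list) with all model
#'   features; a \code{patient_id} column is carried into the record.
#' @param clock a zero-argument function returning the timestamp string;
#'   see \code{\link{afpr_clock}}.
#' @return list(probability, class, provenance) where provenance is a
#'   \code{prediction_provenance} list.
#' @export
predict_with_provenance <- function(model, patient, clock = afpr_clock()) {
  UseMethod("predict_with_provenance")
}

provenance_inputs <- function(model, patient) {
  patient <- as.data.frame(patient)
  stopifnot(nrow(patient) == 1L)
  miss <- setdiff(model$features, names(patient))
  if (length(miss)) {
    stop("patient is missing model feature(s): ", paste(miss, collapse = ", "))
  }
  x <- as.list(patient[1, model$features, drop = FALSE])
  pid <- if ("patient_id" %in% names(patient)) patient$patient_id[1] else NA_character_
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && is.finite(v), logical(1))]
  if (length(bad)) stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  list(x = x, patient_id = pid)
}

#' @export
predict_with_provenance.logistic_audit <- function(model, patient,
                                                   clock = afpr_clock()) {
  inp <- provenance_inputs(model, patient)
  w <- model$coefficients
  contributions <- unlist(inp$x) * w[model$features]
  logit <- unname(w[["(intercept)"]] + sum(contributions))
  prob <- sigmoid(logit)
  cls <- as.integer(prob >= 0.5)
  prov <- structure(list(
    patient_id = inp$patient_id,
    model_version = model$model_version,
    model_class = "logistic",
    timestamp = clock(),
    inputs = inp$x,
    mechanism = list(intercept = unname(w[["(intercept)"]]),
                     contributions = as.list(contributions),
                     logit = logit),
    probability = unname(prob),
    predicted_class = cls,
    threshold = 0.5), class = "prediction_provenance")
  list(probability = unname(prob), class = cls, provenance = prov)
}

#' @export
predict_with_provenance.forest_audit <- function(model, patient,
                                                 clock = afpr_clock()) {
  inp <- provenance_inputs(model, patient)
  replays <- lapply(model$trees, replay_tree_path, x = inp$x)
  tree_p1 <- vapply(replays, `[[`, numeric(1), "p1")
  votes <- as.integer(tree_p1 >= 0.5)
  prob <- mean(tree_p1)
  cls <- as.integer(prob >= 0.5)
  paths <- lapply(replays, function(r) {
    list(steps = lapply(seq_len(nrow(r$path)), function(i) {
      list(node = r$path$node[i], feature = r$path$feature[i],
           threshold = r$path$threshold[i], branch = r$path$branch[i])
    }), leaf = r$leaf)
  })
  prov <- structure(list(
    patient_id = inp$patient_id,
    model_version = model$model_version,
    model_class = "forest",
    timestamp = clock(),
    inputs = inp$x,
    mechanism = list(tree_paths = paths,
                     tree_probabilities = as.list(tree_p1),
                     tree_votes = as.list(votes),
                     positive_vote_fraction = mean(votes),
                     importances = as.list(model$importances)),
    probability = prob,
    predicted_class = cls,
    threshold = 0.5), class = "prediction_provenance")
  list(probability = prob, class = cls, provenance = prov)
}

#' @export
print.prediction_provenance <- function(x, ...) {
  cat(sprintf("Prediction provenance (%s model %s...)\n", x$model_class,
              substr(x$model_version, 1, 12)))
  cat(sprintf("  patient: %s at %s\n", x$patient_id, x$timestamp))
  cat(sprintf("  probability %.4f -> class %d (threshold %.2f)\n",
              x$probability, x$predicted_class, x$threshold))
  if (x$model_class == "logistic") {
    cat(sprintf("  logit %.4f = intercept %.4f + contributions:\n",
                x$mechanism$logit, x$mechanism$intercept))
    print(round(unlist(x$mechanism$contributions), 4))
  } else {
    cat(sprintf("  %d trees; positive-vote fraction %.3f\n",
                length(x$mechanism$tree_votes),
                x$mechanism$positive_vote_fraction))
  }
  invisible(x)
}

#' Serialize a fitted model to a JSON archive
#'
#' The archive carries everything provenance replay needs (weights or full
#' tree structures, hyperparameters, importances, version hash) so logged
#' decisions can be re-verified without the fitting backend.
#'
#' @param model a fitted audit model.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "logistic_audit")) {
    list(class = "logistic_audit",
         coefficients = as.list(model$coefficients),
         features = model$features, outcome = model$outcome,
         config = model$config, converged = model$converged,
         n_iter = model$n_iter, n_train = model$n_train,
         model_version = model$model_version)
  } else if (inherits(model, "forest_audit")) {
    list(class = "forest_audit",
         trees = lapply(model$trees, function(t) as.list(t)),
         importances = as.list(model$importances),
         features = model$features, outcome = model$outcome,
         config = model$config, n_train = model$n_train,
         model_version = model$model_version)
  } else stop("unsupported model class")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' Read a model archive written by \code{write_model}
#'
#' @param path JSON archive path.
#' @return A \code{logistic_audit} or \code{forest_audit} (without a
#'   fitting backend; forest predictions replay the stored trees).
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chr <- function(x) unlist(x)
  if (obj$class == "logistic_audit") {
    structure(list(coefficients = unlist(obj$coefficients),
                   features = chr(obj$features), outcome = obj$outcome,
                   config = obj$config, converged = obj$converged,
                   n_iter = obj$n_iter, n_train = obj$n_train,
                   model_version = obj$model_version),
              class = "logistic_audit")
  } else if (obj$class == "forest_audit") {
    col <- function(t, nm, na) {
      out <- lapply(t[[nm]], function(v) if (is.null(v)) na else v)
      unlist(out)
    }
    trees <- lapply(obj$trees, function(t) {
      data.frame(node = col(t, "node", NA_integer_),
                 left = col(t, "left", NA_real_),
                 right = col(t, "right", NA_real_),
                 feature = as.character(col(t, "feature", NA_character_)),
                 threshold = as.numeric(col(t, "threshold", NA_real_)),
                 terminal = col(t, "terminal", NA),
                 p0 = as.numeric(col(t, "p0", NA_real_)),
                 p1 = as.numeric(col(t, "p1", NA_real_)),
                 stringsAsFactors = FALSE)
    })
    structure(list(trees = trees, importances = unlist(obj$importances),
                   features = chr(obj$features), outcome = obj$outcome,
                   config = obj$config, n_train = obj$n_train,
                   model_version = obj$model_version,
                   ranger_fit = NULL),
              class = "forest_audit")
  } else stop("unknown model archive class: ", obj$class)
}
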