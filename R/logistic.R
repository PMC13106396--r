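#' Fit the L2-penalized logistic risk model
#'
#' Maximum penalized likelihood for the audited linear model
#' \eqn{\hat y = \sigma(w_0 + \sum_j w_j x_j)}. The objective is the
#' summed negative log-likelihood plus \eqn{\|w\|^2 / (2C)} on the feature
#' weights (intercept unpenalized), minimized by Newton iterations with
#' step halving. The fit is deterministic for fixed input.
#'
#' @param train a \code{cohort}, or any data.frame holding the model
#'   columns.
#' @param features character vector of feature column names; the default is
#'   the standardized clinical feature set including gender.
#' @param outcome name of the binary outcome column.
#' @param C inverse regularization strength (larger = weaker penalty).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the max absolute gradient.
#' @return A \code{logistic_audit} model: coefficients (intercept first),
#'   training config, convergence status and a \code{model_version}
#'   content hash of config + training-data fingerprint.
#' @seealso \code{\link{predict_with_provenance}}, \code{\link{fit_forest}}
#' @export
fit_logistic <- function(train,
                         features = c("age_std", "bmi_std", "comorbidity", "gender"),
                         outcome = "outcome",
                         C = 1.0, max_iter = 1000L, tol = 1e-4) {
  miss <- setdiff(c(features, outcome), names(train))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- train[[outcome]]
  if (length(unique(y)) < 2L) stop("training outcome has a single class; cannot fit")
  stopifnot(all(y %in% c(0, 1)))
  X <- cbind(`(intercept)` = 1, as.matrix(train[features]))
  p <- length(features)
  pen <- c(0, rep(1 / C, p)) # ridge on features only
  w <- numeric(p + 1L)
  converged <- FALSE
  iter <- 0L
  obj <- function(w) {
    eta <- drop(X %*% w)
    # numerically stable summed NLL: log(1+exp(eta)) - y*eta
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      sum(pen * w^2) / 2
  }
  f_old <- obj(w)
  polish <- 0L # one extra Newton step after the gradient criterion is met,
               # so the returned optimum is sharp to near machine precision
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% w)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(X, mu - y)) + pen * w
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      if (polish >= 1L) break
      polish <- polish + 1L
    }
    Wd <- mu * (1 - mu)
    H <- crossprod(X, X * Wd) + diag(pen, p + 1L)
    step <- solve(H, grad)
    # backtracking to guarantee descent
    alpha <- 1
    repeat {
      w_new <- w - alpha * step
      f_new <- obj(w_new)
      if (f_new <= f_old + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    w <- w_new
    f_old <- f_new
  }
  warn <- NULL
  if (!converged) {
    warn <- sprintf("logistic fit did not reach gradient tolerance %g in %d iterations",
                    tol, max_iter)
    warning(warn, call. = FALSE)
  }
  names(w) <- c("(intercept)", features)
  config <- list(model = "logistic", features = features, outcome = outcome,
                 C = C, max_iter = as.integer(max_iter), tol = tol)
  structure(list(coefficients = w, features = features, outcome = outcome,
                 config = config, converged = converged, n_iter = iter,
                 warning = warn,
                 n_train = nrow(train),
                 model_version = model_version_hash(config, train[c(features, outcome)])),
            class = "logistic_audit")
}

#' @export
coef.logistic_audit <- function(object, ...) object$coefficients

#' @export
print.logistic_audit <- function(x, ...) {
  cat(sprintf("L2-logistic audit model (C = %g, %s after %d iterations)\n",
              x$config$C, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(round(x$coefficients, 4))
  cat("model_version:", substr(x$model_version, 1, 12), "...\n")
  invisible(x)
}

#' @export
predict.logistic_audit <- function(object, newdata,
                                   type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(as.data.frame(newdata)[object$features]))
  eta <- drop(X %*% object$coefficients)
  switch(type,
         link = eta,
         response = sigmoid(eta),
         class = as.integer(sigmoid(eta) >= 0.5))
}

#' Content hash identifying a model build
#'
#' SHA-256 over the canonical JSON of the training configuration plus a
#' fingerprint of the training data, so the version is stable across
#' re-runs with identical config + data and differs when either changes.
#'
#' @param config list of training configuration values.
#' @param data training data (data.frame of the used columns).
#' @return 64-character hex string.
#' @keywords internal
model_version_hash <- function(config, data) {
  df <- as.data.frame(data)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) paste(sprintf("%.17g", as.numeric(col)), collapse = ",")
    else paste(as.character(col), collapse = ",")
  })
  names(cols) <- names(df)
  fp <- sha256_hex(canonical_json(list(nrow = nrow(df), columns = cols)))
  sha256_hex(canonical_json(list(config = config_for_hash(config),
                                 data_fingerprint = fp)))
}

config_for_hash <- function(config) {
  # encode NULL (unlimited depth) as an explicit sentinel so it hashes
  rapply(config, function(x) x, how = "replace")
}
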