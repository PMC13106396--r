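#' Fit the random-forest risk model with provenance-ready structure
#'
#' Trains a probability forest (bootstrap samples, Gini impurity splits,
#' random feature subsets per split; each leaf predicts its class
#' proportion and the ensemble probability is the mean over trees) and
#' extracts every tree's full structure so that decision paths can be
#' replayed, logged and verified without the fitting backend. Fitting is
#' backed by \pkg{ranger}; the stored per-tree node tables are the model
#' of record for provenance replay.
#'
#' @param train a \code{cohort} or data.frame.
#' @param features,outcome model columns, as in \code{\link{fit_logistic}}.
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth; \code{NULL} means unlimited
#'   (encoded as the sentinel 0 in configs and logs).
#' @param min_samples_split minimum node size eligible for splitting.
#' @param mtry features tried per split; default \code{ceiling(sqrt(p))}.
#' @param seed integer seed controlling bootstrap and split randomness.
#' @param bootstrap sample with replacement per tree (default TRUE).
#' @param sample_fraction fraction of rows sampled per tree.
#' @return A \code{forest_audit} model: per-tree node tables, normalized
#'   impurity importances, hyperparameters, \code{model_version} hash, and
#'   the backing ranger fit (dropped on JSON serialization).
#' @export
fit_forest <- function(train,
                       features = c("age_std", "bmi_std", "comorbidity", "gender"),
                       outcome = "outcome",
                       n_trees = 100L, max_depth = NULL,
                       min_samples_split = 2L, mtry = NULL,
                       seed = 42L, bootstrap = TRUE, sample_fraction = 1) {
  miss <- setdiff(c(features, outcome), names(train))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- train[[outcome]]
  if (length(unique(y)) < 2L) stop("training outcome has a single class; cannot fit")
  if (is.null(mtry)) mtry <- ceiling(sqrt(length(features)))
  depth_sentinel <- if (is.null(max_depth)) 0L else as.integer(max_depth)
  df <- as.data.frame(train)[c(features, outcome)]
  df[[outcome]] <- factor(df[[outcome]], levels = c(0, 1))
  fml <- stats::as.formula(paste(outcome, "~", paste(features, collapse = "+")))
  fit <- ranger::ranger(fml, data = df,
                        num.trees = as.integer(n_trees),
                        probability = TRUE,
                        importance = "impurity",
                        mtry = as.integer(mtry),
                        min.node.size = as.integer(min_samples_split),
                        max.depth = depth_sentinel,
                        replace = bootstrap,
                        sample.fraction = sample_fraction,
                        respect.unordered.factors = "ignore",
                        seed = as.integer(seed),
                        num.threads = 1L)
  trees <- lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    data.frame(node = ti$nodeID,
               left = ti$leftChild, right = ti$rightChild,
               feature = ti$splitvarName, threshold = ti$splitval,
               terminal = ti$terminal,
               p0 = ti$pred.0, p1 = ti$pred.1,
               stringsAsFactors = FALSE)
  })
  imp_raw <- fit$variable.importance[features]
  importances <- imp_raw / sum(imp_raw)
  config <- list(model = "forest", features = features, outcome = outcome,
                 n_trees = as.integer(n_trees), max_depth = depth_sentinel,
                 min_samples_split = as.integer(min_samples_split),
                 mtry = as.integer(mtry), bootstrap = bootstrap,
                 sample_fraction = sample_fraction, seed = as.integer(seed))
  structure(list(trees = trees, importances = importances,
                 features = features, outcome = outcome, config = config,
                 n_train = nrow(df),
                 model_version = model_version_hash(config, df),
                 ranger_fit = fit),
            class = "forest_audit")
}

#' @export
print.forest_audit <- function(x, ...) {
  cat(sprintf("Random-forest audit model: %d trees, max_depth %s, min_samples_split %d, mtry %d\n",
              x$config$n_trees,
              if (x$config$max_depth == 0) "unlimited" else x$config$max_depth,
              x$config$min_samples_split, x$config$mtry))
  cat("normalized impurity importances:\n")
  print(round(x$importances, 4))
  cat("model_version:", substr(x$model_version, 1, 12), "...\n")
  invisible(x)
}

#' @export
coef.forest_audit <- function(object, ...) object$importances

#' Replay one tree's decision path for one patient
#'
#' Traverses the stored node table: cases with feature value <= threshold
#' go left. Returns the visited internal nodes and the leaf probability.
#'
#' @param tree one stored tree (data.frame of nodes).
#' @param x named numeric vector of feature values.
#' @return list(path = data.frame(node, feature, threshold, branch),
#'   leaf = node id, p1 = leaf positive-class proportion).
#' @keywords internal
replay_tree_path <- function(tree, x) {
  node <- 1L # row index of nodeID 0
  steps_node <- integer(0); steps_feat <- character(0)
  steps_thr <- numeric(0); steps_branch <- character(0)
  while (!tree$terminal[node]) {
    f <- tree$feature[node]
    thr <- tree$threshold[node]
    go_left <- x[[f]] <= thr
    steps_node <- c(steps_node, tree$node[node])
    steps_feat <- c(steps_feat, f)
    steps_thr <- c(steps_thr, thr)
    steps_branch <- c(steps_branch, if (go_left) "left" else "right")
    node <- (if (go_left) tree$left[node] else tree$right[node]) + 1L
  }
  list(path = data.frame(node = steps_node, feature = steps_feat,
                         threshold = steps_thr, branch = steps_branch,
                         stringsAsFactors = FALSE),
       leaf = tree$node[node], p1 = tree$p1[node])
}

forest_tree_probs <- function(object, newdata) {
  X <- as.data.frame(newdata)[object$features]
  vapply(object$trees, function(tree) {
    vapply(seq_len(nrow(X)), function(i) {
      replay_tree_path(tree, as.list(X[i, , drop = FALSE]))$p1
    }, numeric(1))
  }, numeric(nrow(X)))
}

#' @export
predict.forest_audit <- function(object, newdata,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  if (!is.null(object$ranger_fit)) {
    p <- ranger::predictions(stats::predict(object$ranger_fit,
                                            data = as.data.frame(newdata),
                                            num.threads = 1L))[, "1"]
  } else {
    tp <- forest_tree_probs(object, newdata)
    p <- rowMeans(matrix(tp, ncol = length(object$trees)))
  }
  if (type == "class") as.integer(p >= 0.5) else unname(p)
}

#' Grid-search tuning of the forest by cross-validated ROC-AUC
#'
#' Evaluates every hyperparameter candidate with outcome-stratified k-fold
#' cross-validation on the training data, scoring mean area under the ROC
#' curve across folds, and selects the maximum (ties broken by row-major
#' grid order). The default grid is n_trees {50,100,200} x max_depth
#' {unlimited,10,20} x min_samples_split {2,5}: 18 candidates.
#'
#' @param train training data.
#' @param grid data.frame with columns \code{n_trees}, \code{max_depth}
#'   (0 = unlimited), \code{min_samples_split}; default the 18-candidate
#'   grid above.
#' @param cv_folds folds for the inner CV (default 3).
#' @param seed integer seed (fold assignment and per-fit seeds).
#' @param features,outcome model columns.
#' @return A \code{grid_search_result}: the grid with per-candidate mean
#'   CV AUC, the selected row, fold count and seed.
#' @export
tune_forest <- function(train, grid = default_forest_grid(), cv_folds = 3L,
                        seed = 42L,
                        features = c("age_std", "bmi_std", "comorbidity", "gender"),
                        outcome = "outcome") {
  stopifnot(nrow(grid) >= 1L,
            all(c("n_trees", "max_depth", "min_samples_split") %in% names(grid)))
  y <- train[[outcome]]
  folds <- make_stratified_folds(y, cv_folds, substream_seed(seed, "tune_folds"))
  df <- as.data.frame(train)[c(features, outcome)]
  df[[outcome]] <- factor(df[[outcome]], levels = c(0, 1))
  fml <- stats::as.formula(paste(outcome, "~", paste(features, collapse = "+")))
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_auc <- rep(NA_real_, cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- df[folds != f, , drop = FALSE]
      te <- df[folds == f, , drop = FALSE]
      if (length(unique(te[[outcome]])) < 2L || length(unique(tr[[outcome]])) < 2L) {
        warning(sprintf("tune_forest: fold %d has a single outcome class; skipped", f))
        next
      }
      # candidate scoring needs only the probabilities, not the full
      # provenance structure, so fit the backend directly
      fit <- ranger::ranger(fml, data = tr,
                            num.trees = grid$n_trees[g],
                            probability = TRUE,
                            mtry = ceiling(sqrt(length(features))),
                            min.node.size = grid$min_samples_split[g],
                            max.depth = grid$max_depth[g],
                            seed = substream_seed(seed, "tune_fit",
                                                  (g - 1L) * cv_folds + f),
                            num.threads = 1L)
      p <- ranger::predictions(stats::predict(fit, data = te,
                                              num.threads = 1L))[, "1"]
      fold_auc[f] <- auc_score(as.integer(as.character(te[[outcome]])), p)
    }
    scores[g] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(scores) # which.max takes the first maximum: row-major tie-break
  out <- grid
  out$mean_cv_auc <- scores
  structure(list(grid = out, selected = grid[best, , drop = FALSE],
                 selected_index = best, best_score = scores[best],
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Forest grid search: %d candidates, %d-fold CV on ROC-AUC\n",
              nrow(x$grid), x$cv_folds))
  cat(sprintf("selected: n_trees=%d, max_depth=%s, min_samples_split=%d (mean CV AUC %.3f)\n",
              x$selected$n_trees,
              if (x$selected$max_depth == 0) "unlimited" else x$selected$max_depth,
              x$selected$min_samples_split, x$best_score))
  invisible(x)
}

#' The 18-candidate forest tuning grid
#'
#' @return data.frame of n_trees {50,100,200} x max_depth {0 (unlimited),
#'   10, 20} x min_samples_split {2,5}, in row-major order.
#' @export
default_forest_grid <- function() {
  expand.grid(min_samples_split = c(2L, 5L),
              max_depth = c(0L, 10L, 20L),
              n_trees = c(50L, 100L, 200L))[, c("n_trees", "max_depth", "min_samples_split")]
}

make_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Refit a model without one input feature
#'
#' Ablation used to test whether excluding the protected attribute removes
#' disparity. The refit model's provenance carries no term for the
#' excluded feature.
#'
#' @param model a fitted \code{logistic_audit} or \code{forest_audit}.
#' @param train training data to refit on.
#' @param excluded name of the feature to drop.
#' @return A model of the same class fit on the reduced feature set.
#' @export
refit_without_feature <- function(model, train, excluded) {
  if (!excluded %in% model$features) {
    stop(sprintf("feature '%s' is not in the model's feature set", excluded))
  }
  keep <- setdiff(model$features, excluded)
  if (!length(keep)) stop("cannot exclude all features")
  if (inherits(model, "logistic_audit")) {
    fit_logistic(train, features = keep, outcome = model$outcome,
                 C = model$config$C, max_iter = model$config$max_iter,
                 tol = model$config$tol)
  } else if (inherits(model, "forest_audit")) {
    cfg <- model$config
    fit_forest(train, features = keep, outcome = model$outcome,
               n_trees = cfg$n_trees,
               max_depth = if (cfg$max_depth == 0) NULL else cfg$max_depth,
               min_samples_split = cfg$min_samples_split,
               mtry = min(cfg$mtry, length(keep)),
               seed = cfg$seed, bootstrap = cfg$bootstrap,
               sample_fraction = cfg$sample_fraction)
  } else {
    stop("unsupported model class: ", class(model)[1])
  }
}
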