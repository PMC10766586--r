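#' Enumerate the eight ensemble model paths
#'
#' The ensemble is the full cross of the two compositional transforms
#' (l1, clr) with the four feature strategies (lasso, adaptive lasso, CFS,
#' full feature set), in a fixed deterministic order: l1 before clr, and
#' within each transform lasso, alasso, cfs, full. Path ids run 1..8.
#'
#' @return A data.frame with columns `path_id`, `transform_tag`,
#'   `selector_tag` and 8 rows.
#' @export
build_paths <- function() {
  grid <- expand.grid(selector_tag = c("lasso", "alasso", "cfs", "full"),
                      transform_tag = c("l1", "clr"),
                      stringsAsFactors = FALSE)
  data.frame(path_id = seq_len(nrow(grid)),
             transform_tag = grid$transform_tag,
             selector_tag = grid$selector_tag,
             stringsAsFactors = FALSE)
}

.path_label <- function(path) paste(path$transform_tag, path$selector_tag, sep = "_")

.transform_values <- function(ft, tag, pseudocount) {
  switch(tag,
         l1  = l1_normalize(ft)$values,
         clr = clr_transform(ft, pseudocount)$values,
         stop("unknown transform tag: ", tag))
}

.run_selector <- function(tag, X, y, seed, gamma, cfs_stall) {
  switch(tag,
         lasso  = lasso_select(X, y, seed = seed),
         alasso = adaptive_lasso_select(X, y, gamma = gamma, seed = seed),
         cfs    = cfs_select(X, y, stall_limit = cfs_stall),
         full   = .selection_result("full", colnames(X)),
         stop("unknown selector tag: ", tag))
}

#' Pooled leave-one-out performance metrics
#'
#' R-squared and mean squared error of the n held-out LOOCV predictions,
#' pooled into single numbers: `r2 = 1 - SS_res / SS_tot` with `SS_tot`
#' taken about the mean of the observed targets, and `mse` the mean squared
#' residual. A per-fold R-squared is undefined for a single test sample, so
#' pooling is the only option. `r2` can be negative (worse than predicting
#' the mean); it is never greater than 1.
#'
#' @param y Observed targets.
#' @param yhat Held-out predictions, aligned with `y`.
#' @return List with `r2` and `mse`.
#' @export
pooled_r2_mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("target is constant; R-squared is undefined")
  ss_res <- sum((y - yhat)^2)
  list(r2 = 1 - ss_res / ss_tot, mse = mean((y - yhat)^2))
}

.fit_forest <- function(X, y, n_trees, seed) {
  ranger::ranger(x = as.data.frame(X), y = y,
                 num.trees = n_trees,
                 mtry = max(1L, floor(ncol(X) / 3)),
                 importance = "impurity",
                 seed = seed, num.threads = 1)
}

.forest_predict <- function(fit, X) {
  predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
}

# Precompute per-fold and whole-data selector outputs for both transforms.
# Selections depend only on the data and the selection seed -- not on the
# forest seed -- so robustness protocols that vary only the forest seed can
# reuse them.
.ensemble_selections <- function(Xl1, Xclr, y, seed, gamma, cfs_stall) {
  n <- nrow(Xl1)
  tabs <- list(l1 = Xl1, clr = Xclr)
  out <- list()
  for (tr in names(tabs)) {
    X <- tabs[[tr]]
    out[[tr]] <- list()
    for (sel in c("lasso", "alasso", "cfs", "full")) {
      full <- .run_selector(sel, X, y, seed, gamma, cfs_stall)
      folds <- lapply(seq_len(n), function(i) {
        if (sel == "full") return(colnames(X))
        .run_selector(sel, X[-i, , drop = FALSE], y[-i],
                      seed + i, gamma, cfs_stall)$selected
      })
      out[[tr]][[sel]] <- list(full = full, folds = folds)
    }
  }
  out
}

#' Leave-one-out cross-validation of one model path
#'
#' For each sample i the path's transform is applied, its selector is run on
#' the n-1 training samples only (the held-out sample never influences
#' selection), a random-forest regressor is trained on the selected features
#' (all features for the `full` strategy) and predicts sample i. The n
#' held-out predictions are pooled into R-squared and MSE via
#' [pooled_r2_mse()]. A fold in which the selector returns no features falls
#' back to the training-target mean as a constant prediction (logged).
#'
#' @param path One row of [build_paths()] (a list/data.frame row with
#'   `path_id`, `transform_tag`, `selector_tag`).
#' @param ft A [feature_table()], sample-aligned with `tv`.
#' @param tv A [target_vector()].
#' @param seed Integer; selector CV folds use `seed + fold`, forests use
#'   `seed + 1000 * path_id + fold`.
#' @param n_trees Trees per random forest (default 500).
#' @param gamma Adaptive-lasso weight exponent.
#' @param pseudocount clr pseudocount.
#' @param cfs_stall CFS best-first stall limit.
#' @param fold_selected Optional precomputed list of per-fold selected
#'   feature-id vectors (length n); when given, selectors are not re-run.
#' @return List with `r2`, `mse`, `predictions` (named by sample),
#'   `fold_selected`, and `empty_folds` (indices that fell back to the
#'   training mean).
#' @export
loocv_evaluate <- function(path, ft, tv, seed = 42, n_trees = 500,
                           gamma = 1, pseudocount = 1, cfs_stall = 5,
                           fold_selected = NULL) {
  y <- as.numeric(tv)
  n <- length(y)
  if (n < 5) stop("need at least 5 samples for LOOCV")
  X <- .transform_values(ft, path$transform_tag, pseudocount)
  preds <- numeric(n)
  empty <- integer(0)
  sel_out <- vector("list", n)
  for (i in seq_len(n)) {
    feats <- if (!is.null(fold_selected)) fold_selected[[i]] else
      .run_selector(path$selector_tag, X[-i, , drop = FALSE], y[-i],
                    seed + i, gamma, cfs_stall)$selected
    sel_out[[i]] <- feats
    if (length(feats) == 0) {
      preds[i] <- mean(y[-i])
      empty <- c(empty, i)
    } else {
      fit <- .fit_forest(X[-i, feats, drop = FALSE], y[-i], n_trees,
                         seed + 1000L * path$path_id + i)
      preds[i] <- .forest_predict(fit, X[i, feats, drop = FALSE])
    }
  }
  names(preds) <- names(tv)
  perf <- pooled_r2_mse(y, preds)
  if (length(empty) > 0)
    message(sprintf("[%s] %d LOOCV fold(s) had an empty selection; used training-mean prediction",
                    .path_label(path), length(empty)))
  list(r2 = perf$r2, mse = perf$mse, predictions = preds,
       fold_selected = sel_out, empty_folds = empty)
}

#' Whole-data fit of one model path
#'
#' Runs the path's selector on all n samples, trains a random forest on the
#' selected features, and reports impurity-based importances normalized to
#' sum to one (features outside the selected set have importance exactly 0).
#' For the lasso/alasso paths the penalized fit's nonzero coefficients and
#' intercept (original predictor scale) are recorded; these whole-data fits
#' supply the direction-of-association coefficients, while predictive
#' performance always comes from [loocv_evaluate()].
#'
#' @inheritParams loocv_evaluate
#' @param loocv Optional precomputed result of [loocv_evaluate()] for this
#'   path; computed if missing.
#' @param selection Optional precomputed `selection_result` for the whole
#'   data.
#' @return A `path_result`: list with `path`, `r2`, `mse`, `predictions`,
#'   `selected`, `importance` (named over all features), `coefficients`,
#'   `intercept`, `seed`.
#' @export
fit_path_full <- function(path, ft, tv, seed = 42, n_trees = 500,
                          gamma = 1, pseudocount = 1, cfs_stall = 5,
                          loocv = NULL, selection = NULL) {
  y <- as.numeric(tv)
  X <- .transform_values(ft, path$transform_tag, pseudocount)
  if (is.null(selection))
    selection <- .run_selector(path$selector_tag, X, y, seed, gamma, cfs_stall)
  if (is.null(loocv))
    loocv <- loocv_evaluate(path, ft, tv, seed = seed, n_trees = n_trees,
                            gamma = gamma, pseudocount = pseudocount,
                            cfs_stall = cfs_stall)
  feats <- selection$selected
  importance <- setNames(rep(0, ncol(X)), colnames(X))
  if (length(feats) > 0) {
    fit <- .fit_forest(X[, feats, drop = FALSE], y, n_trees,
                       seed + 1000L * path$path_id)
    imp <- fit$variable.importance
    if (sum(imp) > 0) imp <- imp / sum(imp)
    importance[names(imp)] <- imp
  } else {
    message(sprintf("[%s] whole-data selection is empty; all importances 0",
                    .path_label(path)))
  }
  structure(list(path = path,
                 r2 = loocv$r2, mse = loocv$mse,
                 predictions = loocv$predictions,
                 selected = feats,
                 importance = importance,
                 coefficients = if (path$selector_tag %in% c("lasso", "alasso"))
                   selection$coefficients else NULL,
                 intercept = if (path$selector_tag %in% c("lasso", "alasso"))
                   selection$intercept else NULL,
                 seed = seed),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result:%s> LOOCV R2 = %.4f, MSE = %.4g, %d feature(s) selected\n",
              .path_label(x$path), x$r2, x$mse, length(x$selected)))
  invisible(x)
}
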