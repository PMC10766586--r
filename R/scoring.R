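.is_chosen <- function(feature, res) {
  if (res$path$selector_tag == "full") {
    isTRUE(res$importance[feature] > 0)
  } else {
    feature %in% res$selected
  }
}

#' Number of model paths that chose a feature
#'
#' A feature is "chosen" by a subset path (lasso, alasso, cfs) when it is in
#' that path's selected set, and by a full-feature path when its random
#' forest importance is positive (the full paths would otherwise trivially
#' choose everything). The count lies in 0..8 and enters the score as the
#' robustness term m_k.
#'
#' @param feature A feature id.
#' @param results List of the 8 `path_result`s.
#' @return Integer in 0..8.
#' @export
model_count <- function(feature, results) {
  stopifnot(length(results) == 8)
  sum(vapply(results, function(r) .is_chosen(feature, r), logical(1)))
}

#' Aggregated per-feature score
#'
#' `score_k = (sum_t importance_kt * max(R2_t, 0)) / 8 * (m_k / 8)`, summing
#' over the 8 paths: each path contributes the feature's normalized
#' importance weighted by the path's pooled LOOCV R-squared, and the mean
#' contribution is scaled by the fraction of paths that chose the feature.
#' Negative LOOCV R-squared values are clamped to 0 so non-predictive paths
#' contribute nothing; with normalized importances this keeps the score in
#' [0, 1]. A feature chosen by no path scores exactly 0.
#'
#' @inheritParams model_count
#' @return Score in [0, 1].
#' @export
compute_score <- function(feature, results) {
  stopifnot(length(results) == 8)
  mk <- model_count(feature, results)
  if (mk == 0) return(0)
  contrib <- vapply(results, function(r) {
    if (!.is_chosen(feature, r)) return(0)
    imp <- r$importance[feature]
    if (is.na(imp)) imp <- 0
    imp * max(r$r2, 0)
  }, numeric(1))
  sum(contrib) / 8 * (mk / 8)
}

#' Rank all features by their aggregated score
#'
#' Computes the score and m_k for every feature in the common universe of
#' the 8 path results, sorts descending by score with ties broken by larger
#' m_k and then lexicographic feature id, and attaches the per-path
#' importances and the lasso/alasso whole-data coefficients.
#'
#' @param results List of the 8 `path_result`s over a common feature set.
#' @return A `score_table`: data.frame with columns `rank`, `feature_id`,
#'   `score`, `m_k`, one importance column `imp_<path>` per path and one
#'   coefficient column `coef_<path>` per lasso/alasso path; per-path
#'   metrics (`r2`, `mse`, `intercept`) are stored in the
#'   `"path_metrics"` attribute.
#' @export
rank_features <- function(results) {
  stopifnot(length(results) == 8)
  feats <- names(results[[1]]$importance)
  for (r in results) stopifnot(identical(names(r$importance), feats))

  score <- vapply(feats, compute_score, numeric(1), results = results)
  mk <- vapply(feats, model_count, numeric(1), results = results)
  labels <- vapply(results, function(r) .path_label(r$path), character(1))

  imp <- sapply(results, function(r) r$importance[feats])
  colnames(imp) <- paste0("imp_", labels)

  coef_paths <- which(vapply(results, function(r)
    r$path$selector_tag %in% c("lasso", "alasso"), logical(1)))
  cf <- sapply(results[coef_paths], function(r) {
    v <- setNames(rep(NA_real_, length(feats)), feats)
    if (length(r$coefficients) > 0) v[names(r$coefficients)] <- r$coefficients
    v
  })
  colnames(cf) <- paste0("coef_", labels[coef_paths])

  ord <- order(-score, -mk, feats)
  st <- data.frame(rank = seq_along(feats),
                   feature_id = feats[ord],
                   score = score[ord],
                   m_k = as.integer(mk[ord]),
                   imp[ord, , drop = FALSE],
                   cf[ord, , drop = FALSE],
                   row.names = NULL,
                   check.names = FALSE,
                   stringsAsFactors = FALSE)
  metrics <- data.frame(path = labels,
                        r2 = vapply(results, function(r) r$r2, numeric(1)),
                        mse = vapply(results, function(r) r$mse, numeric(1)),
                        intercept = vapply(results, function(r)
                          if (is.null(r$intercept)) NA_real_ else r$intercept,
                          numeric(1)),
                        stringsAsFactors = FALSE)
  attr(st, "path_metrics") <- metrics
  class(st) <- c("score_table", "data.frame")
  st
}

#' @export
print.score_table <- function(x, n = 10, ...) {
  cat(sprintf("<score_table> %d features ranked by aggregated score\n", nrow(x)))
  print.data.frame(head(x[, c("rank", "feature_id", "score", "m_k")], n),
                   row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

.fmt6 <- function(v) {
  ifelse(is.na(v), "", vapply(v, function(x)
    format(signif(x, 6), scientific = FALSE, trim = TRUE), character(1)))
}

#' Write the ranked ensemble report
#'
#' Wide CSV mirroring the standard output layout: a header block of three
#' rows (pooled LOOCV R-squared per path, MSE per path, intercepts — blank
#' for the cfs/full paths, which fit no linear model), followed by one row
#' per feature in rank order with its score, m_k, the 8 per-path
#' importances and the lasso/alasso coefficients. Numbers carry 6
#' significant digits.
#'
#' @param st A `score_table` from [rank_features()].
#' @param results The list of 8 `path_result`s used to build it.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(st, results, path) {
  labels <- vapply(results, function(r) .path_label(r$path), character(1))
  metrics <- attr(st, "path_metrics")
  imp_cols <- paste0("imp_", labels)
  coef_cols <- grep("^coef_", colnames(st), value = TRUE)

  header_cols <- c("row", "score", "m_k", labels,
                   sub("^coef_", "coef.", coef_cols))
  blank <- rep("", length(coef_cols))
  rows <- list(
    c("R2", "", "", .fmt6(metrics$r2), blank),
    c("MSE", "", "", .fmt6(metrics$mse), blank),
    c("Intercept", "", "", .fmt6(metrics$intercept), blank)
  )
  for (i in seq_len(nrow(st))) {
    rows[[length(rows) + 1L]] <- c(
      st$feature_id[i], .fmt6(st$score[i]), as.character(st$m_k[i]),
      .fmt6(unlist(st[i, imp_cols])), .fmt6(unlist(st[i, coef_cols])))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- header_cols
  ok <- tryCatch({
    write.table(m, path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to: ", path)
  invisible(path)
}

#' Write a tidy long-format report
#'
#' One row per (feature, path, metric): metrics are `importance` and,
#' where available, `coefficient`. Convenient for programmatic use and
#' plotting; the wide report from [write_report()] remains the primary
#' human-readable output.
#'
#' @inheritParams write_report
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_long <- function(st, results, path) {
  labels <- vapply(results, function(r) .path_label(r$path), character(1))
  recs <- list()
  for (j in seq_along(results)) {
    r <- results[[j]]
    recs[[length(recs) + 1L]] <- data.frame(
      feature = names(r$importance), path = labels[j],
      metric = "importance", value = as.numeric(r$importance),
      stringsAsFactors = FALSE)
    if (length(r$coefficients) > 0)
      recs[[length(recs) + 1L]] <- data.frame(
        feature = names(r$coefficients), path = labels[j],
        metric = "coefficient", value = as.numeric(r$coefficients),
        stringsAsFactors = FALSE)
  }
  recs[[length(recs) + 1L]] <- data.frame(
    feature = st$feature_id, path = "ensemble", metric = "score",
    value = st$score, stringsAsFactors = FALSE)
  out <- do.call(rbind, recs)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-read a wide report written by [write_report()]
#'
#' @param path Path to the CSV report.
#' @return List with `metrics` (R2/MSE/intercept per path) and `features`
#'   (the ranked feature block as a data.frame).
#' @export
read_report <- function(path) {
  raw <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  hdr <- raw[1:3, ]
  feat <- raw[-(1:3), ]
  num <- function(v) suppressWarnings(as.numeric(v))
  metrics <- data.frame(path = colnames(raw)[4:11],
                        r2 = num(unlist(hdr[1, 4:11])),
                        mse = num(unlist(hdr[2, 4:11])),
                        intercept = num(unlist(hdr[3, 4:11])),
                        stringsAsFactors = FALSE)
  features <- data.frame(feature_id = feat$row,
                         score = num(feat$score),
                         m_k = as.integer(feat$m_k),
                         stringsAsFactors = FALSE)
  for (cl in colnames(raw)[-(1:3)]) features[[cl]] <- num(feat[[cl]])
  list(metrics = metrics, features = features)
}
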