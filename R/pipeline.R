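#' Run the full ensemble on a feature table and target
#'
#' End-to-end single-tier run: sample alignment, optional taxonomic
#' aggregation, the two compositional transforms, per-path feature selection
#' inside every LOOCV fold, random-forest evaluation, whole-data fits for
#' importances and coefficients, scoring, and ranking.
#'
#' Selector outputs depend on the data and `seed` only; forests additionally
#' depend on `forest_seed` (default: same as `seed`). Robustness protocols
#' that vary only the forest seed can pass `selections` from a previous run
#' to avoid re-running the selectors.
#'
#' @param ft A [feature_table()].
#' @param tv A [target_vector()].
#' @param rank Optional taxonomic rank; when given the table is collapsed
#'   with [aggregate_to_rank()] after alignment.
#' @param pseudocount clr pseudocount (default 1 on raw counts).
#' @param seed Integer seed for feature-selection CV folds.
#' @param forest_seed Integer seed for the random forests.
#' @param n_trees Trees per forest (default 500).
#' @param gamma Adaptive-lasso weight exponent.
#' @param cfs_stall CFS best-first stall limit.
#' @param selections Optional precomputed selection cache from a previous
#'   run on identical data and `seed`.
#' @param out_dir Optional directory; when given, writes `report.csv`,
#'   `report_long.tsv` and `run_log.txt`.
#' @return A `taxassoc_run`: list with `score_table`, `results` (8
#'   `path_result`s), `paths`, `selections`, `config`.
#' @export
run_ensemble <- function(ft, tv, rank = NULL, pseudocount = 1,
                         seed = 42, forest_seed = seed, n_trees = 500,
                         gamma = 1, cfs_stall = 5, selections = NULL,
                         out_dir = NULL) {
  al <- align_samples(ft, tv)
  ft <- al$ft; tv <- al$tv
  if (!is.null(rank)) ft <- aggregate_to_rank(ft, rank)
  n <- nrow(ft$counts); p <- ncol(ft$counts)
  if (n < 20)
    warning(sprintf("only %d samples; results below ~20 samples warrant cautious interpretation", n),
            call. = FALSE)
  if (p > 1000)
    warning(sprintf("%d features; consider the two-tier workflow (aggregate first, then re-run on children of top-ranked taxa)", p),
            call. = FALSE)

  Xl1 <- l1_normalize(ft)$values
  Xclr <- clr_transform(ft, pseudocount)$values
  y <- as.numeric(tv)
  if (is.null(selections))
    selections <- .ensemble_selections(Xl1, Xclr, y, seed, gamma, cfs_stall)

  paths <- build_paths()
  results <- lapply(seq_len(nrow(paths)), function(j) {
    path <- as.list(paths[j, ])
    cache <- selections[[path$transform_tag]][[path$selector_tag]]
    cv <- loocv_evaluate(path, ft, tv, seed = forest_seed, n_trees = n_trees,
                         gamma = gamma, pseudocount = pseudocount,
                         cfs_stall = cfs_stall, fold_selected = cache$folds)
    fit_path_full(path, ft, tv, seed = forest_seed, n_trees = n_trees,
                  gamma = gamma, pseudocount = pseudocount,
                  cfs_stall = cfs_stall, loocv = cv, selection = cache$full)
  })
  st <- rank_features(results)
  config <- list(n_samples = n, n_features = p, rank = rank,
                 pseudocount = pseudocount, seed = seed,
                 forest_seed = forest_seed, n_trees = n_trees, gamma = gamma,
                 cfs_stall = cfs_stall,
                 package_version = as.character(utils::packageVersion("taxassoc")),
                 r_version = as.character(getRversion()))
  run <- structure(list(score_table = st, results = results, paths = paths,
                        selections = selections, config = config),
                   class = "taxassoc_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(st, results, file.path(out_dir, "report.csv"))
    write_report_long(st, results, file.path(out_dir, "report_long.tsv"))
    writeLines(paste(names(config), vapply(config, function(v)
      paste(format(v), collapse = " "), character(1)), sep = "="),
      file.path(out_dir, "run_log.txt"))
  }
  run
}

#' @export
print.taxassoc_run <- function(x, ...) {
  m <- attr(x$score_table, "path_metrics")
  cat(sprintf("<taxassoc_run> %d samples x %d features; best path %s (LOOCV R2 = %.4f)\n",
              x$config$n_samples, x$config$n_features,
              m$path[which.max(m$r2)], max(m$r2)))
  print(x$score_table, n = 5)
  invisible(x)
}

#' Two-tier workflow: rank families first, then their member ASVs
#'
#' Tier 1 collapses the table at `parent_rank` and runs the ensemble; the
#' `top_n_parents` highest-scoring real labels (the pooled
#' `Unclassified_<rank>` feature is not an eligible parent) define the
#' tier-2 universe: the child-level table restricted to their member
#' features, on which the ensemble runs independently. Recommended for
#' tables with more than ~1000 ASVs/OTUs, where a direct child-level run is
#' costly and noisy.
#'
#' @inheritParams run_ensemble
#' @param parent_rank Rank of tier 1 (default `"family"`).
#' @param top_n_parents Number of top parents carried to tier 2 (default 5).
#' @param out_dir Optional directory; tier reports are written to
#'   `tier1/` and `tier2/` subdirectories.
#' @param ... Passed to [run_ensemble()] for both tiers.
#' @return List with `parent` and `child` `taxassoc_run`s and the chosen
#'   `parents`.
#' @export
run_two_tier <- function(ft, tv, parent_rank = "family", top_n_parents = 5,
                         out_dir = NULL, ...) {
  if (top_n_parents < 1) stop("top_n_parents must be >= 1")
  tier1 <- run_ensemble(ft, tv, rank = parent_rank,
                        out_dir = if (is.null(out_dir)) NULL else
                          file.path(out_dir, "tier1"), ...)
  st <- tier1$score_table
  eligible <- st$feature_id[st$feature_id != paste0("Unclassified_", parent_rank)]
  if (length(eligible) < top_n_parents) {
    warning(sprintf("only %d labeled parent taxa available (requested %d); using all",
                    length(eligible), top_n_parents), call. = FALSE)
    top_n_parents <- length(eligible)
  }
  parents <- eligible[seq_len(top_n_parents)]
  child_ft <- filter_children_of(ft, parent_rank, parents)
  tier2 <- run_ensemble(child_ft, tv,
                        out_dir = if (is.null(out_dir)) NULL else
                          file.path(out_dir, "tier2"), ...)
  list(parent = tier1, child = tier2, parents = parents)
}
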