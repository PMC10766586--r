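#' Generate a sparse compositional count dataset with planted associations
#'
#' Emulates the shape of an amplicon study relating a microbial community
#' matrix to a continuous host trait: few samples, many features (p >> n),
#' sparse overdispersed counts, and a small planted set of features whose
#' (clr-scale) abundances drive the target. Latent per-sample abundances are
#' log-normal; background features additionally receive structural zeros at
#' rate `sparsity`; counts are drawn by multinomial sampling at a Poisson
#' library size.
#'
#' Planted features model a trait-associated consortium: they share a latent
#' community factor (per-sample standard normal) that enters their
#' log-abundance with unit loading — positively or negatively according to
#' the feature's sign — alongside unit independent log-scale noise, so
#' member taxa co-vary, as co-responding taxa do in real communities. The
#' target is the sum of the planted features' standardized clr abundances
#' (signed) plus Gaussian noise whose s.d. is set so that
#' `sd(signal) / sd(noise) = effect_size`; at the default `effect_size = 2`
#' the planted signal explains 80% of the target variance. The target is
#' then shifted/scaled to an ED50-like range (mean 35, s.d. 1 — degrees C in
#' the motivating application), which changes no downstream statistic.
#'
#' Planted features are modeled as prevalent, moderately abundant taxa
#' (baseline log-abundance N(1, 0.5), no structural zeros), the regime in
#' which a taxon--trait association is biologically observable; background
#' taxa get baseline N(0, 1.5). A toy two-rank taxonomy assigns the
#' informative features to a minority of families (4 per family, one sign
#' per family so that family-aggregated counts retain the association) and
#' spreads background features over the remaining families, with 5% left
#' unlabeled.
#'
#' @param n_samples,n_features,n_informative Dataset dimensions.
#' @param effect_size Signal-to-noise ratio of the planted association
#'   (s.d. of the planted signal in units of the target noise s.d.);
#'   0 gives a null dataset (target independent of the table).
#' @param sparsity Fraction of structural zeros among background features,
#'   in [0, 1).
#' @param library_size_mean Mean sequencing depth per sample.
#' @param n_families Families in the toy taxonomy.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `synthetic_dataset`: list with `table` (a [feature_table()]
#'   with taxonomy), `target` (a [target_vector()]), `truth` (data.frame
#'   feature_id / sign / effect_size), `seed`, `params`.
#' @export
generate_synthetic <- function(n_samples = 28, n_features = 150,
                               n_informative = 8, effect_size = 2,
                               sparsity = 0.5, library_size_mean = 1e4,
                               n_families = 12, seed = 1) {
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (n_samples < 2 || n_features < 2) stop("need at least 2 samples and 2 features")
  set.seed(seed)

  n <- n_samples; p <- n_features; k <- n_informative
  feats <- sprintf("ASV_%04d", seq_len(p))
  samples <- sprintf("S%02d", seq_len(n))
  inf_idx <- if (k > 0) sort(sample(p, k)) else integer(0)

  signs <- if (k > 0) rep(rep(c(1, -1), length.out = ceiling(k / 4)),
                          each = 4)[seq_len(k)] else numeric(0)

  mu <- rnorm(p, 0, 1.5)
  if (k > 0) mu[inf_idx] <- rnorm(k, 1, 0.5)
  u <- rnorm(n)                            # shared community factor
  logB <- matrix(rnorm(n * p), n, p) + matrix(mu, n, p, byrow = TRUE)
  if (k > 0 && effect_size > 0)
    logB[, inf_idx] <- logB[, inf_idx] + outer(u, signs)
  B <- exp(logB)

  A <- B
  bg <- setdiff(seq_len(p), inf_idx)
  if (length(bg) > 0 && sparsity > 0) {
    mask <- matrix(runif(n * length(bg)) < sparsity, n, length(bg))
    A[, bg][mask] <- 0
  }
  # every sample must keep at least one nonzero feature
  dead <- which(rowSums(A) == 0)
  for (i in dead) {
    j <- sample(p, 1)
    A[i, j] <- B[i, j]
  }

  lib <- pmax(1L, rpois(n, library_size_mean))
  counts <- t(vapply(seq_len(n), function(i)
    as.numeric(rmultinom(1, lib[i], A[i, ] / sum(A[i, ]))), numeric(p)))
  dimnames(counts) <- list(samples, feats)

  noise <- rnorm(n)
  if (k > 0 && effect_size > 0) {
    L <- logB - rowMeans(logB)               # clr of the latent abundances
    Z <- scale(L[, inf_idx, drop = FALSE])
    signal <- as.vector(Z %*% signs)
    y_lat <- signal + noise * sd(signal) / effect_size
  } else {
    y_lat <- noise
  }
  y <- 35 + as.vector(scale(y_lat))
  names(y) <- samples

  fam_ids <- sprintf("Family_%02d", seq_len(n_families))
  tax_lab <- rep(NA_character_, p)
  if (k > 0) {
    inf_fams <- fam_ids[ceiling(seq_len(k) / 4)]
    tax_lab[inf_idx] <- inf_fams
    rest_fams <- setdiff(fam_ids, unique(inf_fams))
  } else {
    rest_fams <- fam_ids
  }
  if (length(bg) > 0) {
    unlabeled <- runif(length(bg)) < 0.05
    pool <- if (length(rest_fams) > 0) rest_fams else fam_ids
    tax_lab[bg[!unlabeled]] <- sample(pool, sum(!unlabeled), replace = TRUE)
  }
  taxonomy <- setNames(lapply(tax_lab, function(f)
    if (is.na(f)) NULL else c(family = f)), feats)
  taxonomy <- taxonomy[!vapply(taxonomy, is.null, logical(1))]

  structure(list(
    table = feature_table(counts, taxonomy = taxonomy),
    target = target_vector(y),
    truth = data.frame(feature_id = feats[inf_idx],
                       sign = signs,
                       effect_size = rep(effect_size, k),
                       family = tax_lab[inf_idx],
                       stringsAsFactors = FALSE),
    seed = seed,
    params = list(n_samples = n, n_features = p, n_informative = k,
                  effect_size = effect_size, sparsity = sparsity,
                  library_size_mean = library_size_mean,
                  n_families = n_families)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples x %d features, %d planted (effect %.2g), seed %d\n",
              nrow(x$table$counts), ncol(x$table$counts),
              nrow(x$truth), x$params$effect_size, x$seed))
  invisible(x)
}

#' Write a synthetic dataset as standard input files
#'
#' Emits `features.tsv` (samples x features counts), `target.tsv`,
#' `taxonomy.tsv` (feature id, lineage), and `truth.tsv` into `dir`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(ds$table, file.path(dir, "features.tsv"))
  write_target(ds$target, file.path(dir, "target.tsv"))
  tax <- ds$table$taxonomy
  if (length(tax) > 0) {
    df <- data.frame(feature_id = names(tax),
                     lineage = vapply(tax, function(v)
                       paste(sprintf("%s__%s", substr(names(v), 1, 1), v),
                             collapse = "; "), character(1)))
    write.table(df, file.path(dir, "taxonomy.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Repeat-run stability of scores and ranks
#'
#' Runs the full ensemble `n_runs` times on the same dataset varying only
#' the random-forest seed, then reports pairwise Pearson correlations of the
#' score vectors and pairwise Spearman correlations of the rank vectors,
#' both over all features and restricted to the top-`k_top` features (by
#' mean score across runs). Selector outputs do not depend on the forest
#' seed, so they are computed once and shared across runs.
#'
#' @param ds A `synthetic_dataset`, or a list with elements `table`/`ft`
#'   and `target`/`tv`.
#' @param n_runs Number of repeats (>= 2).
#' @param base_seed Base seed; run r uses forest seed
#'   `forest_seeds[r]` (default `base_seed + r - 1`).
#' @param k_top Size of the top set for the restricted Spearman.
#' @param forest_seeds Optional explicit vector of forest seeds.
#' @param ... Passed to [run_ensemble()] (e.g. `n_trees`).
#' @return List with `scores` and `ranks` matrices (features x runs), the
#'   pairwise correlation matrices `pearson`, `spearman_all`,
#'   `spearman_top`, the `top_features`, and the minima
#'   `min_pearson`, `min_spearman_all`, `min_spearman_top`.
#' @export
repeat_run_stability <- function(ds, n_runs = 10, base_seed = 1, k_top = 10,
                                 forest_seeds = NULL, ...) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  ft <- if (!is.null(ds$table)) ds$table else ds$ft
  tv <- if (!is.null(ds$target)) ds$target else ds$tv
  if (is.null(forest_seeds)) forest_seeds <- base_seed + seq_len(n_runs) - 1L
  stopifnot(length(forest_seeds) == n_runs)

  first <- run_ensemble(ft, tv, seed = base_seed,
                        forest_seed = forest_seeds[1], ...)
  feats <- sort(names(first$results[[1]]$importance))
  scores <- matrix(NA_real_, length(feats), n_runs,
                   dimnames = list(feats, paste0("run", seq_len(n_runs))))
  ranks <- scores
  grab <- function(run, j) {
    st <- run$score_table
    scores[match(st$feature_id, feats), j] <<- st$score
    ranks[match(st$feature_id, feats), j] <<- st$rank
  }
  grab(first, 1)
  for (r in seq_len(n_runs)[-1]) {
    run <- run_ensemble(ft, tv, seed = base_seed, forest_seed = forest_seeds[r],
                        selections = first$selections, ...)
    grab(run, r)
  }
  pear <- cor(scores)
  sp_all <- cor(ranks, method = "spearman")
  top <- names(sort(rowMeans(scores), decreasing = TRUE))[seq_len(min(k_top, length(feats)))]
  sp_top <- cor(ranks[top, , drop = FALSE], method = "spearman")
  off <- upper.tri(pear)
  list(scores = scores, ranks = ranks,
       pearson = pear, spearman_all = sp_all, spearman_top = sp_top,
       top_features = top,
       min_pearson = min(pear[off]),
       min_spearman_all = min(sp_all[off]),
       min_spearman_top = min(sp_top[off]))
}

#' Jackknife sensitivity to sample size
#'
#' For each requested sample count, draws `replicates_per_size` random
#' subsamples without replacement, runs the full ensemble on each, and
#' records the mean and s.d. across replicates of the best path's pooled
#' LOOCV R-squared. Sizes below 5 cannot support LOOCV and are skipped with
#' a warning.
#'
#' @param ds As in [repeat_run_stability()].
#' @param sizes Sample counts to test.
#' @param replicates_per_size Subsample replicates per size.
#' @param seed Base seed for subsampling and runs.
#' @param ... Passed to [run_ensemble()].
#' @return data.frame with `size`, `mean_r2`, `sd_r2`, `n_replicates`.
#' @export
jackknife_sensitivity <- function(ds, sizes, replicates_per_size = 10,
                                  seed = 1, ...) {
  ft <- if (!is.null(ds$table)) ds$table else ds$ft
  tv <- if (!is.null(ds$target)) ds$target else ds$tv
  n <- nrow(ft$counts)
  if (max(sizes) > n) stop("requested size exceeds the number of samples")
  keep <- sizes >= 5
  if (any(!keep))
    warning("skipping size(s) below 5 samples: ",
            paste(sizes[!keep], collapse = ", "), call. = FALSE)
  sizes <- sizes[keep]
  out <- lapply(sizes, function(s) {
    r2 <- vapply(seq_len(replicates_per_size), function(rep) {
      set.seed(seed + 1000L * s + rep)
      idx <- sort(sample(n, s))
      ids <- rownames(ft$counts)[idx]
      sub_ft <- feature_table(ft$counts[ids, , drop = FALSE],
                              taxonomy = ft$taxonomy)
      sub_tv <- target_vector(unclass(tv)[ids])
      run <- run_ensemble(sub_ft, sub_tv, seed = seed + rep, ...)
      max(attr(run$score_table, "path_metrics")$r2)
    }, numeric(1))
    data.frame(size = s, mean_r2 = mean(r2), sd_r2 = sd(r2),
               n_replicates = replicates_per_size)
  })
  do.call(rbind, out)
}
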