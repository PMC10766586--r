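# Shared fixtures, all built in code.

toy_counts <- function() {
  m <- matrix(c(2, 0,
                1, 5,
                0, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  m
}

toy_ft <- function() feature_table(toy_counts())

# 6 samples x 4 features with a 2-family taxonomy, counts chosen by hand
tax_ft <- function() {
  m <- matrix(c(3, 4, 2, 1,
                1, 2, 5, 0,
                6, 0, 1, 2,
                2, 2, 2, 2,
                0, 5, 3, 1,
                4, 1, 0, 6), nrow = 6, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:6), sprintf("asv%d", 1:4)))
  feature_table(m, taxonomy = list(
    asv1 = c(family = "FamA"),
    asv2 = c(family = "FamA"),
    asv3 = c(family = "FamB")))  # asv4 unclassified
}

rand_X <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent exhaustive CFS oracle: enumerate all 2^p subsets, re-deriving
# Hall's merit from means (not via cfs_merit's sum form).
exhaustive_cfs_merit <- function(X, y) {
  p <- ncol(X)
  r_cf <- abs(as.vector(cor(X, y))); r_cf[!is.finite(r_cf)] <- 0
  r_ff <- abs(cor(X)); r_ff[!is.finite(r_ff)] <- 0; diag(r_ff) <- 1
  best <- 0
  for (m in seq_len(2^p - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    k <- length(S)
    rbar_cf <- mean(r_cf[S])
    rbar_ff <- if (k >= 2) mean(r_ff[S, S][upper.tri(diag(k))]) else 0
    merit <- k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
    if (merit > best) best <- merit
  }
  best
}

# Tiny fabricated path_result set for scoring tests: 8 paths over a given
# feature universe, with specified importances / R2 / selections.
fake_results <- function(feats, imp_list, r2s, selected_list = NULL) {
  paths <- build_paths()
  lapply(seq_len(8), function(j) {
    imp <- setNames(rep(0, length(feats)), feats)
    if (!is.null(imp_list[[j]])) imp[names(imp_list[[j]])] <- imp_list[[j]]
    sel <- if (!is.null(selected_list)) selected_list[[j]] else
      names(imp)[imp > 0]
    structure(list(path = as.list(paths[j, ]),
                   r2 = r2s[j], mse = 0.5,
                   predictions = NULL,
                   selected = sel,
                   importance = imp,
                   coefficients = if (paths$selector_tag[j] %in% c("lasso", "alasso"))
                     setNames(rep(0.1, length(sel)), sel) else NULL,
                   intercept = if (paths$selector_tag[j] %in% c("lasso", "alasso"))
                     35 else NULL,
                   seed = 1), class = "path_result")
  })
}
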