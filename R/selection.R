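#' @keywords internal
.standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  ok <- is.finite(sdv) & sdv > 0
  Xs <- sweep(X, 2, mu, "-")
  Xs <- sweep(Xs, 2, ifelse(ok, sdv, 1), "/")
  if (any(!ok)) Xs[, !ok] <- 0
  list(Xs = Xs, mu = mu, sd = sdv, ok = ok)
}

.cv_foldid <- function(n, seed, nfolds = 5) {
  set.seed(seed)
  sample(rep_len(seq_len(nfolds), n))
}

.selection_result <- function(tag, selected, coefficients = NULL,
                              intercept = NULL, penalty = NULL) {
  structure(list(selector_tag = tag, selected = selected,
                 coefficients = coefficients, intercept = intercept,
                 penalty_strength = penalty),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result:%s> %d feature(s) selected\n",
              x$selector_tag, length(x$selected)))
  invisible(x)
}

# Core weighted L1 fit. Columns are standardized in-house and glmnet is run
# with standardize = FALSE: glmnet's own standardization would silently undo
# adaptive-lasso weights (which act by rescaling columns). Coefficients are
# mapped back to the original predictor scale. Zero-variance columns get a
# zero column (never selected). With weights = 1 this is plain lasso.
.weighted_lasso <- function(X, y, weights, seed, lambda = NULL, tag = "lasso") {
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples for penalized selection")
  std <- .standardize_cols(X)
  if (!any(std$ok)) {
    return(.selection_result(tag, character(0), numeric(0), mean(y), NA_real_))
  }
  Xw <- sweep(std$Xs, 2, weights, "*")
  padded <- FALSE
  if (ncol(Xw) < 2) {                     # glmnet requires >= 2 columns
    Xw <- cbind(Xw, .pad. = 0)
    padded <- TRUE
  }
  if (is.null(lambda)) {
    foldid <- .cv_foldid(n, seed)
    grouped <- min(table(foldid)) >= 3
    cvfit <- suppressWarnings(glmnet::cv.glmnet(
      Xw, y, alpha = 1, standardize = FALSE, foldid = foldid,
      grouped = grouped))
    lambda <- cvfit$lambda.min
    b <- as.vector(stats::coef(cvfit$glmnet.fit, s = lambda))
  } else {
    # a fixed penalty may lie off the default path; refit exactly at it
    fit <- glmnet::glmnet(Xw, y, alpha = 1, standardize = FALSE)
    b <- as.vector(stats::coef(fit, s = lambda, exact = TRUE,
                               x = Xw, y = y, alpha = 1, standardize = FALSE))
  }
  a <- b[1]
  bw <- b[-1]
  if (padded) bw <- bw[-length(bw)]
  beta_std <- bw * weights
  beta_orig <- ifelse(std$ok, beta_std / ifelse(std$ok, std$sd, 1), 0)
  intercept <- a - sum((std$mu / ifelse(std$ok, std$sd, 1) * beta_std)[std$ok])
  names(beta_orig) <- colnames(X)
  sel <- colnames(X)[beta_orig != 0]
  .selection_result(tag, sel, beta_orig[sel], intercept, lambda)
}

#' Lasso feature selection
#'
#' L1-penalized linear regression of the target on the (transformed) feature
#' matrix; the penalty strength is chosen by internal 5-fold cross-validation
#' over glmnet's log-spaced path, on the provided data only (never a held-out
#' LOOCV sample). Predictors are standardized internally; coefficients are
#' reported on the original predictor scale. Features with a nonzero
#' coefficient form the selected set.
#'
#' @param X Numeric matrix, samples x features, with column names.
#' @param y Numeric target, aligned with the rows of `X`.
#' @param seed Integer seed controlling the internal CV fold assignment.
#' @param lambda Optional fixed penalty strength; skips internal CV.
#' @return A `selection_result` with `selected`, nonzero `coefficients`,
#'   `intercept`, and `penalty_strength`.
#' @export
lasso_select <- function(X, y, seed = 42, lambda = NULL) {
  .weighted_lasso(X, y, rep(1, ncol(X)), seed, lambda, tag = "lasso")
}

#' Adaptive lasso feature selection
#'
#' Two-stage weighted L1 regression: stage one fits ridge regression (penalty
#' by internal 5-fold CV; ridge rather than OLS because p >> n makes OLS
#' ill-posed) to obtain initial standardized estimates; stage two runs the
#' lasso with per-feature penalty proportional to
#' `1 / (|beta_ridge| + epsilon)^gamma`, giving strongly supported features a
#' lighter penalty and improving selection consistency. With `gamma = 0` the
#' weights are all one and the result is identical to [lasso_select()].
#'
#' @inheritParams lasso_select
#' @param gamma Weight exponent (default 1).
#' @param epsilon Stabilizer added to the initial estimates (default 1e-6).
#' @return A `selection_result`, coefficients on the original scale.
#' @export
adaptive_lasso_select <- function(X, y, gamma = 1, seed = 42,
                                  epsilon = 1e-6, lambda = NULL) {
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples for penalized selection")
  std <- .standardize_cols(X)
  if (!any(std$ok))
    return(.selection_result("alasso", character(0), numeric(0), mean(y), NA_real_))
  Xs <- std$Xs
  padded <- FALSE
  if (ncol(Xs) < 2) {
    Xs <- cbind(Xs, .pad. = 0)
    padded <- TRUE
  }
  foldid <- .cv_foldid(n, seed + 1L)
  grouped <- min(table(foldid)) >= 3
  ridge <- suppressWarnings(glmnet::cv.glmnet(
    Xs, y, alpha = 0, standardize = FALSE, foldid = foldid, grouped = grouped))
  b0 <- as.vector(stats::coef(ridge, s = "lambda.min"))[-1]
  if (padded) b0 <- b0[-length(b0)]
  w <- (abs(b0) + epsilon)^gamma
  out <- .weighted_lasso(X, y, w, seed, lambda, tag = "alasso")
  out
}

#' Correlation-based feature selection merit
#'
#' Hall's subset heuristic: for a subset of size k with mean absolute
#' feature--target correlation `r_cf` and mean absolute feature--feature
#' correlation `r_ff` over its pairs,
#' `merit = k * mean(r_cf) / sqrt(k + k*(k-1) * mean(r_ff))`.
#' It rewards subsets whose members track the target while being mutually
#' non-redundant. The empty subset has merit 0.
#'
#' @param subset Character vector of feature ids (possibly empty).
#' @param r_cf Named numeric vector of absolute feature--target correlations
#'   (undefined correlations for constant features are 0).
#' @param r_ff Symmetric named matrix of absolute feature--feature
#'   correlations.
#' @return The merit, a single number.
#' @export
cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  if (k == 0) return(0)
  scf <- sum(r_cf[subset])
  sff <- 0
  if (k >= 2) {
    block <- r_ff[subset, subset, drop = FALSE]
    sff <- (sum(block) - sum(diag(block))) / 2
  }
  scf / sqrt(k + 2 * sff)
}

.cfs_correlations <- function(X, y) {
  r_cf <- suppressWarnings(abs(as.vector(cor(X, y))))
  r_cf[!is.finite(r_cf)] <- 0
  names(r_cf) <- colnames(X)
  r_ff <- suppressWarnings(abs(cor(X)))
  r_ff[!is.finite(r_ff)] <- 0
  diag(r_ff) <- 1
  dimnames(r_ff) <- list(colnames(X), colnames(X))
  list(r_cf = r_cf, r_ff = r_ff)
}

#' Correlation-based feature selection (CFS)
#'
#' Computes absolute Pearson correlations once, then runs a forward
#' best-first search over feature subsets maximizing [cfs_merit()]: the
#' highest-merit frontier subset is expanded by every single-feature
#' addition; the search stops after `stall_limit` consecutive expansions
#' that fail to improve the best merit found. Ties in expansion order are
#' broken by lexicographic feature id, making the search deterministic.
#'
#' @inheritParams lasso_select
#' @param stall_limit Consecutive non-improving expansions tolerated before
#'   termination (default 5).
#' @return A `selection_result`; CFS produces no coefficients.
#' @export
cfs_select <- function(X, y, stall_limit = 5) {
  if (nrow(X) < 5) stop("need at least 5 samples for CFS")
  sdv <- apply(X, 2, sd)
  if (all(sdv == 0)) stop("all features are constant; CFS has nothing to rank")
  cors <- .cfs_correlations(X, y)
  r_cf <- cors$r_cf
  r_ff <- cors$r_ff
  p <- ncol(X)
  ids <- colnames(X)

  node_key <- function(idx) paste0("k", paste(idx, collapse = ","))
  visited <- new.env(parent = emptyenv())

  # nodes: list(idx = sorted int vector, scf, sff, merit)
  open_idx <- list(integer(0))
  open_scf <- 0
  open_sff <- 0
  open_merit <- 0
  best_idx <- integer(0)
  best_merit <- 0
  stall <- 0L
  assign(node_key(integer(0)), TRUE, envir = visited)

  while (length(open_idx) > 0 && stall < stall_limit) {
    # pop the best open node; merit ties broken by lexicographic id string
    top <- which(open_merit == max(open_merit))
    if (length(top) > 1) {
      keys <- vapply(open_idx[top],
                     function(ii) paste(sort(ids[ii]), collapse = "|"),
                     character(1))
      top <- top[order(keys)]
    }
    j <- top[1]
    cur <- open_idx[[j]]
    cur_scf <- open_scf[j]
    cur_sff <- open_sff[j]
    open_idx <- open_idx[-j]
    open_scf <- open_scf[-j]
    open_sff <- open_sff[-j]
    open_merit <- open_merit[-j]

    cand <- setdiff(seq_len(p), cur)
    if (length(cand) > 0) {
      new <- !vapply(cand, function(f)
        exists(node_key(sort(c(cur, f))), envir = visited), logical(1))
      cand <- cand[new]
    }
    if (length(cand) == 0) {
      stall <- stall + 1L
      next
    }
    k <- length(cur)
    scf_new <- cur_scf + r_cf[cand]
    cross <- if (k > 0) colSums(r_ff[cur, cand, drop = FALSE]) else rep(0, length(cand))
    sff_new <- cur_sff + cross
    merits <- scf_new / sqrt((k + 1) + 2 * sff_new)

    children <- lapply(cand, function(f) sort(c(cur, f)))
    for (ch in children) assign(node_key(ch), TRUE, envir = visited)
    open_idx <- c(open_idx, children)
    open_scf <- c(open_scf, scf_new)
    open_sff <- c(open_sff, sff_new)
    open_merit <- c(open_merit, unname(merits))
    if (max(merits) > best_merit + 1e-12) {
      winners <- which(merits == max(merits))
      if (length(winners) > 1) winners <- winners[order(ids[cand[winners]])]
      best_idx <- sort(c(cur, cand[winners[1]]))
      best_merit <- max(merits)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  .selection_result("cfs", ids[best_idx], NULL, NULL, NULL)
}
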