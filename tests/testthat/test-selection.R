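lambda_max <- function(X, y) {
  Xs <- scale(X)
  max(abs(crossprod(Xs, y - mean(y)))) / length(y)
}

test_that("lasso at the full-shrinkage penalty selects nothing", {
  X <- rand_X(30, 50, seed = 21)
  set.seed(22)
  y <- rnorm(30)
  lmax <- lambda_max(X, y)
  res <- lasso_select(X, y, seed = 1, lambda = lmax * 1.0001)
  expect_length(res$selected, 0)
  expect_equal(res$intercept, mean(y), tolerance = 1e-8)

  # CV on pure noise keeps the selection small
  cvres <- lasso_select(X, y, seed = 1)
  expect_lt(length(cvres$selected), 25)
})

test_that("lasso recovers a single exact predictor with vanishing penalty", {
  set.seed(23)
  X <- rand_X(40, 10, seed = 23)
  X[, 1] <- as.vector(scale(X[, 1]))
  y <- 3 * X[, 1]
  res <- lasso_select(X, y, seed = 2, lambda = 1e-5)
  expect_true("f001" %in% res$selected)
  expect_equal(unname(res$coefficients["f001"]), 3, tolerance = 1e-3)
})

test_that("lasso coefficients are reported on the original predictor scale", {
  # with p << n and lambda ~ 0 the fit must approach OLS in original units
  set.seed(24)
  X <- rand_X(50, 3, seed = 24)
  X[, 2] <- X[, 2] * 10 + 5                     # deliberately unscaled column
  y <- 1 + 2 * X[, 1] - 0.3 * X[, 2] + rnorm(50, 0, 0.1)
  res <- lasso_select(X, y, seed = 3, lambda = 1e-7)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(res$intercept), unname(ols[1]), tolerance = 1e-2)
  expect_equal(unname(res$coefficients[c("f001", "f002")]),
               unname(ols[2:3]), tolerance = 1e-2)
})

test_that("duplicated predictor columns split, not inflate, coefficient mass", {
  set.seed(25)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- 2 * x1 + rnorm(40, 0, 0.2)
  X2 <- cbind(f1 = x1, f2 = x2)
  X3 <- cbind(f1 = x1, f2 = x2, f3 = x1)     # exact duplicate of f1
  lam <- 0.05
  r2 <- lasso_select(X2, y, seed = 4, lambda = lam)
  r3 <- lasso_select(X3, y, seed = 4, lambda = lam)
  mass2 <- sum(r2$coefficients[names(r2$coefficients) %in% c("f1")])
  mass3 <- sum(r3$coefficients[names(r3$coefficients) %in% c("f1", "f3")])
  expect_equal(mass3, mass2, tolerance = 1e-6)
})

test_that("zero-variance predictors are never selected", {
  set.seed(26)
  X <- rand_X(20, 6, seed = 26)
  X[, 4] <- 7
  y <- rnorm(20)
  expect_false("f004" %in% lasso_select(X, y, seed = 5)$selected)
  expect_false("f004" %in% adaptive_lasso_select(X, y, seed = 5)$selected)
})

test_that("adaptive lasso with unit weights reproduces plain lasso", {
  set.seed(27)
  X <- rand_X(30, 40, seed = 27)
  y <- 2 * X[, 3] - X[, 7] + rnorm(30)
  a <- adaptive_lasso_select(X, y, gamma = 0, seed = 6)
  b <- lasso_select(X, y, seed = 6)
  expect_identical(a$selected, b$selected)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_equal(a$penalty_strength, b$penalty_strength, tolerance = 1e-12)
})

test_that("adaptive lasso finds a strong planted predictor among noise", {
  set.seed(28)
  X <- rand_X(30, 60, seed = 28)
  y <- 3 * as.vector(scale(X[, 11])) + rnorm(30)
  res <- adaptive_lasso_select(X, y, seed = 7)
  expect_true("f011" %in% res$selected)
})

test_that("cfs merit matches its closed form", {
  r_cf <- c(a = 0.7, b = 0.6, c = 0.6)
  r_ff <- matrix(1, 3, 3, dimnames = list(names(r_cf), names(r_cf)))
  expect_equal(cfs_merit("a", r_cf, r_ff), 0.7)
  expect_equal(cfs_merit(c("b", "c"), r_cf, r_ff), 1.2 / sqrt(4))
  expect_equal(cfs_merit(character(0), r_cf, r_ff), 0)
  # permutation invariance
  expect_equal(cfs_merit(c("c", "b"), r_cf, r_ff),
               cfs_merit(c("b", "c"), r_cf, r_ff))
})

test_that("cfs merit increases with target correlation at fixed redundancy", {
  set.seed(29)
  r_ff <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(r_ff) <- 1
  for (i in 1:20) {
    r1 <- setNames(runif(4), letters[1:4])
    r2 <- r1
    j <- sample(4, 1)
    r2[j] <- min(1, r1[j] + runif(1, 0, 0.3))
    expect_gte(cfs_merit(letters[1:4], r2, r_ff),
               cfs_merit(letters[1:4], r1, r_ff))
  }
})

test_that("cfs best-first equals exhaustive merit maximization for small p", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    p <- sample(6:8, 1)
    X <- rand_X(15, p, seed = seed)
    b <- rnorm(p) * rbinom(p, 1, 0.4)
    y <- as.vector(X %*% b) + rnorm(15)
    got <- cfs_select(X, y)
    cors <- taxassoc:::.cfs_correlations(X, y)
    expect_equal(cfs_merit(got$selected, cors$r_cf, cors$r_ff),
                 exhaustive_cfs_merit(X, y), tolerance = 1e-9)
  }
})

test_that("cfs keeps a perfectly informative feature and drops its clone", {
  set.seed(34)
  X <- rand_X(25, 10, seed = 34)
  y <- X[, 5] * 2                       # f005 perfectly correlated with y
  res <- cfs_select(X, y)
  expect_true("f005" %in% res$selected)

  Xdup <- cbind(X, f011 = X[, 5])       # identical clone of the best feature
  res2 <- cfs_select(Xdup, y)
  expect_equal(sum(c("f005", "f011") %in% res2$selected), 1L)
})

test_that("cfs rejects an all-constant table", {
  X <- matrix(3, 10, 4, dimnames = list(NULL, letters[1:4]))
  expect_error(cfs_select(X, rnorm(10)), "constant")
})
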