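# Fabricated 8-path results make the scoring arithmetic fully controllable.

test_that("model count distinguishes subset membership from full-path importance", {
  feats <- c("A", "B", "C")
  # A: chosen by every path; B: two subset paths + one full path; C: nowhere
  imp <- lapply(1:8, function(j) c(A = 0.6, B = if (j %in% c(1, 2, 4)) 0.4 else 0,
                                   C = 0))
  sel <- lapply(1:8, function(j) {
    tag <- build_paths()$selector_tag[j]
    if (tag == "full") c("A", "B", "C") else if (j %in% c(1, 2)) c("A", "B") else "A"
  })
  res <- fake_results(feats, imp, r2s = rep(0.5, 8), selected_list = sel)
  expect_equal(model_count("A", res), 8L)
  expect_equal(model_count("C", res), 0L)
  # B: subset paths 1,2 + full path 4 (importance > 0); full path 8 has imp 0
  expect_equal(model_count("B", res), 3L)
})

test_that("the aggregated score reproduces its worked examples", {
  feats <- c("A", "B")
  # maximal case: importance 1 everywhere, R2 = 1 everywhere
  res <- fake_results(feats, lapply(1:8, function(j) c(A = 1)), r2s = rep(1, 8))
  expect_equal(compute_score("A", res), 1)
  expect_equal(compute_score("B", res), 0)

  # two-path case: importance 0.5 with R2 0.8 and 0.4, m_k = 2
  imp <- c(list(c(A = 0.5)), list(c(A = 0.5)), rep(list(NULL), 6))
  res2 <- fake_results(feats, imp, r2s = c(0.8, 0.4, rep(0, 6)))
  expect_equal(model_count("A", res2), 2L)
  expect_equal(compute_score("A", res2), (0.5 * 0.8 + 0.5 * 0.4) / 8 * 2 / 8)
  expect_equal(compute_score("A", res2), 0.01875)
})

test_that("negative path R2 is clamped to zero in the score", {
  feats <- "A"
  imp <- c(list(c(A = 1)), list(c(A = 1)), rep(list(NULL), 6))
  res <- fake_results(feats, imp, r2s = c(0.6, -5, rep(0, 6)))
  # the negative path contributes nothing but still counts toward m_k
  expect_equal(compute_score("A", res), (1 * 0.6 + 0) / 8 * 2 / 8)
})

test_that("scores stay in [0,1], increase with importance, decrease when R2 drops", {
  set.seed(71)
  feats <- sprintf("F%02d", 1:6)
  for (trial in 1:15) {
    imp <- lapply(1:8, function(j) {
      v <- runif(6) * rbinom(6, 1, 0.6)
      if (sum(v) > 0) v <- v / sum(v)
      setNames(v, feats)
    })
    r2s <- runif(8, -0.5, 1)
    res <- fake_results(feats, imp, r2s)
    s <- vapply(feats, compute_score, numeric(1), results = res)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all((vapply(feats, model_count, numeric(1), results = res) == 0) == (s == 0)))

    # bump one importance: the bumped feature's score must not decrease
    f <- sample(feats, 1); j <- sample(8, 1)
    res_up <- res
    res_up[[j]]$importance[f] <- res_up[[j]]$importance[f] + 0.5
    if (res_up[[j]]$path$selector_tag != "full")
      res_up[[j]]$selected <- union(res_up[[j]]$selected, f)
    expect_gte(compute_score(f, res_up), s[f])

    # kill one path's R2: no score may increase
    res_z <- res
    res_z[[j]]$r2 <- 0
    s_z <- vapply(feats, compute_score, numeric(1), results = res_z)
    expect_true(all(s_z <= s + 1e-12))
  }
})

test_that("ranking sorts by score with m_k then id as tie-breakers", {
  feats <- c("A", "B", "C", "D")
  # A and B tie on score but B has larger m_k; C and D tie entirely
  imp <- lapply(1:8, function(j) {
    v <- c(A = 0, B = 0, C = 0, D = 0)
    if (j == 4) v <- c(A = 0.4, B = 0.2, C = 0.2, D = 0.2)
    if (j == 8) v <- c(A = 0, B = 0.2, C = 0.2, D = 0.2)
    v
  })
  res <- fake_results(feats, imp, r2s = rep(1, 8))
  st <- rank_features(res)
  expect_equal(st$rank, 1:4)
  expect_equal(st$feature_id[1], "B")        # 0.4/64*2 > 0.4/64*1? both .4 sum; B mk2
  sA <- compute_score("A", res); sB <- compute_score("B", res)
  expect_true(sB > sA || (sB == sA && st$feature_id[1] == "B"))
  # full tie between C and D -> lexicographic
  iC <- which(st$feature_id == "C"); iD <- which(st$feature_id == "D")
  expect_lt(iC, iD)
  expect_true(all(diff(st$score) <= 1e-15))
})

test_that("the report mirrors the expected layout and round-trips", {
  set.seed(72)
  feats <- sprintf("Fam%02d", 1:7)
  imp <- lapply(1:8, function(j) {
    v <- runif(7); setNames(v / sum(v), feats)
  })
  res <- fake_results(feats, imp, r2s = runif(8, 0, 0.9))
  st <- rank_features(res)
  path <- tempfile(fileext = ".csv")
  write_report(st, res, path)

  lines <- readLines(path)
  expect_length(lines, 1 + 3 + 7)            # header line + metric block + features
  back <- read_report(path)
  expect_equal(back$features$score,
               st$score[match(back$features$feature_id, st$feature_id)],
               tolerance = 1e-6)
  expect_equal(back$metrics$r2, attr(st, "path_metrics")$r2, tolerance = 1e-6)
  # intercept cells empty for cfs/full paths
  expect_true(all(is.na(back$metrics$intercept[c(3, 4, 7, 8)])))
  expect_true(all(!is.na(back$metrics$intercept[c(1, 2, 5, 6)])))

  long <- tempfile(fileext = ".tsv")
  write_report_long(st, res, long)
  tidy <- read.table(long, header = TRUE, sep = "\t")
  expect_setequal(unique(tidy$metric), c("importance", "coefficient", "score"))
})
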