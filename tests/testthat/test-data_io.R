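test_that("feature tables parse from TSV and reject invalid cells", {
  p <- write_tmp(c("sample\tf1\tf2", "s1\t2\t0", "s2\t1\t5", "s3\t0\t3"), ".tsv")
  ft <- read_feature_table(p)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(unname(ft$counts), unname(toy_counts()))

  neg <- write_tmp(c("sample\tf1\tf2", "s1\t2\t0", "s2\t-1\t5"), ".tsv")
  expect_error(read_feature_table(neg), "s2.*f1")

  dup <- write_tmp(c("sample,f1,f1", "s1,2,0", "s2,1,5"), ".csv")
  expect_error(read_feature_table(dup), "duplicate")

  txt <- write_tmp(c("sample\tf1\tf2", "s1\tx\t0", "s2\t1\t5"), ".tsv")
  expect_error(read_feature_table(txt), "non-numeric")
})

test_that("features-as-rows input is transposed and lineage column parsed", {
  p <- write_tmp(c("feature\ts1\ts2\ttaxonomy",
                   "asv1\t2\t1\td__Bacteria; f__FamA",
                   "asv2\t0\t5\td__Bacteria; f__FamB"), ".tsv")
  ft <- read_feature_table(p, orientation = "features_as_rows")
  expect_equal(rownames(ft$counts), c("s1", "s2"))
  expect_equal(colnames(ft$counts), c("asv1", "asv2"))
  expect_equal(ft$taxonomy$asv1[["family"]], "FamA")
  expect_equal(ft$taxonomy$asv2[["domain"]], "Bacteria")
})

test_that("write-then-read round trip preserves counts to 12 digits", {
  set.seed(7)
  m <- matrix(runif(20, 0, 100), 4, 5,
              dimnames = list(sprintf("s%d", 1:4), sprintf("f%d", 1:5)))
  ft <- feature_table(m)
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$counts, ft$counts, tolerance = 1e-12)
})

test_that("target files validate ids, missing values and variance", {
  ok <- write_tmp(c("sample,ed50", "s1,35.1", "s2,36.0"), ".csv")
  tv <- read_target(ok)
  expect_length(tv, 2)
  expect_equal(unname(unclass(tv)), c(35.1, 36.0))

  dup <- write_tmp(c("sample,ed50", "s1,35.1", "s1,36.0"), ".csv")
  expect_error(read_target(dup), "duplicate")

  const <- write_tmp(c("sample,ed50", "s1,5", "s2,5"), ".csv")
  expect_error(read_target(const), "constant|variance")

  mis <- write_tmp(c("sample,ed50", "s1,35.1", "s2,"), ".csv")
  expect_error(read_target(mis), "s2")
})

test_that("sample alignment intersects, reorders by id, and is idempotent", {
  m <- matrix(1:12, 6, 2, dimnames = list(letters[1:6], c("f1", "f2")))
  ft <- feature_table(m)
  tv <- target_vector(setNames(c(5, 3, 8, 1, 9, 2), c("f", "e", "b", "c", "d", "z")))

  al <- suppressWarnings(align_samples(ft, tv))
  expect_equal(rownames(al$ft$counts), names(al$tv))
  expect_setequal(names(al$tv), c("b", "c", "d", "e", "f"))
  # values matched by id, not by position
  expect_equal(unname(unclass(al$tv)[["b"]]), 8)
  expect_warning(align_samples(ft, tv), "dropped")

  al2 <- align_samples(al$ft, al$tv)
  expect_identical(al2$ft$counts, al$ft$counts)
  expect_identical(unclass(al2$tv), unclass(al$tv))

  tv2 <- target_vector(setNames(c(1, 2), c("x", "y")))
  expect_error(align_samples(ft, tv2), "shared")
})

test_that("rank aggregation sums within labels, pools unlabeled, conserves totals", {
  ft <- tax_ft()
  ag <- aggregate_to_rank(ft, "family")
  expect_setequal(colnames(ag$counts), c("FamA", "FamB", "Unclassified_family"))
  # two FamA members: asv1 + asv2
  expect_equal(unname(ag$counts[, "FamA"]),
               unname(ft$counts[, "asv1"] + ft$counts[, "asv2"]))
  expect_equal(rowSums(ag$counts), rowSums(ft$counts))
  expect_error(aggregate_to_rank(ft, "genus"), "rank")
  expect_error(aggregate_to_rank(toy_ft(), "family"), "taxonomy")
})

test_that("aggregation feature count matches brute-force grouping", {
  set.seed(11)
  p <- 10
  fams <- c("F1", "F2", "F3")
  labs <- c(sample(fams, 8, replace = TRUE), NA, NA)
  m <- matrix(rpois(5 * p, 5), 5, p,
              dimnames = list(sprintf("s%d", 1:5), sprintf("a%02d", 1:p)))
  tax <- list()
  for (j in seq_len(p)) if (!is.na(labs[j])) tax[[colnames(m)[j]]] <- c(family = labs[j])
  ft <- feature_table(m, taxonomy = tax)
  ag <- aggregate_to_rank(ft, "family")
  expect_equal(ncol(ag$counts), length(unique(labs[!is.na(labs)])) + 1L)
})

test_that("filter_children_of keeps exactly the members of the given parents", {
  ft <- tax_ft()
  kept <- filter_children_of(ft, "family", c("FamA"))
  expect_setequal(colnames(kept$counts), c("asv1", "asv2"))
  expect_equal(kept$counts, ft$counts[, c("asv1", "asv2")])

  all_f <- filter_children_of(ft, "family", c("FamA", "FamB"))
  expect_setequal(colnames(all_f$counts), c("asv1", "asv2", "asv3"))

  expect_error(filter_children_of(ft, "family", "Nope"), "Nope")
})

test_that("membership filtering agrees with brute force on a larger table", {
  ds <- generate_synthetic(n_samples = 10, n_features = 60, n_informative = 4,
                           library_size_mean = 2000, seed = 3)
  fams <- unique(vapply(ds$table$taxonomy, function(v) v[["family"]], character(1)))
  pick <- fams[1:2]
  got <- filter_children_of(ds$table, "family", pick)
  want <- names(Filter(function(v) v[["family"]] %in% pick, ds$table$taxonomy))
  expect_setequal(colnames(got$counts), want)
})
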