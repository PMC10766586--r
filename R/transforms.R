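#' l1 (total-sum) normalization
#'
#' Divides each sample row by its total count, yielding relative abundances
#' that sum to one. Applied to raw counts, in parallel with the clr branch.
#'
#' @param ft A [feature_table()].
#' @return A `transformed_table`: list with `values` (matrix), and
#'   `transform_tag = "l1"`.
#' @export
l1_normalize <- function(ft) {
  rs <- rowSums(ft$counts)
  zero <- which(rs <= 0)
  if (length(zero) > 0)
    stop("all-zero sample row(s): ", paste(sample_ids(ft)[zero], collapse = ", "))
  structure(list(values = ft$counts / rs, transform_tag = "l1",
                 pseudocount = NA_real_),
            class = "transformed_table")
}

#' Centered log-ratio (clr) transform
#'
#' Per sample row: adds `pseudocount` to the counts, then maps each entry to
#' its log ratio against the row's geometric mean, so rows sum to zero. The
#' pseudocount handles the zeros endemic to amplicon count tables; 1.0 on
#' raw counts is the default.
#'
#' @param ft A [feature_table()].
#' @param pseudocount Non-negative value added to every count before taking
#'   logs; must be positive if any zero count is present.
#' @return A `transformed_table` with `transform_tag = "clr"`.
#' @export
clr_transform <- function(ft, pseudocount = 1) {
  if (pseudocount < 0) stop("`pseudocount` must be non-negative")
  if (pseudocount == 0 && any(ft$counts == 0))
    stop("zero counts present; a positive `pseudocount` is required for clr")
  lx <- log(ft$counts + pseudocount)
  structure(list(values = lx - rowMeans(lx), transform_tag = "clr",
                 pseudocount = pseudocount),
            class = "transformed_table")
}

#' @export
print.transformed_table <- function(x, ...) {
  cat(sprintf("<transformed_table:%s> %d samples x %d features\n",
              x$transform_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}
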