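#' Construct and validate a feature table
#'
#' A feature table holds a samples x features matrix of non-negative counts
#' (or abundances) with unique sample and feature identifiers, plus an
#' optional per-feature taxonomy.
#'
#' @param counts Numeric matrix, samples in rows, features in columns, with
#'   row and column names set to the sample and feature identifiers.
#' @param taxonomy Optional named list: one entry per feature id, each a
#'   named character vector mapping rank name (e.g. `"family"`) to a label.
#'   Features may be missing from the list (unclassified).
#' @return An object of class `feature_table` with elements `counts` and
#'   `taxonomy`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x features)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have row names (samples) and column names (features)")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative or non-finite count at sample '%s', feature '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !is.list(taxonomy))
      stop("`taxonomy` must be a named list keyed by feature id")
    extra <- setdiff(names(taxonomy), colnames(counts))
    if (length(extra) > 0)
      stop("taxonomy refers to unknown features: ", paste(head(extra, 5), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else
                sprintf(", taxonomy for %d features", length(x$taxonomy))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

sample_ids <- function(ft) rownames(ft$counts)
feature_ids <- function(ft) colnames(ft$counts)

#' Construct and validate a target vector
#'
#' @param values Named numeric vector: one finite value per sample id.
#'   At least two distinct values are required (a constant target makes
#'   R-squared undefined).
#' @return An object of class `target_vector` (a named numeric vector).
#' @export
target_vector <- function(values) {
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector")
  miss <- names(values)[!is.finite(values)]
  if (length(miss) > 0)
    stop("missing or non-finite target value for sample(s): ",
         paste(head(miss, 5), collapse = ", "))
  if (anyDuplicated(names(values)))
    stop("duplicate sample identifiers in target: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "))
  if (length(unique(values)) < 2)
    stop("target variable is constant (zero variance); R-squared is undefined")
  structure(values, class = "target_vector")
}

#' @export
print.target_vector <- function(x, ...) {
  cat(sprintf("<target_vector> %d samples, range [%.4g, %.4g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

.sniff_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab", "txt")) return("\t")
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

.read_delim_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path)
  read.table(path, header = TRUE, sep = sep, row.names = 1,
             check.names = FALSE, stringsAsFactors = FALSE,
             comment.char = "", quote = "\"")
}

#' Read a community feature table from CSV/TSV
#'
#' The first column holds identifiers and the first row holds the other
#' dimension's identifiers. Delimiter is sniffed from the file extension
#' (`.csv` vs `.tsv`/`.txt`) or content. A lineage column named
#' `taxonomy`/`lineage` (case-insensitive; only meaningful with
#' `orientation = "features_as_rows"`) is parsed into the taxonomy map.
#'
#' @param path Path to a CSV or TSV file of non-negative counts.
#' @param orientation Either `"samples_as_rows"` (default) or
#'   `"features_as_rows"`; the latter is transposed on read.
#' @param taxonomy Optional path to a separate two-column lineage file
#'   (feature id, lineage string), see [read_taxonomy()].
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows", "features_as_rows"),
                               taxonomy = NULL) {
  orientation <- match.arg(orientation)
  df <- .read_delim_strict(path)

  tax <- NULL
  if (orientation == "features_as_rows") {
    taxcol <- which(tolower(colnames(df)) %in% c("taxonomy", "lineage", "taxon"))
    if (length(taxcol) > 0) {
      tax <- .parse_lineages(setNames(as.character(df[[taxcol[1]]]), rownames(df)))
      df <- df[, -taxcol, drop = FALSE]
    }
  }

  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(df)[bad], colnames(df)[j]))
    }
  }
  m <- as.matrix(df)
  if (orientation == "features_as_rows") m <- t(m)

  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or missing count at sample '%s', feature '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))

  if (!is.null(taxonomy)) tax <- read_taxonomy(taxonomy)
  if (!is.null(tax)) tax <- tax[intersect(names(tax), colnames(m))]
  feature_table(m, taxonomy = if (length(tax) > 0) tax else NULL)
}

#' Write a feature table to CSV/TSV
#'
#' Samples as rows; delimiter follows the file extension. Inverse of
#' [read_feature_table()] up to numeric formatting (15 significant digits,
#' round-trip safe to at least 12).
#'
#' @param ft A [feature_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- as.data.frame(signif(ft$counts, 15))
  df <- cbind(sample_id = rownames(ft$counts), df)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-sample continuous target from CSV/TSV
#'
#' Expects two columns: sample identifier, numeric value. Rejects duplicate
#' identifiers, missing values, and constant targets.
#'
#' @param path Path to a CSV or TSV file.
#' @return A validated [target_vector()].
#' @export
read_target <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("target file must have two columns: sample id, value")
  ids <- as.character(df[[1]])
  vals <- suppressWarnings(as.numeric(df[[2]]))
  bad <- ids[is.na(vals)]
  if (length(bad) > 0)
    stop("missing or non-numeric target value for sample(s): ",
         paste(head(bad, 5), collapse = ", "))
  target_vector(setNames(vals, ids))
}

#' Write a target vector to CSV/TSV
#' @param tv A [target_vector()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target <- function(tv, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(sample_id = names(tv), value = as.numeric(tv))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Lineage strings like "d__Bacteria; p__...; f__Flavobacteriaceae" are split on
# ";" and assigned to ranks by prefix (case-insensitive); prefix-less parts
# fall back to positional rank order domain..species.
.rank_prefixes <- c(d = "domain", k = "kingdom", p = "phylum", c = "class",
                    o = "order", f = "family", g = "genus", s = "species")
.rank_positions <- c("domain", "phylum", "class", "order", "family", "genus",
                     "species")

.parse_lineages <- function(lineages) {
  out <- lapply(lineages, function(s) {
    parts <- trimws(strsplit(s, ";")[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return(character(0))
    labs <- character(0)
    prefixed <- grepl("^[A-Za-z]__", parts)
    if (any(prefixed)) {
      for (p in parts[prefixed]) {
        rk <- .rank_prefixes[tolower(substr(p, 1, 1))]
        lab <- sub("^[A-Za-z]__", "", p)
        if (!is.na(rk) && nzchar(lab)) labs[rk] <- lab
      }
    } else {
      n <- min(length(parts), length(.rank_positions))
      labs <- setNames(parts[seq_len(n)], .rank_positions[seq_len(n)])
      labs <- labs[nzchar(labs)]
    }
    labs
  })
  out[vapply(out, length, 1L) > 0]
}

#' Read a feature taxonomy from a lineage file
#'
#' Two columns: feature id, semicolon-separated lineage string in
#' SILVA/Greengenes style (`d__...; p__...; f__...`). Rank prefixes are
#' parsed case-insensitively; lineages without prefixes are assigned by
#' position (domain, phylum, class, order, family, genus, species).
#'
#' @param path Path to a CSV/TSV lineage file with a header row.
#' @return Named list: feature id -> named character vector (rank -> label).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 2) stop("taxonomy file must have two columns: feature id, lineage")
  if (anyDuplicated(df[[1]])) stop("duplicate feature ids in taxonomy file")
  .parse_lineages(setNames(as.character(df[[2]]), as.character(df[[1]])))
}

#' Restrict a feature table and target to their common samples
#'
#' Inner join on sample ids: both outputs contain exactly the intersection,
#' in the feature table's order, values matched by id. Samples present in
#' only one input are dropped with a warning.
#'
#' @param ft A [feature_table()].
#' @param tv A [target_vector()].
#' @param min_samples Minimum admissible overlap; below this the data cannot
#'   support leave-one-out cross-validation and an error is raised.
#' @return List with elements `ft` and `tv`, sample-aligned.
#' @export
align_samples <- function(ft, tv, min_samples = 5) {
  common <- intersect(sample_ids(ft), names(tv))
  if (length(common) < min_samples)
    stop(sprintf("only %d samples shared between feature table and target (need >= %d)",
                 length(common), min_samples))
  dropped <- c(setdiff(sample_ids(ft), common), setdiff(names(tv), common))
  if (length(dropped) > 0)
    warning("dropped samples absent from one input: ",
            paste(head(dropped, 10), collapse = ", "), call. = FALSE)
  keep <- sample_ids(ft)[sample_ids(ft) %in% common]
  ft2 <- feature_table(ft$counts[keep, , drop = FALSE], taxonomy = ft$taxonomy)
  tv2 <- target_vector(unclass(tv)[keep])
  list(ft = ft2, tv = tv2)
}

#' Collapse features to a taxonomic rank
#'
#' Features sharing the same label at `rank` have their counts summed per
#' sample. Features with no label at that rank are pooled into a single
#' `Unclassified_<rank>` feature rather than dropped, so per-sample totals
#' are conserved exactly (the compositional transforms are closure-sensitive).
#'
#' @param ft A [feature_table()] with taxonomy.
#' @param rank Rank name present in the taxonomy (e.g. `"family"`).
#' @return A [feature_table()] whose features are the rank labels (plus
#'   `Unclassified_<rank>` if needed), each carrying a single-rank taxonomy.
#' @export
aggregate_to_rank <- function(ft, rank) {
  if (is.null(ft$taxonomy)) stop("feature table has no taxonomy")
  labs <- vapply(feature_ids(ft), function(f) {
    tx <- ft$taxonomy[[f]]
    if (!is.null(tx) && rank %in% names(tx)) tx[[rank]] else NA_character_
  }, character(1))
  if (all(is.na(labs)))
    stop("no feature has a label at rank '", rank, "'")
  labs[is.na(labs)] <- paste0("Unclassified_", rank)
  groups <- unique(labs)
  agg <- sapply(groups, function(g)
    rowSums(ft$counts[, labs == g, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(sample_ids(ft), groups))
  tax <- setNames(lapply(groups, function(g) setNames(g, rank)), groups)
  uncl <- paste0("Unclassified_", rank)
  tax[names(tax) == uncl] <- NULL
  feature_table(agg, taxonomy = if (length(tax) > 0) tax else NULL)
}

#' Keep only child features of given parent taxa
#'
#' Retains exactly the features whose label at `parent_rank` is in
#' `parents`; counts of retained features are unchanged. Used by the
#' two-tier workflow to restrict an ASV table to the children of
#' high-scoring families or orders.
#'
#' @param ft_child A [feature_table()] with taxonomy at the child level.
#' @param parent_rank Rank name of the parents (e.g. `"family"`).
#' @param parents Character vector of parent labels to keep.
#' @return A [feature_table()] restricted to matching child features.
#' @export
filter_children_of <- function(ft_child, parent_rank, parents) {
  if (is.null(ft_child$taxonomy)) stop("feature table has no taxonomy")
  keep <- vapply(feature_ids(ft_child), function(f) {
    tx <- ft_child$taxonomy[[f]]
    !is.null(tx) && parent_rank %in% names(tx) && tx[[parent_rank]] %in% parents
  }, logical(1))
  if (!any(keep))
    stop("no child features found for ", parent_rank, " label(s): ",
         paste(parents, collapse = ", "))
  kept <- feature_ids(ft_child)[keep]
  feature_table(ft_child$counts[, kept, drop = FALSE],
                taxonomy = ft_child$taxonomy[intersect(names(ft_child$taxonomy), kept)])
}
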