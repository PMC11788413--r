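#' Construct and validate a community table
#'
#' The central object of the pipeline: an integer matrix of read counts with
#' samples as rows and taxa (ASVs) as columns. Row names are sample ids,
#' column names taxon ids; both must be unique and counts non-negative
#' integers.
#'
#' @param counts numeric matrix of non-negative integer counts, samples x
#'   taxa, with unique dimnames.
#' @return the validated matrix with class `"community_table"` prepended.
#' @export
community_table <- function(counts) {
  if (!is.matrix(counts)) stop_format("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_format("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts))) stop_format("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop_format("duplicate taxon ids")
  if (any(!is.finite(counts))) stop_validation("non-finite counts")
  if (any(counts < 0)) stop_validation("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_validation("non-integer counts")
  storage.mode(counts) <- "integer"
  class(counts) <- c("community_table", class(counts))
  counts
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x), "samples x", ncol(x), "taxa;",
      "total reads", sum(x), "\n")
  invisible(x)
}

#' Read a community (ASV) count table from TSV
#'
#' Expects one header row of labels and one label column. Both dialects
#' common in amplicon outputs are supported: samples as rows (default) or
#' taxa as rows.
#'
#' @param path file path to a tab-separated count table.
#' @param orientation `"samples_as_rows"` or `"taxa_as_rows"`.
#' @return a [community_table()].
#' @export
read_community_table <- function(path,
                                 orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_format("non-numeric cells in count table")
  if (orientation == "taxa_as_rows") m <- t(m)
  community_table(m)
}

#' Write a community table to TSV
#'
#' @param table a [community_table()].
#' @param path output path.
#' @param orientation layout to write; see [read_community_table()].
#' @export
write_community_table <- function(table, path,
                                  orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  if (orientation == "taxa_as_rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "samples_as_rows") "sample_id" else "taxon_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Tips must be uniquely labeled and every edge must carry a branch length,
#' so that patristic (cophenetic) distances are defined for all tip pairs.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object, validated.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_format("could not parse Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_format("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop_format("duplicate tip labels: ",
                paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop_format("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop_validation("negative branch lengths")
  if (any(tree$tip.label == "")) stop_format("unlabeled tips")
  tree
}

#' Write a tree to Newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Required columns: `sample_id`, `region`, `steppe`, `site_id`, `latitude`,
#' `longitude`. Any extra columns are retained as environmental variables
#' (e.g. MAT, MAP, AI, pH). Missing environmental values are permitted and
#' propagate as `NA`.
#'
#' @param path path to a CSV file.
#' @return a data frame with class `"sample_metadata"`; environmental
#'   variable names are recorded in `attr(, "env_vars")`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Validate a sample metadata frame
#' @param df data frame with the required columns of [read_metadata()].
#' @return the validated frame, classed `"sample_metadata"`.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "region", "steppe", "site_id", "latitude", "longitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_format("missing required metadata column(s): ",
                paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_format("duplicate sample_id in metadata")
  if (any(!is.na(df$latitude) & abs(df$latitude) > 90))
    stop_validation("latitude out of [-90, 90]")
  if (any(!is.na(df$longitude) & abs(df$longitude) > 180))
    stop_validation("longitude out of [-180, 180]")
  env_vars <- setdiff(names(df), required)
  env_vars <- env_vars[vapply(df[env_vars], is.numeric, logical(1))]
  attr(df, "env_vars") <- env_vars
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Write sample metadata to CSV
#' @param metadata a `sample_metadata` frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join a community table to metadata
#'
#' Succeeds only when the join is a bijection on sample ids; otherwise an
#' explicit error names the offending samples.
#'
#' @param table a [community_table()].
#' @param metadata a `sample_metadata` frame.
#' @return the metadata reordered to match the table's sample order.
#' @export
join_metadata <- function(table, metadata) {
  ids <- rownames(table)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss))
    stop_validation("samples absent from metadata: ", paste(miss, collapse = ", "))
  out <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "env_vars") <- attr(metadata, "env_vars")
  class(out) <- class(metadata)
  out
}

#' Construct a labeled distance matrix
#'
#' The pipeline's uniform container for community dissimilarity, geographic
#' and environmental distance, betaNTI, and topology distance. Symmetric
#' with zero diagonal; non-negative unless `signed = TRUE` (betaNTI carries
#' a sign).
#'
#' @param values square numeric matrix with identical row/column labels.
#' @param signed logical; allow negative off-diagonal values.
#' @return the matrix with class `"dist_matrix"` and a `"signed"` attribute.
#' @export
dist_matrix <- function(values, signed = FALSE) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_format("distance matrix must be square")
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values)))
    stop_format("distance matrix must have identical row and column labels")
  ok <- !is.na(values)
  if (any(abs(values - t(values))[ok & t(ok)] > 1e-9))
    stop_validation("distance matrix not symmetric")
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE))
    stop_validation("nonzero diagonal")
  if (!signed && any(values[ok] < 0))
    stop_validation("negative values in unsigned distance matrix")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  attr(values, "signed") <- signed
  class(values) <- c("dist_matrix", class(values))
  values
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix:", nrow(x), "x", ncol(x),
      if (isTRUE(attr(x, "signed"))) "(signed)" else "", "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Read / write labeled distance matrices as TSV
#'
#' Serialized as a label header row plus a label column: diffable and
#' language-neutral.
#'
#' @param path file path.
#' @param signed logical, see [dist_matrix()].
#' @return [read_dist_matrix()] returns a `dist_matrix`.
#' @export
read_dist_matrix <- function(path, signed = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  dist_matrix(as.matrix(df), signed = signed)
}

#' @rdname read_dist_matrix
#' @param dm a `dist_matrix`.
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(id = rownames(dm), unclass(dm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a dist_matrix to a label subset/order.
subset_dm <- function(dm, labels) {
  miss <- setdiff(labels, rownames(dm))
  if (length(miss))
    stop_validation("labels absent from distance matrix: ",
                    paste(miss, collapse = ", "))
  dist_matrix(unclass(dm)[labels, labels, drop = FALSE],
              signed = isTRUE(attr(dm, "signed")))
}
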