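#' Construct an expression matrix with sample metadata
#'
#' Bundles a genes-by-samples matrix of FPKM values with a sample metadata
#' table mapping every sample to a tissue and an experimental group, and
#' validates the pairing.  This is the universal input object of the
#' pipeline: every downstream stage (contrast calling, overlap
#' classification, SOM module discovery, enrichment) consumes it.
#'
#' @param values Numeric matrix of non-negative, finite FPKM values with
#'   unique gene identifiers as row names and unique sample identifiers as
#'   column names.
#' @param metadata Data frame with columns `sample_id`, `tissue`, `group`;
#'   exactly one row per matrix column.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix, columns ordered as `metadata$sample_id`) and
#'   `metadata`.
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_config("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort_config("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(gene_ids)) {
    abort_config("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    abort_config("duplicate sample id: %s",
                 sample_ids[duplicated(sample_ids)][1L])
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    abort_config("negative or non-finite value at gene '%s', sample '%s'",
                 gene_ids[i[1L]], sample_ids[i[2L]])
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "group")
  if (!all(req %in% names(metadata))) {
    abort_config("metadata must have columns sample_id, tissue, group")
  }
  metadata <- metadata[, req]
  if (anyDuplicated(metadata$sample_id)) {
    abort_config("duplicate metadata record for sample '%s'",
                 metadata$sample_id[duplicated(metadata$sample_id)][1L])
  }
  missing_meta <- setdiff(sample_ids, metadata$sample_id)
  if (length(missing_meta)) {
    abort_config("sample '%s' present in matrix but absent from metadata",
                 missing_meta[1L])
  }
  extra_meta <- setdiff(metadata$sample_id, sample_ids)
  if (length(extra_meta)) {
    abort_config("sample '%s' present in metadata but absent from matrix",
                 extra_meta[1L])
  }
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("tissues: %s\n",
              paste(unique(x$metadata$tissue), collapse = ", ")))
  cat(sprintf("groups:  %s\n",
              paste(unique(x$metadata$group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an FPKM matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and a first column of gene identifiers; the metadata file is
#' tab-separated with columns `sample_id`, `tissue`, `group`.  Parsing is
#' locale-independent (decimal point only); any non-numeric or negative
#' cell is reported with its gene/sample coordinates.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return A validated [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2L) abort_config("matrix file has no sample columns")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort_config("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], gene_ids[bad[1L]], sample_ids[j])
    }
    vals[, j] <- num
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort_config("negative value at gene '%s', sample '%s'",
                 gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]])
  }
  metadata <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE,
                                colClasses = "character", quote = "")
  expression_matrix(vals, metadata)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, `em`.
#' @export
write_expression_matrix <- function(em, matrix_path, metadata_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, matrix_path)
  write_table(em$metadata, metadata_path)
  invisible(em)
}

# Sample ids belonging to one tissue x group cell.
samples_for <- function(em, tissue, group) {
  md <- em$metadata
  md$sample_id[md$tissue == tissue & md$group == group]
}

# Mean FPKM per gene for a set of (tissue, group) conditions.
# `conditions` is a data.frame with columns tissue, group.
condition_means <- function(em, conditions) {
  labs <- paste(conditions$tissue, conditions$group)
  out <- matrix(NA_real_, nrow = nrow(em$values), ncol = nrow(conditions),
                dimnames = list(rownames(em$values), labs))
  for (i in seq_len(nrow(conditions))) {
    ids <- samples_for(em, conditions$tissue[i], conditions$group[i])
    if (!length(ids)) {
      abort_config("condition '%s' has no samples", labs[i])
    }
    out[, i] <- rowMeans(em$values[, ids, drop = FALSE])
  }
  out
}
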