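#' Over-representation analysis via Fisher's exact test
#'
#' Tests every set of a collection for over-representation in a gene
#' list.  With `N` universe genes, `K` of them in the set, and a list of
#' size `n` overlapping the set in `k` genes, the p-value is the
#' one-sided upper hypergeometric tail `P(X >= k)`, X ~
#' Hypergeom(N, K, n).  Benjamini-Hochberg adjustment is applied across
#' all sets tested for the list; significance is `q < 0.05`.  Set
#' members are intersected with the universe before counting; sets with
#' no members in the universe are reported with p = 1.
#'
#' @param gene_list Character vector of genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of background genes.
#' @param sets A `gene_set_collection`.
#' @return Data frame (class `enrichment_result`) with one row per set:
#'   `set`, `k`, `K`, `n`, `N`, `odds_ratio`, `p_value`, `q_value`,
#'   `significant`.
#' @export
fisher_enrichment <- function(gene_list, universe, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) abort_config("empty universe")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    abort_config("gene list contains %d genes outside the universe (e.g. '%s')",
                 length(outside), outside[1L])
  }
  n <- length(gene_list)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$members, universe)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    ## odds ratio of the 2x2 table (list x set), Inf when a zero cell
    ## makes the denominator vanish
    a <- k; b <- n - k; c_ <- K - k; d <- N - K - n + k
    or <- if (b * c_ == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * c_)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- benjamini_hochberg(res$p_value)
  res$significant <- res$q_value < 0.05
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Enrichment significance matrix with clustered ordering
#'
#' Runs [fisher_enrichment()] for each labeled gene list and assembles a
#' sets x lists matrix of -log10 p-values.  Rows (sets) and columns
#' (lists) are ordered by average-linkage hierarchical clustering on the
#' Euclidean distance between their -log10 p profiles; inputs are sorted
#' by label first so the leaf order is deterministic.  This is the data
#' behind a clustered enrichment heat map.
#'
#' @param lists Named list of character vectors (>= 2 gene lists).
#' @param universe Background gene vector.
#' @param sets A `gene_set_collection`.
#' @return List with `matrix` (-log10 p, ordered), `row_order`,
#'   `col_order` (labels in clustered order), and the `hclust` trees
#'   `row_hclust` / `col_hclust` (NULL when a dimension has < 3 entries).
#' @export
enrichment_matrix <- function(lists, universe, sets) {
  if (length(lists) < 2L) {
    abort_config("need at least 2 gene lists, got %d", length(lists))
  }
  if (is.null(names(lists)) || anyDuplicated(names(lists))) {
    abort_config("gene lists must have unique names")
  }
  lists <- lists[order(names(lists))]
  mat <- vapply(lists, function(gl) {
    res <- fisher_enrichment(gl, universe, sets)
    stats::setNames(-log10(res$p_value), res$set)
  }, numeric(length(sets)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  order_by_clustering <- function(m) {
    if (nrow(m) < 3L) return(list(order = seq_len(nrow(m)), tree = NULL))
    tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                          method = "average")
    list(order = tree$order, tree = tree)
  }
  rows <- order_by_clustering(mat)
  cols <- order_by_clustering(t(mat))
  out <- mat[rows$order, cols$order, drop = FALSE]
  list(matrix = out,
       row_order = rownames(out), col_order = colnames(out),
       row_hclust = rows$tree, col_hclust = cols$tree)
}
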