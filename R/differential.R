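#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Returns FDR-adjusted values in the input order: with p sorted
#' ascending, `q_(i) = min_{j >= i}(m * p_(j) / j)` clipped to 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort_config("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorised two-sided Welch t-test across rows of two matrices of
# log2(FPKM+1) replicate values.  Rows with zero variance in both groups
# get p = 1 when the means are equal and p = 0 otherwise (a deterministic
# difference).
welch_rows <- function(x_ref, x_alt) {
  n1 <- ncol(x_ref); n2 <- ncol(x_alt)
  m1 <- rowMeans(x_ref); m2 <- rowMeans(x_alt)
  v1 <- rowSums((x_ref - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_alt - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  ok <- !degenerate
  if (any(ok)) {
    tt <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 /
      ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(tt), df)
  }
  list(p = p, mean_ref = m1, mean_alt = m2)
}

#' Call differentially expressed genes for one pairwise contrast
#'
#' Within one tissue, compares two groups gene-by-gene with a two-sided
#' Welch t-test on log2(FPKM+1) replicate values and controls the FDR
#' across all genes of the contrast with Benjamini-Hochberg.  A gene is
#' significant when its q-value is strictly below `alpha`.  The log2 fold
#' change is `log2((mean_alt + 1) / (mean_ref + 1))` on FPKM group means,
#' oriented alternative minus reference.
#'
#' @param matrix An [expression_matrix()].
#' @param tissue Tissue label.
#' @param group_ref,group_alt Reference and alternative group labels; for
#'   a disease contrast orient control -> disease, for a treatment
#'   contrast disease -> treated-disease.
#' @param alpha FDR threshold (default 0.05, strict inequality).
#' @return A `contrast_result`: data frame with columns `gene`,
#'   `mean_ref`, `mean_alt`, `log2_fold_change`, `p_value`, `q_value`,
#'   `direction` (up/down/none), `significant`; attributes
#'   `contrast_name` ("(tissue) ref vs alt"), `tissue`, `alpha`.
#' @export
call_degs <- function(matrix, tissue, group_ref, group_alt, alpha = 0.05) {
  stopifnot(inherits(matrix, "expression_matrix"))
  md <- matrix$metadata
  if (!tissue %in% md$tissue) abort_config("unknown tissue '%s'", tissue)
  for (g in c(group_ref, group_alt)) {
    if (!g %in% md$group) abort_config("unknown group '%s'", g)
  }
  ref_ids <- samples_for(matrix, tissue, group_ref)
  alt_ids <- samples_for(matrix, tissue, group_alt)
  if (length(ref_ids) < 2L || length(alt_ids) < 2L) {
    stop(sprintf(
      "insufficient replication in tissue '%s' (%s: %d, %s: %d); need >= 2",
      tissue, group_ref, length(ref_ids), group_alt, length(alt_ids)),
      call. = FALSE)
  }
  y <- log2(matrix$values + 1)
  w <- welch_rows(y[, ref_ids, drop = FALSE], y[, alt_ids, drop = FALSE])
  mean_ref <- rowMeans(matrix$values[, ref_ids, drop = FALSE])
  mean_alt <- rowMeans(matrix$values[, alt_ids, drop = FALSE])
  lfc <- log2((mean_alt + 1) / (mean_ref + 1))
  q <- benjamini_hochberg(w$p)
  sig <- q < alpha
  direction <- rep("none", length(lfc))
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"
  res <- data.frame(gene = rownames(matrix$values),
                    mean_ref = mean_ref, mean_alt = mean_alt,
                    log2_fold_change = lfc,
                    p_value = w$p, q_value = q,
                    direction = direction, significant = sig,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res,
            contrast_name = sprintf("(%s) %s vs %s",
                                    tissue, group_ref, group_alt),
            tissue = tissue, alpha = alpha,
            class = c("contrast_result", "data.frame"))
}

#' Extract the signed DEG set from a contrast result
#'
#' @param result A `contrast_result` from [call_degs()].
#' @return A `deg_set`: list with `contrast_name`, `tissue` and `members`,
#'   a named numeric vector mapping each significant gene to the sign
#'   (+1/-1) of its log2 fold change.  Significant genes with an exactly
#'   zero fold change (possible only degenerately) are omitted.
#' @export
extract_deg_set <- function(result) {
  stopifnot(inherits(result, "contrast_result"))
  keep <- result$significant & result$log2_fold_change != 0
  structure(list(contrast_name = attr(result, "contrast_name"),
                 tissue = attr(result, "tissue"),
                 members = stats::setNames(
                   sign(result$log2_fold_change[keep]), result$gene[keep])),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set '%s': %d genes (%d up, %d down)\n",
              x$contrast_name, length(x$members),
              sum(x$members > 0), sum(x$members < 0)))
  invisible(x)
}
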