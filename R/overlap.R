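#' Classify shared DEGs as reversed or exacerbated by treatment
#'
#' Intersects the disease-contrast DEG set (control -> disease) with the
#' treatment-contrast DEG set (disease -> treated disease).  A shared gene
#' is *reversed* when its two signs are opposite (the sign product is -1)
#' and *exacerbated* when they agree.  Genes significant in only one
#' contrast land in `disease_only` / `treatment_only`.  Percentages are
#' taken over the shared set and left unrounded.
#'
#' @param disease,treatment `deg_set` objects from [extract_deg_set()],
#'   both derived from the same tissue's gene universe.
#' @param tissue Tissue label; defaults to the disease set's tissue.
#' @return An `overlap_classification`: list with `tissue`, gene-set
#'   fields `reversed`, `exacerbated`, `disease_only`, `treatment_only`,
#'   and `pct_reversed` / `pct_exacerbated` (NA when no genes are shared).
#' @export
classify_overlap <- function(disease, treatment, tissue = disease$tissue) {
  stopifnot(inherits(disease, "deg_set"), inherits(treatment, "deg_set"))
  d <- disease$members
  t_ <- treatment$members
  shared <- intersect(names(d), names(t_))
  prod_sign <- d[shared] * t_[shared]
  if (any(prod_sign == 0)) {
    stop("internal error: shared gene with sign 0", call. = FALSE)
  }
  reversed <- sort(shared[prod_sign < 0])
  exacerbated <- sort(shared[prod_sign > 0])
  n_shared <- length(shared)
  structure(list(
    tissue = tissue,
    reversed = reversed,
    exacerbated = exacerbated,
    disease_only = sort(setdiff(names(d), shared)),
    treatment_only = sort(setdiff(names(t_), shared)),
    pct_reversed = if (n_shared) 100 * length(reversed) / n_shared
                   else NA_real_,
    pct_exacerbated = if (n_shared) 100 * length(exacerbated) / n_shared
                      else NA_real_
  ), class = "overlap_classification")
}

#' @export
print.overlap_classification <- function(x, ...) {
  cat(sprintf(
    "overlap_classification [%s]: %d shared (%.1f%% reversed, %.1f%% exacerbated), %d disease-only, %d treatment-only\n",
    x$tissue, length(x$reversed) + length(x$exacerbated),
    x$pct_reversed, x$pct_exacerbated,
    length(x$disease_only), length(x$treatment_only)))
  invisible(x)
}

#' Compare two labeled gene sets across tissues or strata
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param label_a,label_b Labels (e.g. "SCN Reversed", "Glom Reversed").
#' @return List with `label_a`, `label_b`, counts `n_a`, `n_b`,
#'   `n_shared`, `n_a_only`, `n_b_only`, and `shared`, the shared gene
#'   identifiers sorted lexicographically.
#' @export
cross_tissue_compare <- function(set_a, set_b,
                                 label_a = "A", label_b = "B") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- sort(intersect(set_a, set_b), method = "radix")
  list(label_a = label_a, label_b = label_b,
       n_a = length(set_a), n_b = length(set_b),
       n_shared = length(shared),
       n_a_only = length(setdiff(set_a, set_b)),
       n_b_only = length(setdiff(set_b, set_a)),
       shared = shared)
}

#' Stratify a disease DEG set by its treatment response
#'
#' Splits the disease DEG set into the three strata used for cross-tissue
#' comparison: genes unaffected by treatment ("db/db only"), genes pushed
#' further in the same direction ("Exacerbated"), and genes pushed back
#' ("Reversed").  Labels carry the tissue prefix.
#'
#' @param classification An `overlap_classification`.
#' @param disease The disease `deg_set` the classification was built from.
#' @return Named list of three character vectors; names are
#'   `"<tissue> db/db only"`, `"<tissue> Exacerbated"`,
#'   `"<tissue> Reversed"`.
#' @export
stratify_deg_sets <- function(classification, disease) {
  stopifnot(inherits(classification, "overlap_classification"),
            inherits(disease, "deg_set"))
  t <- classification$tissue
  out <- list(classification$disease_only,
              classification$exacerbated,
              classification$reversed)
  names(out) <- paste(t, c("db/db only", "Exacerbated", "Reversed"))
  out
}
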