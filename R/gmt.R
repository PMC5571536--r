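#' Read a gene-set collection from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a line are collapsed; member order is not
#' meaningful.  Gene identifiers are opaque, case-sensitive strings.
#'
#' @param gmt_path Path to a GMT file.
#' @return A `gene_set_collection`: a named list whose elements are lists
#'   with fields `description` and `members` (character vector).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  names(sets) <- rep_len("", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort_config("GMT line %d has %d tab-separated fields; need >= 3",
                   i, length(fields))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      abort_config("GMT line %d ('%s') has no members", i, fields[1L])
    }
    names(sets)[i] <- fields[1L]
    sets[[i]] <- list(description = fields[2L], members = members)
  }
  if (anyDuplicated(names(sets))) {
    abort_config("duplicate gene-set name: %s",
                 names(sets)[duplicated(names(sets))][1L])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets A `gene_set_collection`.
#' @param gmt_path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gene_sets <- function(sets, gmt_path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(sets)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1))
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L))
  invisible(x)
}
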