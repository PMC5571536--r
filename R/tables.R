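#' Write a rectangular result table as TSV
#'
#' Writes a data frame with a header row, tab-separated.  Numeric columns
#' are rendered with 8 significant digits so that reading the file back
#' reproduces every value to at least 6 significant digits.  Labels (column
#' names and character cells) must not contain tab characters.
#'
#' @param records A data frame; may have zero rows (header-only output).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (any(grepl("\t", names(records), fixed = TRUE))) {
    abort_config("column names must be tab-free")
  }
  cols <- lapply(records, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- sprintf("%.8g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      if (any(grepl("\t", out, fixed = TRUE))) {
        abort_config("labels must be tab-free")
      }
      out
    }
  })
  header <- paste(names(records), collapse = "\t")
  body <- if (nrow(records)) {
    do.call(paste, c(cols, sep = "\t"))
  } else character(0)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame with columns typed by [utils::type.convert()].
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
}
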