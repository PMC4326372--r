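# Deterministic TSV output for every result table.

#' Write a result table as deterministic TSV
#'
#' Tab-delimited with a header row. Rows are ordered by every column from
#' left to right (character columns in C-locale order), so identical inputs
#' always produce byte-identical files. List-columns (e.g. cluster member
#' lists) are collapsed with `","` before writing.
#'
#' @param x A data frame (any cosreg result table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  for (col in names(x)[is_list]) {
    x[[col]] <- vapply(x[[col]], function(v) paste(as.character(v), collapse = ","),
                       character(1))
  }
  if (nrow(x) > 0 && ncol(x) > 0) {
    ord <- do.call(order, c(unname(as.list(x)), list(method = "radix")))
    x <- x[ord, , drop = FALSE]
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot write '%s': directory does not exist.", path))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
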