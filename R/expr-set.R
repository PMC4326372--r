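# Expression container: a probes x samples matrix of log2 intensities plus a
# per-column sample design. Matrix-backed so normalization and cosine steps
# stay linear algebra; tidy() views it as a long tibble.

DAYS <- c("E7", "E9", "E11")
REGIONS <- c("feather", "scale")
COMPARTMENTS <- c("epithelium", "mesenchyme")

#' Short group label for a (day, region, compartment) combination
#'
#' Follows the field's sample naming: day, first letter of the region, first
#' letter of the compartment, e.g. `E7fe` for day-7 feather epithelium.
#'
#' @param day Character vector, one of `"E7"`, `"E9"`, `"E11"`.
#' @param region Character vector, `"feather"` or `"scale"`.
#' @param compartment Character vector, `"epithelium"` or `"mesenchyme"`.
#' @return Character vector of group labels.
#' @export
#' @examples
#' group_label("E7", "feather", "epithelium")
group_label <- function(day, region, compartment) {
  paste0(day, substr(region, 1, 1), substr(compartment, 1, 1))
}

validate_design <- function(design) {
  if (!is.data.frame(design)) {
    abort("`design` must be a data frame.")
  }
  needed <- c("sample_id", "day", "region", "compartment", "replicate")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("design sample_ids must be unique.")
  }
  bad_day <- setdiff(unique(design$day), DAYS)
  if (length(bad_day) > 0) {
    abort(paste0("unknown day value(s): ", paste(bad_day, collapse = ", ")))
  }
  bad_region <- setdiff(unique(design$region), REGIONS)
  if (length(bad_region) > 0) {
    abort(paste0("unknown region value(s): ",
                 paste(bad_region, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(design$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0) {
    abort(paste0("unknown compartment value(s): ",
                 paste(bad_comp, collapse = ", ")))
  }
  if (any(design$replicate < 1) || any(design$replicate != round(design$replicate))) {
    abort("design replicate indices must be positive integers.")
  }
  design <- as_tibble(design)
  design$replicate <- as.integer(design$replicate)
  if (!"group" %in% names(design)) {
    design$group <- group_label(design$day, design$region, design$compartment)
  }
  design
}

#' Construct an expression set from a matrix and a sample design
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns. Values are log2-scale intensities.
#' @param design Data frame with columns `sample_id`, `day`, `region`,
#'   `compartment`, `replicate`; one row per matrix column.
#' @param input_scale Either `"log2"` (default; values used as-is) or
#'   `"linear"`, in which case `log2(x + 1)` is applied.
#' @return A `cosreg_expr` object.
#' @export
expr_set <- function(values, design, input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  design <- validate_design(design)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values))) {
    abort("`values` must have probe ids as rownames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate probe ids in expression matrix.")
  }
  if (ncol(values) != nrow(design)) {
    abort(sprintf("matrix has %d columns but design describes %d samples.",
                  ncol(values), nrow(design)))
  }
  if (!is.null(colnames(values))) {
    missing <- setdiff(design$sample_id, colnames(values))
    if (length(missing) > 0) {
      abort(paste0("sample(s) in design not found in matrix: ",
                   paste(missing, collapse = ", ")))
    }
    values <- values[, design$sample_id, drop = FALSE]
  } else {
    colnames(values) <- design$sample_id
  }
  if (any(!is.finite(values))) {
    abort("expression matrix contains missing or non-finite values.")
  }
  if (input_scale == "linear") {
    if (any(values < 0)) {
      abort("linear-scale input must be non-negative.")
    }
    values <- log2(values + 1)
  }
  structure(list(values = values, design = design), class = "cosreg_expr")
}

#' @export
print.cosreg_expr <- function(x, ...) {
  cat(sprintf("<cosreg_expr> %d probes x %d samples (%d groups)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$group))))
  cat("groups:", paste(unique(x$design$group), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.cosreg_expr <- function(x) dim(x$values)

#' Tidy an expression set into a long tibble
#'
#' @param x A `cosreg_expr` object.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `group`, `value`.
#' @export
tidy.cosreg_expr <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "value")
  long %>%
    left_join(x$design %>% select("sample_id", "group"), by = "sample_id") %>%
    select("probe_id", "sample_id", "group", "value")
}

#' Read a sample design table
#'
#' Tab-delimited with header; columns `sample_id`, `day`, `region`,
#' `compartment`, `replicate`.
#'
#' @param path File path.
#' @return A tibble with one row per sample plus a derived `group` column.
#' @export
read_design_tsv <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE,
                            locale = readr::locale(decimal_mark = "."))
  validate_design(design)
}

# Parse a character matrix of expression values, reporting the first
# offending cell on failure.
parse_numeric_cells <- function(chr, probe_ids, sample_ids, path) {
  suppressWarnings(num <- matrix(as.numeric(chr), nrow = nrow(chr)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric expression value %s in '%s' at probe '%s' (row %d), sample '%s' (column %d).",
      dQuote(chr[bad[1], bad[2]]), path, probe_ids[bad[1]], bad[1],
      sample_ids[bad[2]], bad[2]))
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  num
}

#' Read an expression matrix and its design from tab-delimited files
#'
#' The expression file has a header row of sample ids and a first column of
#' probe ids. Columns are re-ordered to follow the design file. Duplicate
#' probe rows and samples absent from the design are hard errors.
#'
#' @param path Expression TSV path.
#' @param design_path Design TSV path (see [read_design_tsv()]).
#' @param input_scale `"log2"` (default) or `"linear"`; see [expr_set()].
#' @return A `cosreg_expr` object.
#' @export
read_expression_tsv <- function(path, design_path,
                                input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  design <- read_design_tsv(design_path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         locale = readr::locale(decimal_mark = "."))
  if (ncol(raw) < 2) {
    abort(sprintf("'%s' must have a probe-id column plus sample columns.", path))
  }
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    abort(paste0("duplicated probe_id row(s) in '", path, "': ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  sample_ids <- names(raw)[-1]
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing) > 0) {
    abort(paste0("sample_id(s) in '", path, "' missing from design: ",
                 paste(missing, collapse = ", ")))
  }
  absent <- setdiff(design$sample_id, sample_ids)
  if (length(absent) > 0) {
    abort(paste0("design sample_id(s) absent from '", path, "': ",
                 paste(absent, collapse = ", ")))
  }
  chr <- as.matrix(raw[, -1, drop = FALSE])
  values <- parse_numeric_cells(chr, probe_ids, sample_ids, path)
  expr_set(values[, design$sample_id, drop = FALSE], design,
           input_scale = input_scale)
}

#' Read the table block of a GEO series-matrix file
#'
#' Parses only the rows between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`; quoted identifiers are unquoted. Series-matrix
#' metadata is not interpreted, so the sample design must be supplied
#' separately and is matched to the table's sample columns.
#'
#' @param path Series-matrix file path.
#' @param design Data frame of the sample design, or a path to a design TSV.
#' @param input_scale `"log2"` (default) or `"linear"`; see [expr_set()].
#' @return A `cosreg_expr` object.
#' @export
read_series_matrix <- function(path, design,
                               input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  if (is.character(design) && length(design) == 1) {
    design <- read_design_tsv(design)
  } else {
    design <- validate_design(design)
  }
  lines <- readr::read_lines(path)
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    abort(sprintf(
      "'%s' does not contain a !series_matrix_table_begin/!series_matrix_table_end block.",
      path))
  }
  block <- lines[(begin + 1):(end - 1)]
  fields <- strsplit(block, "\t", fixed = TRUE)
  unquote <- function(v) gsub('^"|"$', "", v)
  header <- unquote(fields[[1]])
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(sprintf("ragged series-matrix table in '%s'.", path))
  }
  cells <- do.call(rbind, body)
  probe_ids <- unquote(cells[, 1])
  if (anyDuplicated(probe_ids)) {
    abort(sprintf("duplicated probe ids in series-matrix table of '%s'.", path))
  }
  sample_ids <- header[-1]
  values <- parse_numeric_cells(cells[, -1, drop = FALSE], probe_ids,
                                sample_ids, path)
  missing <- setdiff(design$sample_id, sample_ids)
  if (length(missing) > 0) {
    abort(paste0("design sample_id(s) absent from series-matrix table: ",
                 paste(missing, collapse = ", ")))
  }
  expr_set(values[, design$sample_id, drop = FALSE], design,
           input_scale = input_scale)
}
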