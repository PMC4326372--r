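# GMT gene-set collections for the enrichment stage.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member identifiers.
#' @param universe_size Positive integer, the size N of the gene universe the
#'   hypergeometric test draws from.
#' @param universe Optional character vector enumerating the universe; when
#'   supplied it overrides `universe_size` and lets [enrich()] drop
#'   out-of-universe query genes.
#' @return A `cosreg_gene_sets` object.
#' @export
gene_sets <- function(sets, universe_size = NULL, universe = NULL) {
  if (!is.list(sets)) abort("`sets` must be a named list.")
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == ""))) {
    abort("every gene set must be named.")
  }
  if (any(lengths(sets) == 0)) {
    abort("every gene set must be non-empty.")
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    universe_size <- length(universe)
  }
  if (is.null(universe_size) || universe_size < 1 ||
      universe_size != round(universe_size)) {
    abort("`universe_size` must be a positive integer.")
  }
  structure(list(sets = sets, universe_size = as.integer(universe_size),
                 universe = universe),
            class = "cosreg_gene_sets")
}

#' @export
print.cosreg_gene_sets <- function(x, ...) {
  cat(sprintf("<cosreg_gene_sets> %d sets, universe N = %d\n",
              length(x$sets), x$universe_size))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then members. The description is discarded; duplicated members within a
#' line are counted once (with a warning). A line with fewer than three
#' fields is an error reported with its line number. An empty file yields an
#' empty, valid collection.
#'
#' @param path GMT file path.
#' @inheritParams gene_sets
#' @return A `cosreg_gene_sets` object.
#' @export
read_gmt <- function(path, universe_size, universe = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d of '%s' has %d field(s); need name, description, members.",
                    i, path, length(fields)))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("GMT set '%s' (line %d) has duplicated members; counting each once.",
                   fields[1], i))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  gene_sets(sets, universe_size = universe_size, universe = universe)
}
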