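# Across-array quantile normalization and per-group means.

quantile_normalize_matrix <- function(M) {
  ref <- rowMeans(apply(M, 2, sort))
  out <- M
  for (j in seq_len(ncol(M))) {
    o <- order(M[, j])
    sorted <- M[o, j]
    # Tied entries all receive the mean of the reference values spanning
    # their tied ranks.
    grp <- cumsum(!duplicated(sorted))
    out[o, j] <- ave(ref, grp)
  }
  out
}

#' Quantile-normalize an expression matrix across arrays
#'
#' Forces every column (array) to share the same empirical distribution: the
#' value at rank r in each column becomes the mean over columns of each
#' column's r-th order statistic. Tied entries within a column all receive
#' the mean of the reference values for their tied ranks, so ties stay tied.
#' The map is rank-preserving within each column and idempotent.
#'
#' @param x A `cosreg_expr` object or a numeric matrix with at least two
#'   columns.
#' @return An object of the same type with normalized values.
#' @export
#' @examples
#' M <- cbind(a = c(0, 2, 4), b = c(1, 2, 3))
#' rownames(M) <- c("p1", "p2", "p3")
#' quantile_normalize(M)
quantile_normalize <- function(x) {
  M <- if (inherits(x, "cosreg_expr")) x$values else x
  if (!is.matrix(M) || !is.numeric(M)) {
    abort("`x` must be a cosreg_expr or a numeric matrix.")
  }
  if (ncol(M) < 2) {
    abort("quantile normalization needs at least 2 columns.")
  }
  out <- quantile_normalize_matrix(M)
  if (inherits(x, "cosreg_expr")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Arithmetic group means of log2 expression
#'
#' Averages replicate columns within each (day, region, compartment) group on
#' the log2 scale (i.e. the geometric-mean convention on the linear scale).
#'
#' @param x A `cosreg_expr` object.
#' @return A `cosreg_means` tibble: `probe_id` plus one column per group, in
#'   design order.
#' @export
group_means <- function(x) {
  if (!inherits(x, "cosreg_expr")) abort("`x` must be a cosreg_expr.")
  groups <- unique(x$design$group)
  means <- vapply(groups, function(g) {
    cols <- x$design$sample_id[x$design$group == g]
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- as_tibble(means)
  out <- bind_cols(tibble(probe_id = rownames(x$values)), out)
  class(out) <- c("cosreg_means", class(out))
  attr(out, "groups") <- groups
  out
}
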