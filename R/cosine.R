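# Probe-by-seed cosine similarity, Fisher z-transformation and tail calling.

FISHER_CLIP <- 1 - 1e-7

#' Cosine similarity of two expression vectors
#'
#' `cos(theta) = sum(a*b) / sqrt(sum(a^2) * sum(b^2))`, clipped to
#' `[-1, 1]` against floating-point round-off. Vectors of zero norm are an
#' error: the caller is expected to have excluded flat probes.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(3, 2, 1))  # 10/14
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine undefined for a zero-norm vector.")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Mean-center each probe across samples
#'
#' Subtracts each probe's across-sample mean. Probes left with zero variance
#' (flat rows) are flagged in the `"zero_variance"` attribute for exclusion
#' from similarity scoring.
#'
#' @param x A `cosreg_expr` object.
#' @return The centered `cosreg_expr`, with attribute `"zero_variance"`
#'   listing flat probe ids.
#' @export
center_probes <- function(x) {
  if (!inherits(x, "cosreg_expr")) abort("`x` must be a cosreg_expr.")
  centered <- x$values - rowMeans(x$values)
  flat <- rownames(centered)[rowSums(centered^2) == 0]
  x$values <- centered
  attr(x, "zero_variance") <- flat
  x
}

#' Fisher z-transformation of a cosine or correlation value
#'
#' `z = arctanh(r) = log((1 + r) / (1 - r)) / 2`, a variance-stabilizing map
#' of `(-1, 1)` onto the real line. Magnitudes at or beyond `1 - 1e-7` are
#' clipped to `1 - 1e-7` so the poles stay finite while preserving order.
#'
#' @param r Numeric vector with `|r| <= 1` (up to round-off).
#' @return Numeric vector of z values.
#' @export
#' @examples
#' fisher_z(0.5)  # 0.549306...
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) {
    abort("`r` must lie in [-1, 1].")
  }
  r <- pmin(FISHER_CLIP, pmax(-FISHER_CLIP, r))
  atanh(r)
}

# Rank-based per-seed tail selection with deterministic lexicographic
# tie-breaks at the cut.
select_tail <- function(values, ids, n_tail, decreasing) {
  ord <- if (decreasing) {
    order(-values, ids, method = "radix")
  } else {
    order(values, ids, method = "radix")
  }
  ord[seq_len(n_tail)]
}

#' Score every probe against every seed and call similarity tails
#'
#' Computes the cosine of each probe vector against each seed vector over the
#' full sample space (after optional mean-centering, in which case cosine
#' equals the Pearson correlation), Fisher-transforms the values, and flags
#' per seed the `ceiling(tail_fraction * P)` probes with the largest z as
#' co-regulated (`"co"`) and the same number with the smallest z as
#' reciprocally regulated (`"reciprocal"`), `P` being the number of scored
#' probes. At the default 0.5% per tail this flags 1% of the probe set per
#' seed. The seed's self-comparison is excluded; ties at a cut are broken by
#' probe id (lexicographic), so results are deterministic. Tail lists of
#' different seeds may overlap.
#'
#' @param x A `cosreg_expr` object (typically quantile-normalized).
#' @param seeds Seed tibble from [select_seeds()], restricted to one
#'   comparison.
#' @param tail_fraction Fraction per tail, in (0, 0.5). Default 0.005.
#' @param center Mean-center probe vectors before cosine (default `TRUE`).
#'   Centering makes both tails realizable on all-positive log2 data.
#' @param pooled Call tails on the pooled (seed, probe) distribution of the
#'   whole seed group instead of per seed. Default `FALSE` (per seed).
#' @return A `cosreg_simtab` object holding the probe-by-seed cosine matrix
#'   and a tibble of tail calls (`tidy()` to extract it).
#' @export
similarity_table <- function(x, seeds, tail_fraction = 0.005, center = TRUE,
                             pooled = FALSE) {
  if (!inherits(x, "cosreg_expr")) abort("`x` must be a cosreg_expr.")
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1 ||
      tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("`tail_fraction` must lie strictly between 0 and 0.5.")
  }
  comparison <- unique(seeds$comparison)
  if (length(comparison) != 1) {
    abort("`seeds` must cover exactly one comparison; split by comparison first.")
  }
  if (center) {
    x <- center_probes(x)
    flat <- attr(x, "zero_variance")
  } else {
    flat <- rownames(x$values)[rowSums(x$values^2) == 0]
  }
  M <- x$values
  if (length(flat) > 0) {
    warn(sprintf("%d zero-norm probe(s) excluded from similarity scoring.",
                 length(flat)))
    M <- M[setdiff(rownames(M), flat), , drop = FALSE]
  }
  probe_ids <- rownames(M)
  seed_ids <- sort(unique(seeds$probe_id))
  missing <- setdiff(seed_ids, probe_ids)
  if (length(missing) > 0) {
    abort(paste0("seed probe(s) not present (or flat) in matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  P <- nrow(M)
  n_tail <- ceiling(tail_fraction * P)
  if (2 * n_tail > P - 1) {
    abort("too few probes for the requested tail fraction.")
  }
  Mn <- M / sqrt(rowSums(M^2))
  C <- Mn %*% t(Mn[seed_ids, , drop = FALSE])
  C[C > 1] <- 1
  C[C < -1] <- -1

  if (!pooled) {
    tails <- purrr::map_dfr(seed_ids, function(s) {
      keep <- probe_ids != s
      ids <- probe_ids[keep]
      v <- C[keep, s]
      co <- select_tail(v, ids, n_tail, decreasing = TRUE)
      re <- select_tail(v, ids, n_tail, decreasing = FALSE)
      idx <- c(co, re)
      tibble(
        seed_id = s,
        probe_id = ids[idx],
        cosine = v[idx],
        tail = rep(c("co", "reciprocal"), each = n_tail)
      )
    })
  } else {
    pairs <- tibble(
      seed_id = rep(seed_ids, each = P),
      probe_id = rep(probe_ids, times = length(seed_ids)),
      cosine = as.vector(C)
    ) %>%
      filter(.data$seed_id != .data$probe_id)
    m_pool <- ceiling(tail_fraction * nrow(pairs))
    key <- paste(pairs$seed_id, pairs$probe_id)
    co <- select_tail(pairs$cosine, key, m_pool, decreasing = TRUE)
    re <- select_tail(pairs$cosine, key, m_pool, decreasing = FALSE)
    tails <- bind_rows(
      pairs[co, ] %>% mutate(tail = "co"),
      pairs[re, ] %>% mutate(tail = "reciprocal")
    )
  }
  tails <- tails %>%
    mutate(comparison = comparison, z = fisher_z(.data$cosine)) %>%
    select("comparison", "seed_id", "probe_id", "cosine", "z", "tail") %>%
    arrange(.data$seed_id, .data$tail, .data$probe_id)

  structure(list(
    comparison = comparison,
    cosine = C,
    tails = tails,
    probe_ids = probe_ids,
    seed_ids = seed_ids,
    n_probes = P,
    n_tail = n_tail,
    tail_fraction = tail_fraction,
    centered = center,
    pooled = pooled,
    excluded = flat
  ), class = "cosreg_simtab")
}

#' @export
print.cosreg_simtab <- function(x, ...) {
  cat(sprintf(
    "<cosreg_simtab> %s: %d probes x %d seeds; %d per tail (%s, %s)\n",
    x$comparison, x$n_probes, length(x$seed_ids), x$n_tail,
    if (x$centered) "centered" else "uncentered",
    if (x$pooled) "pooled tails" else "per-seed tails"))
  invisible(x)
}

#' Tidy a similarity table
#'
#' @param x A `cosreg_simtab` object.
#' @param complete If `TRUE`, return every (seed, probe) pair with its tail
#'   call (`"none"` outside the tails); default returns tail members only.
#' @param ... Unused.
#' @return A tibble with columns `comparison`, `seed_id`, `probe_id`,
#'   `cosine`, `z`, `tail`.
#' @export
tidy.cosreg_simtab <- function(x, complete = FALSE, ...) {
  if (!complete) return(x$tails)
  full <- tibble(
    comparison = x$comparison,
    seed_id = rep(x$seed_ids, each = x$n_probes),
    probe_id = rep(x$probe_ids, times = length(x$seed_ids)),
    cosine = as.vector(x$cosine)
  ) %>%
    filter(.data$seed_id != .data$probe_id) %>%
    mutate(z = fisher_z(.data$cosine)) %>%
    left_join(x$tails %>% select("seed_id", "probe_id", "tail"),
              by = c("seed_id", "probe_id")) %>%
    mutate(tail = dplyr::coalesce(.data$tail, "none"))
  full
}

#' @export
glance.cosreg_simtab <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    n_probes = x$n_probes,
    n_seeds = length(x$seed_ids),
    n_tail_per_seed = x$n_tail,
    tail_fraction = x$tail_fraction,
    centered = x$centered,
    pooled = x$pooled
  )
}

#' Histogram of pooled cosine values in 16 even bins
#'
#' Pools every (seed, probe) cosine of the seed group (self-comparisons
#' excluded) into 16 bins of width 0.125 spanning -1 to 1. Bins are
#' half-open `[edge_k, edge_{k+1})` with the last bin closed at 1, and the
#' counts sum to the number of pairs tallied.
#'
#' @param simtab A `cosreg_simtab` object.
#' @return A `cosreg_hist` tibble with `bin_left`, `bin_right`, `count`.
#' @export
cosine_histogram <- function(simtab) {
  if (!inherits(simtab, "cosreg_simtab")) {
    abort("`simtab` must be a cosreg_simtab.")
  }
  edges <- seq(-1, 1, by = 0.125)
  self <- match(simtab$seed_ids, simtab$probe_ids) +
    (seq_along(simtab$seed_ids) - 1) * simtab$n_probes
  pooled <- as.vector(simtab$cosine)[-self]
  idx <- findInterval(pooled, edges, rightmost.closed = TRUE)
  out <- tibble(
    comparison = simtab$comparison,
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    count = tabulate(idx, nbins = 16)
  )
  class(out) <- c("cosreg_hist", class(out))
  out
}
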