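# Hypergeometric gene-set enrichment and cross-comparison pathway ranking.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K` are
#' annotated:
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' Evaluated through the log-space hypergeometric CDF for numerical
#' stability.
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n Query (draw) size.
#' @param k Observed overlap.
#' @return The upper-tail probability in (0, 1]; `k = 0` gives 1.
#' @export
#' @examples
#' hypergeom_upper(10, 4, 5, 3)  # 66/252
hypergeom_upper <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    abort("N, K, n, k must be non-negative integers.")
  }
  if (K > N || n > N) abort("need K <= N and n <= N.")
  if (k > min(K, n)) {
    abort(sprintf("impossible configuration: k = %d exceeds min(K, n) = %d.",
                  k, min(K, n)))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a query gene list
#'
#' Tests each gene set for over-representation in the query list with the
#' upper-tail hypergeometric test, then applies Benjamini-Hochberg adjustment
#' across all sets. When the collection enumerates its universe, query genes
#' outside it are dropped (with a message) and set sizes are taken within the
#' universe; otherwise the declared `universe_size` is used as N and sets are
#' taken at face value.
#'
#' @param query Character vector of gene/probe identifiers.
#' @param sets A `cosreg_gene_sets` collection.
#' @param alpha Significance level used for the `significant` flag.
#'   Default 0.05.
#' @param comparison Optional comparison label carried into the result.
#' @return Tibble sorted by ascending p-value with columns `comparison`,
#'   `set`, `N`, `K`, `n`, `k`, `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query, sets, alpha = 0.05, comparison = NA_character_) {
  if (!inherits(sets, "cosreg_gene_sets")) {
    abort("`sets` must be a cosreg_gene_sets collection.")
  }
  query <- unique(as.character(query))
  if (length(query) == 0) abort("`query` must contain at least one gene.")
  members <- sets$sets
  N <- sets$universe_size
  if (!is.null(sets$universe)) {
    dropped <- sum(!query %in% sets$universe)
    if (dropped > 0) {
      inform(sprintf("%d query gene(s) outside the universe dropped.", dropped))
    }
    query <- intersect(query, sets$universe)
    if (length(query) == 0) abort("no query genes remain inside the universe.")
    members <- lapply(members, intersect, sets$universe)
  }
  n <- length(query)
  out <- purrr::imap_dfr(members, function(m, name) {
    K <- length(m)
    k <- length(intersect(query, m))
    tibble(set = name, N = N, K = K, n = n, k = k,
           p_value = hypergeom_upper(N, K, n, k))
  })
  out %>%
    mutate(
      comparison = comparison,
      q_value = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < alpha
    ) %>%
    select("comparison", "set", "N", "K", "n", "k", "p_value", "q_value",
           "significant") %>%
    arrange(.data$p_value, .data$set)
}

#' Rank pathways by the number of significant comparisons
#'
#' Combines per-comparison enrichment results and ranks each gene set first
#' by how many comparisons reach `p < alpha` (descending) and then by its
#' minimum p-value across comparisons (ascending).
#'
#' @param results A tibble of [enrich()] results with a `comparison` column,
#'   or a list of such tibbles.
#' @param alpha Significance level. Default 0.05.
#' @return Tibble with `set`, `n_significant_comparisons`, `min_p`, one
#'   `p_<comparison>` column per comparison, ordered by rank.
#' @export
rank_pathways <- function(results, alpha = 0.05) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- bind_rows(results)
  }
  needed <- c("comparison", "set", "p_value")
  missing <- setdiff(needed, names(results))
  if (length(missing) > 0) {
    abort(paste0("results are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n_cmp <- length(unique(results$comparison))
  if (n_cmp < 1 || n_cmp > 4) {
    abort("expected enrichment results for 1-4 comparisons.")
  }
  wide <- results %>%
    select("comparison", "set", "p_value") %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "p_value",
                       names_prefix = "p_")
  results %>%
    group_by(.data$set) %>%
    summarise(
      n_significant_comparisons = sum(.data$p_value < alpha, na.rm = TRUE),
      min_p = min(.data$p_value, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(wide, by = "set") %>%
    arrange(desc(.data$n_significant_comparisons), .data$min_p, .data$set)
}
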