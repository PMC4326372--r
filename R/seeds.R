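# Differential "seed" selection between matched feather/scale groups.

#' The four canonical feather-vs-scale comparisons
#'
#' Feather- and scale-forming skins of matched developmental plasticity,
#' paired within compartment: day-7 feather vs day-9 scale and day-9 feather
#' vs day-11 scale, each for epithelium and mesenchyme.
#'
#' @return A tibble with columns `comparison`, `group_a`, `group_b`.
#' @export
#' @examples
#' comparisons()
comparisons <- function() {
  tibble(
    group_a = c("E7fe", "E7fm", "E9fe", "E9fm"),
    group_b = c("E9se", "E9sm", "E11se", "E11sm")
  ) %>%
    mutate(comparison = paste0(.data$group_a, "_vs_", .data$group_b)) %>%
    select("comparison", "group_a", "group_b")
}

#' Select differentially expressed seed probes
#'
#' A probe is a seed for a comparison when the absolute difference of its
#' log2 group means exceeds `log2(fold_threshold)` — strictly greater than,
#' so a probe sitting exactly at the threshold is not a seed. Both directions
#' are kept and recorded.
#'
#' @param means A `cosreg_means` tibble from [group_means()].
#' @param comparison_set Tibble of comparisons (`comparison`, `group_a`,
#'   `group_b`); defaults to the four canonical comparisons.
#' @param fold_threshold Linear-scale fold-change threshold, > 1. Default 5.
#' @return Tibble with columns `comparison`, `probe_id`, `log2_diff`
#'   (mean_a - mean_b) and `direction` (`"up_in_a"`/`"up_in_b"`), ordered by
#'   comparison then probe id.
#' @export
select_seeds <- function(means, comparison_set = comparisons(),
                         fold_threshold = 5) {
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1 ||
      fold_threshold <= 1) {
    abort("`fold_threshold` must be a single number > 1.")
  }
  missing <- setdiff(unique(c(comparison_set$group_a, comparison_set$group_b)),
                     names(means))
  if (length(missing) > 0) {
    abort(paste0("group(s) absent from means: ",
                 paste(missing, collapse = ", ")))
  }
  cut <- log2(fold_threshold)
  purrr::pmap_dfr(comparison_set, function(comparison, group_a, group_b) {
    delta <- means[[group_a]] - means[[group_b]]
    keep <- abs(delta) > cut
    tibble(
      comparison = comparison,
      probe_id = means$probe_id[keep],
      log2_diff = delta[keep],
      direction = ifelse(delta[keep] > 0, "up_in_a", "up_in_b")
    )
  }) %>%
    arrange(.data$comparison, .data$probe_id)
}
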