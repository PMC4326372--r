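# Diagnostic plots.

#' Plot a pooled cosine-value histogram
#'
#' Bars over the 16 even bins from -1 to 1 (0.125 intervals); an
#' approximately bell-shaped distribution centered near 0 is what the screen
#' expects on mean-centered data.
#'
#' @param object A `cosreg_hist` tibble from [cosine_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosreg_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2, y = .data$count)) +
    ggplot2::geom_col(width = 0.115, fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(-1, 1, 0.25)) +
    ggplot2::labs(x = "cosine similarity to seed", y = "probe pairs",
                  title = unique(object$comparison)) +
    ggplot2::theme_minimal()
}

#' Plot the seed-support distribution
#'
#' Number of probes supported by exactly k seeds, per comparison, on a log10
#' count scale; planted co-regulated structure shows up as a heavy tail at
#' large k.
#'
#' @param object A `cosreg_support` tibble from [support_distribution()].
#' @param min_seed_support Optional threshold to mark with a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosreg_support <- function(object, min_seed_support = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n_seeds, y = .data$n_probes)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "supporting seeds (k)", y = "probes (log10)") +
    ggplot2::theme_minimal()
  if (!is.null(min_seed_support)) {
    p <- p + ggplot2::geom_vline(xintercept = min_seed_support - 0.5,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot per-comparison screen counts
#'
#' Side-by-side bars of seed, co-regulated and supported-candidate counts
#' per comparison — the three-column summary the screen reports.
#'
#' @param object A `cosreg_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosreg_screen <- function(object, ...) {
  long <- object$summary %>%
    tidyr::pivot_longer(c("n_seeds", "n_coregulated", "n_candidates"),
                        names_to = "stage", values_to = "count") %>%
    mutate(stage = factor(.data$stage,
                          levels = c("n_seeds", "n_coregulated",
                                     "n_candidates"),
                          labels = c("seeds", "co-regulated",
                                     "candidates (supported)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$count,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "probes (log10)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
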