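# End-to-end orchestration: normalize -> seeds -> cosine -> candidates ->
# clusters -> enrichment, in memory (run_screen) or file-to-file with a
# manifest (run_pipeline).

#' Run the full co-regulation screen in memory
#'
#' Quantile-normalizes the matrix (optional), computes group means, selects
#' >`fold_threshold`-fold seeds for every comparison, scores probe-by-seed
#' cosine tails, shortlists probes supported by at least `min_seed_support`
#' seeds, clusters seeds with their correlated candidates, and — when gene
#' sets are supplied — runs hypergeometric enrichment of each comparison's
#' combined seed + candidate list with cross-comparison pathway ranking.
#'
#' @param x A `cosreg_expr` object.
#' @param gene_sets Optional `cosreg_gene_sets` collection for enrichment.
#' @param probe_map Optional two-column data frame (`probe_id`, `gene_id`)
#'   mapping probes to gene identifiers before enrichment; identity when
#'   `NULL`.
#' @param fold_threshold Seed fold-change threshold (> 1). Default 5.
#' @param tail_fraction Per-tail fraction for similarity calling.
#'   Default 0.005.
#' @param min_seed_support Inclusive seed-support threshold. Default 10.
#' @param alpha Enrichment significance level. Default 0.05.
#' @param center Mean-center probe vectors before cosine. Default `TRUE`.
#' @param pooled_tails Pool the tail distribution across a comparison's
#'   seeds instead of calling per seed. Default `FALSE`.
#' @param normalize Quantile-normalize before the screen. Default `TRUE`.
#' @param comparison_set Comparisons to run; defaults to [comparisons()].
#' @return A `cosreg_screen` object; see [tidy.cosreg_screen()].
#' @export
run_screen <- function(x, gene_sets = NULL, probe_map = NULL,
                       fold_threshold = 5, tail_fraction = 0.005,
                       min_seed_support = 10, alpha = 0.05, center = TRUE,
                       pooled_tails = FALSE, normalize = TRUE,
                       comparison_set = comparisons()) {
  if (!inherits(x, "cosreg_expr")) abort("`x` must be a cosreg_expr.")
  if (normalize) x <- quantile_normalize(x)
  means <- group_means(x)
  seeds <- select_seeds(means, comparison_set, fold_threshold)

  simtabs <- list()
  for (cmp in comparison_set$comparison) {
    seeds_cmp <- seeds %>% filter(.data$comparison == cmp)
    if (nrow(seeds_cmp) == 0) next
    simtabs[[cmp]] <- similarity_table(x, seeds_cmp,
                                       tail_fraction = tail_fraction,
                                       center = center, pooled = pooled_tails)
  }
  tails <- if (length(simtabs) > 0) purrr::map_dfr(simtabs, "tails") else
    tibble(comparison = character(), seed_id = character(),
           probe_id = character(), cosine = numeric(), z = numeric(),
           tail = character())
  candidates <- build_candidates(tails, min_seed_support = min_seed_support)
  clusters <- build_clusters(tails, candidates)
  support <- support_distribution(tails)

  summary <- comparison_set %>%
    select("comparison") %>%
    left_join(seeds %>% count(.data$comparison, name = "n_seeds"),
              by = "comparison") %>%
    left_join(tails %>% distinct(.data$comparison, .data$probe_id) %>%
                count(.data$comparison, name = "n_coregulated"),
              by = "comparison") %>%
    left_join(candidates %>% count(.data$comparison, name = "n_candidates"),
              by = "comparison") %>%
    mutate(across(c("n_seeds", "n_coregulated", "n_candidates"),
                  ~ dplyr::coalesce(.x, 0L)))

  enrichment <- NULL
  ranking <- NULL
  if (!is.null(gene_sets)) {
    map_probe <- function(ids) {
      if (is.null(probe_map)) return(ids)
      mapped <- probe_map$gene_id[match(ids, probe_map$probe_id)]
      unique(mapped[!is.na(mapped)])
    }
    enr <- list()
    for (cmp in names(simtabs)) {
      query <- map_probe(unique(c(
        seeds$probe_id[seeds$comparison == cmp],
        candidates$probe_id[candidates$comparison == cmp]
      )))
      if (length(query) == 0) next
      enr[[cmp]] <- enrich(query, gene_sets, alpha = alpha, comparison = cmp)
    }
    if (length(enr) > 0) {
      enrichment <- bind_rows(enr)
      ranking <- rank_pathways(enrichment, alpha = alpha)
    }
  }

  structure(list(
    normalized = x,
    means = means,
    seeds = seeds,
    simtabs = simtabs,
    candidates = candidates,
    clusters = clusters,
    support = support,
    summary = summary,
    enrichment = enrichment,
    ranking = ranking,
    params = list(fold_threshold = fold_threshold,
                  tail_fraction = tail_fraction,
                  min_seed_support = min_seed_support, alpha = alpha,
                  center = center, pooled_tails = pooled_tails,
                  normalize = normalize)
  ), class = "cosreg_screen")
}

#' @export
print.cosreg_screen <- function(x, ...) {
  cat("<cosreg_screen>\n")
  cat(sprintf("  fold > %g, tail %.3f%% per side, support >= %d, %s\n",
              x$params$fold_threshold, 100 * x$params$tail_fraction,
              x$params$min_seed_support,
              if (x$params$center) "centered" else "uncentered"))
  print(x$summary)
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `cosreg_screen` object.
#' @param what One of `"summary"` (per-comparison seed / co-regulated /
#'   candidate counts, the default), `"seeds"`, `"tails"`, `"candidates"`,
#'   `"clusters"`, `"support"`, `"enrichment"`, `"ranking"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cosreg_screen <- function(x, what = c("summary", "seeds", "tails",
                                           "candidates", "clusters",
                                           "support", "enrichment",
                                           "ranking"), ...) {
  what <- match.arg(what)
  out <- switch(what,
    summary = x$summary,
    seeds = x$seeds,
    tails = purrr::map_dfr(x$simtabs, "tails"),
    candidates = x$candidates,
    clusters = x$clusters,
    support = x$support,
    enrichment = x$enrichment %||%
      tibble(comparison = character(), set = character()),
    ranking = x$ranking %||% tibble(set = character())
  )
  as_tibble(out)
}

#' One-row overview of a screen
#'
#' @param x A `cosreg_screen` object.
#' @param ... Unused.
#' @return A one-row tibble of totals and thresholds.
#' @export
glance.cosreg_screen <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x$summary),
    total_seeds = sum(x$summary$n_seeds),
    total_coregulated = sum(x$summary$n_coregulated),
    total_candidates = sum(x$summary$n_candidates),
    fold_threshold = x$params$fold_threshold,
    tail_fraction = x$params$tail_fraction,
    min_seed_support = x$params$min_seed_support,
    centered = x$params$center
  )
}

default_pipeline_config <- function() {
  list(input_scale = "log2", fold_threshold = 5, tail_fraction = 0.005,
       min_seed_support = 10, alpha = 0.05, center = TRUE,
       pooled_tails = FALSE, normalize = TRUE, universe_size = NULL)
}

#' Run the screen file-to-file with a manifest
#'
#' Reads the expression matrix (plain TSV or GEO series-matrix dialect) and
#' design, runs [run_screen()], and writes every stage output as
#' deterministic TSV into `out_dir` together with a `manifest.tsv` recording
#' every threshold used and every file written. Identical config and inputs
#' produce byte-identical outputs. `config` is a list or the path to a YAML
#' file with keys: `matrix` (or `series_matrix`), `design`, optional `gmt` +
#' `universe_size`, optional `probe_map`, `out_dir`, plus any of
#' `input_scale`, `fold_threshold`, `tail_fraction`, `min_seed_support`,
#' `alpha`, `center`, `pooled_tails`, `normalize`. Arguments in `...`
#' override config keys.
#'
#' @param config List or YAML file path.
#' @param ... Named overrides of config keys.
#' @return Invisibly, a list with the `cosreg_screen`, the manifest tibble
#'   and the output paths. Any stage failure aborts, naming the stage.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  config <- utils::modifyList(default_pipeline_config(), config)
  config <- utils::modifyList(config, list(...))
  if (is.null(config$out_dir)) abort("config must name an `out_dir`.")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  inform(sprintf(
    "cosreg pipeline: fold_threshold=%g tail_fraction=%g min_seed_support=%d alpha=%g center=%s pooled_tails=%s normalize=%s",
    config$fold_threshold, config$tail_fraction, config$min_seed_support,
    config$alpha, config$center, config$pooled_tails, config$normalize))

  x <- stage("read_input", {
    if (!is.null(config$series_matrix)) {
      read_series_matrix(config$series_matrix, config$design,
                         input_scale = config$input_scale)
    } else if (!is.null(config$matrix)) {
      read_expression_tsv(config$matrix, config$design,
                          input_scale = config$input_scale)
    } else {
      abort("config must name a `matrix` or `series_matrix` input.")
    }
  })
  sets <- NULL
  if (!is.null(config$gmt)) {
    sets <- stage("read_gene_sets", {
      read_gmt(config$gmt,
               universe_size = config$universe_size %||% nrow(x$values))
    })
  }
  pmap <- NULL
  if (!is.null(config$probe_map)) {
    pmap <- stage("read_probe_map", {
      readr::read_tsv(config$probe_map, show_col_types = FALSE)
    })
  }
  screen <- stage("screen", {
    run_screen(x, gene_sets = sets, probe_map = pmap,
               fold_threshold = config$fold_threshold,
               tail_fraction = config$tail_fraction,
               min_seed_support = config$min_seed_support,
               alpha = config$alpha, center = config$center,
               pooled_tails = config$pooled_tails,
               normalize = config$normalize)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  write_stage <- function(name, tbl) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    stage(paste0("write_", name), write_result_tsv(tbl, p))
    paths[[name]] <<- p
    inform(sprintf("wrote %s (%d rows)", p, nrow(tbl)))
  }
  write_stage("summary", screen$summary)
  write_stage("seeds", screen$seeds)
  write_stage("similarity_tails", tidy(screen, "tails"))
  write_stage("candidates", screen$candidates)
  write_stage("clusters", screen$clusters)
  write_stage("support_distribution", screen$support)
  if (!is.null(screen$enrichment)) {
    write_stage("enrichment", screen$enrichment)
    write_stage("pathway_ranking", screen$ranking)
  }

  manifest <- bind_rows(
    tibble(key = paste0("param.", names(unlist(screen$params))),
           value = as.character(unlist(screen$params))),
    tibble(key = paste0("output.", names(paths)),
           value = as.character(unlist(paths))),
    tibble(key = paste0("count.", screen$summary$comparison, ".seeds"),
           value = as.character(screen$summary$n_seeds)),
    tibble(key = paste0("count.", screen$summary$comparison, ".candidates"),
           value = as.character(screen$summary$n_candidates))
  )
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write_result_tsv(manifest, manifest_path)
  invisible(list(screen = screen, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}
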