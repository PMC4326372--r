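# Synthetic expression with planted co-regulated modules and planted
# differential seeds under the canonical 20-array design.

#' The canonical 20-array sample design
#'
#' Eight (day, region, compartment) groups with two epithelial and three
#' mesenchymal replicates each: E7fe(2), E7fm(3), E9fe(2), E9fm(3), E9se(2),
#' E9sm(3), E11se(2), E11sm(3) — twenty samples in total.
#'
#' @return A design tibble (see [read_design_tsv()] for the columns).
#' @export
#' @examples
#' canonical_design()
canonical_design <- function() {
  spec <- tibble(
    day = c("E7", "E7", "E9", "E9", "E9", "E9", "E11", "E11"),
    region = c("feather", "feather", "feather", "feather",
               "scale", "scale", "scale", "scale"),
    compartment = rep(c("epithelium", "mesenchyme"), 4),
    n_rep = rep(c(2L, 3L), 4)
  )
  design <- spec %>%
    mutate(row = dplyr::row_number()) %>%
    tidyr::uncount(.data$n_rep, .id = "replicate") %>%
    mutate(
      group = group_label(.data$day, .data$region, .data$compartment),
      sample_id = paste0(.data$group, "_", .data$replicate),
      replicate = as.integer(.data$replicate)
    ) %>%
    select("sample_id", "day", "region", "compartment", "replicate", "group")
  validate_design(design)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions the screen targets: a 20,000-probe
#' array, five planted modules of 50 genes, thirty planted >5-fold seeds per
#' comparison at 8-fold, log2 baselines around 7 +/- 1.5 and per-sample noise
#' of 0.25 log2 units.
#'
#' @param n_probes Total probes. Default 20000.
#' @param n_modules Number of planted co-regulated modules. Default 5.
#' @param module_size Core members per module. Default 50.
#' @param n_seed_probes_per_comparison Planted differential seeds per
#'   comparison. Default 30.
#' @param seed_fold Linear-scale fold of the planted differential offset,
#'   must exceed 5. Default 8.
#' @param baseline_mean,baseline_sd Log2 baseline distribution. Defaults 7
#'   and 1.5.
#' @param noise_sd Per-sample log2 noise. Default 0.25.
#' @param module_loading_sd Spread of per-gene module loadings around 1.
#'   Default 0.15.
#' @param rng_seed Integer seed; the simulation is bit-reproducible given it.
#' @return A `cosreg_sim_config` list.
#' @export
sim_config <- function(n_probes = 20000, n_modules = 5, module_size = 50,
                       n_seed_probes_per_comparison = 30, seed_fold = 8,
                       baseline_mean = 7, baseline_sd = 1.5, noise_sd = 0.25,
                       module_loading_sd = 0.15, rng_seed = 1) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    n_seed_probes_per_comparison = as.integer(n_seed_probes_per_comparison),
    seed_fold = seed_fold,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    module_loading_sd = module_loading_sd,
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_probes < 1 || cfg$module_size < 1 ||
      cfg$n_seed_probes_per_comparison < 1 || cfg$n_modules < 0) {
    abort("simulation sizes must be positive (n_modules may be 0).")
  }
  if (cfg$seed_fold <= 5) abort("`seed_fold` must exceed 5.")
  if (cfg$baseline_sd <= 0 || cfg$noise_sd <= 0 || cfg$module_loading_sd <= 0) {
    abort("scale parameters must be positive.")
  }
  n_seed_total <- if (cfg$n_modules == 0) 0L else 4L * cfg$n_seed_probes_per_comparison
  if (cfg$n_modules * cfg$module_size + n_seed_total > cfg$n_probes) {
    abort("planted structure exceeds n_probes: need n_modules * module_size + 4 * n_seed_probes_per_comparison <= n_probes.")
  }
  structure(cfg, class = "cosreg_sim_config")
}

# Modules are planted as reciprocally regulated pairs: modules 2j-1 and 2j
# share latent axis j with opposite sign, so the screen's co AND reciprocal
# tails both land on planted structure. An odd last module joins the
# previous pair's negative side. Each trajectory is marginally N(0,1) per
# group.
module_layout <- function(n_modules) {
  if (n_modules == 0) {
    return(tibble(module = integer(), axis = integer(), sign = numeric()))
  }
  axis <- ceiling(seq_len(n_modules) / 2)
  sign <- ifelse(seq_len(n_modules) %% 2 == 1, 1, -1)
  if (n_modules > 2 && n_modules %% 2 == 1) {
    axis[n_modules] <- axis[n_modules - 1]
    sign[n_modules] <- -1
  }
  tibble(module = seq_len(n_modules), axis = axis, sign = sign)
}

# Planted seeds are allocated greedily, one at a time, to the module whose
# axis side currently has the smallest family (core members + seeds so far);
# within a side, to the module with the fewest seeds. Balanced sides keep
# every side's family within the screen's per-seed tail capacity, so the
# planted structure is recoverable by design. Deterministic (no RNG).
seed_allocation <- function(n_modules, n_seed, module_size,
                            n_comparisons = 4L) {
  if (n_modules == 0) return(rep(list(integer()), n_comparisons))
  layout <- module_layout(n_modules)
  side_of <- paste0(layout$axis, ifelse(layout$sign > 0, "+", "-"))
  side_size <- tapply(rep(module_size, n_modules), side_of, sum)
  seeds_of_module <- integer(n_modules)
  lapply(seq_len(n_comparisons), function(c) {
    picked <- integer(n_seed)
    for (i in seq_len(n_seed)) {
      side <- names(side_size)[which.min(side_size)]
      in_side <- which(side_of == side)
      m <- in_side[which.min(seeds_of_module[in_side])]
      picked[[i]] <- m
      side_size[[side]] <<- side_size[[side]] + 1L
      seeds_of_module[[m]] <<- seeds_of_module[[m]] + 1L
    }
    sort(picked)
  })
}

#' Simulate an expression matrix with planted structure
#'
#' Background probe values are `b_g + eps` with `b_g ~ N(baseline_mean,
#' baseline_sd^2)` per probe and `eps ~ N(0, noise_sd^2)` per cell. Each
#' module m draws a latent trajectory `t_m(group) ~ N(0, 1)` once per
#' (day, region, compartment) group — replicates of a group share it — and a
#' member adds `lambda_g * t_m(group)` with loading
#' `lambda_g ~ N(1, module_loading_sd^2)`. Modules are planted as
#' reciprocally regulated pairs — consecutive modules share a latent axis
#' with opposite sign (each trajectory still marginally N(0, 1) per group) —
#' because the screen's reciprocal tails are as much a part of the method as
#' its co-regulated tails. Planted seeds are additional
#' probes carrying their module's trajectory plus `log2(seed_fold)` on one
#' side of their assigned comparison; the boosted side is the comparison
#' group where the module trajectory is higher, so the planted differential
#' is concordant with the module's own regulation and never cancels against
#' it. With `n_modules = 0` the matrix is pure noise and nothing is planted.
#'
#' @param config A [sim_config()] list.
#' @return A list with elements `expr` (a `cosreg_expr`) and `truth`, the
#'   ground truth: `module_members` (list of core member ids per module),
#'   `planted_seeds` (list of seed ids per comparison), `module_of_seed`
#'   (named character), `seed_info` (tibble with side group, direction,
#'   loading and trajectory difference per seed), `trajectories`
#'   (module x group matrix) and `loadings` (named numeric).
#' @export
simulate_expression <- function(config = sim_config()) {
  if (!inherits(config, "cosreg_sim_config")) {
    abort("`config` must come from sim_config().")
  }
  set.seed(config$rng_seed)
  design <- canonical_design()
  n_s <- nrow(design)
  groups <- unique(design$group)
  gidx <- match(design$group, groups)
  comps <- comparisons()
  P <- config$n_probes
  width <- max(5, nchar(as.character(P)))
  probe_ids <- sprintf("P%0*d", width, seq_len(P))

  alloc <- seed_allocation(config$n_modules,
                           config$n_seed_probes_per_comparison,
                           config$module_size, nrow(comps))
  n_mem <- config$n_modules * config$module_size
  n_seed_total <- sum(lengths(alloc))

  perm <- sample.int(P)
  member_idx <- if (n_mem > 0) perm[seq_len(n_mem)] else integer()
  seed_idx <- if (n_seed_total > 0) perm[n_mem + seq_len(n_seed_total)] else integer()

  b <- rnorm(P, config$baseline_mean, config$baseline_sd)
  V <- matrix(rnorm(P * n_s, 0, config$noise_sd), P, n_s) + b
  dimnames(V) <- list(probe_ids, design$sample_id)

  layout <- module_layout(config$n_modules)
  Tm <- if (config$n_modules > 0) {
    axes <- matrix(rnorm(max(layout$axis) * length(groups)),
                   max(layout$axis), length(groups),
                   dimnames = list(NULL, groups))
    layout$sign * axes[layout$axis, , drop = FALSE]
  } else {
    matrix(0, 0, length(groups), dimnames = list(NULL, groups))
  }

  module_members <- list()
  loadings <- numeric(0)
  for (m in seq_len(config$n_modules)) {
    rows <- member_idx[(m - 1) * config$module_size + seq_len(config$module_size)]
    lam <- rnorm(config$module_size, 1, config$module_loading_sd)
    V[rows, ] <- V[rows, ] + lam %o% Tm[m, gidx]
    module_members[[paste0("M", m)]] <- sort(probe_ids[rows])
    loadings[probe_ids[rows]] <- lam
  }

  offset <- log2(config$seed_fold)
  planted_seeds <- setNames(rep(list(character()), nrow(comps)),
                            comps$comparison)
  module_of_seed <- character(0)
  seed_info <- list()
  used <- 0L
  for (c in seq_len(nrow(comps))) {
    mods <- alloc[[c]]
    if (length(mods) == 0) next
    rows <- seed_idx[used + seq_along(mods)]
    used <- used + length(mods)
    lam <- rnorm(length(mods), 1, config$module_loading_sd)
    ga <- comps$group_a[[c]]
    gb <- comps$group_b[[c]]
    for (i in seq_along(mods)) {
      m <- mods[[i]]
      V[rows[[i]], ] <- V[rows[[i]], ] + lam[[i]] * Tm[m, gidx]
      side <- if (Tm[m, ga] >= Tm[m, gb]) ga else gb
      cols <- which(design$group == side)
      V[rows[[i]], cols] <- V[rows[[i]], cols] + offset
      seed_info[[length(seed_info) + 1L]] <- tibble(
        probe_id = probe_ids[rows[[i]]],
        comparison = comps$comparison[[c]],
        module = paste0("M", m),
        side_group = side,
        direction = if (side == ga) "up_in_a" else "up_in_b",
        loading = lam[[i]],
        trajectory_diff = Tm[m, ga] - Tm[m, gb]
      )
    }
    ids <- probe_ids[rows]
    planted_seeds[[comps$comparison[[c]]]] <- sort(ids)
    module_of_seed[ids] <- paste0("M", mods)
    loadings[ids] <- lam
  }
  seed_info <- if (length(seed_info) > 0) bind_rows(seed_info) else
    tibble(probe_id = character(), comparison = character(),
           module = character(), side_group = character(),
           direction = character(), loading = numeric(),
           trajectory_diff = numeric())

  list(
    expr = expr_set(V, design),
    truth = list(
      module_members = module_members,
      planted_seeds = planted_seeds,
      module_of_seed = module_of_seed,
      seed_info = seed_info,
      module_layout = layout,
      trajectories = Tm,
      loadings = loadings,
      config = config
    )
  )
}

#' Score candidate recovery against the planted ground truth
#'
#' Recall of module m is the fraction of its core members appearing among
#' the candidates (any comparison); precision is the fraction of candidate
#' probes that belong to any planted module or seed set. An empty candidate
#' list has recall 0 and, by convention, precision 1 with
#' `empty_candidates = TRUE`.
#'
#' @param candidates Candidate tibble from [build_candidates()] (possibly
#'   covering several comparisons).
#' @param truth Ground-truth list from [simulate_expression()].
#' @return A list with `module_recall` (tibble: module, n_members,
#'   n_recovered, recall), `mean_recall`, `precision`, `n_candidates` and
#'   `empty_candidates`.
#' @export
score_recovery <- function(candidates, truth) {
  cand <- unique(candidates$probe_id)
  planted <- unique(c(unlist(truth$module_members, use.names = FALSE),
                      unlist(truth$planted_seeds, use.names = FALSE)))
  module_recall <- purrr::imap_dfr(truth$module_members, function(members, m) {
    tibble(
      module = m,
      n_members = length(members),
      n_recovered = sum(members %in% cand),
      recall = mean(members %in% cand)
    )
  })
  empty <- length(cand) == 0
  list(
    module_recall = module_recall,
    mean_recall = if (nrow(module_recall) > 0) mean(module_recall$recall) else NA_real_,
    precision = if (empty) 1 else mean(cand %in% planted),
    n_candidates = length(cand),
    empty_candidates = empty
  )
}
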