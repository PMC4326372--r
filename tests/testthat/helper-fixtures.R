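# Shared fixtures: small designs, toy expression sets, crafted tail tables
# and the exhaustive hypergeometric enumeration oracle. Everything is built
# in code at test time.

# A minimal valid design with n samples drawn from distinct canonical groups.
make_design <- function(n = 4) {
  full <- canonical_design()
  groups <- unique(full$group)[seq_len(n)]
  full[match(groups, full$group), ]
}

# Toy expression set: probes x samples matrix over a valid design.
make_expr <- function(values, design = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  }
  if (is.null(design)) design <- make_design(ncol(values))
  colnames(values) <- design$sample_id
  expr_set(values, design)
}

# Random expression set over the full canonical design.
random_expr <- function(n_probes, seed = 42) {
  set.seed(seed)
  design <- canonical_design()
  values <- matrix(rnorm(n_probes * nrow(design), 7, 1),
                   n_probes, nrow(design))
  rownames(values) <- sprintf("p%04d", seq_len(n_probes))
  expr_set(values, design)
}

# Seed tibble pointing at arbitrary probes of an expression set.
fake_seeds <- function(x, n = 5, comparison = "E7fe_vs_E9se") {
  ids <- rownames(x$values)[seq_len(n)]
  tibble::tibble(comparison = comparison, probe_id = ids,
                 log2_diff = 3, direction = "up_in_a")
}

# Hand-built tail table for the candidate/cluster stage.
make_tails <- function(df) {
  df$comparison <- df$comparison %||% "E7fe_vs_E9se"
  df$cosine <- df$cosine %||% ifelse(df$tail == "co", 0.9, -0.9)
  df$z <- atanh(df$cosine)
  tibble::as_tibble(df[c("comparison", "seed_id", "probe_id", "cosine", "z",
                         "tail")])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Small planted-structure configuration: fast, with axis-side families that
# fit inside the per-seed tails (12000 probes -> 60-slot tails; sides of 56)
# and per-comparison, per-side support (12) above the default filter (10),
# so recovery does not depend on how the latent trajectory happens to fall.
small_sim_config <- function(rng_seed = 1, ...) {
  sim_config(n_probes = 12000, n_modules = 2, module_size = 8,
             n_seed_probes_per_comparison = 24, rng_seed = rng_seed, ...)
}

# Exhaustive enumeration oracle for the upper-tail hypergeometric
# probability: counts, over all C(N, n) draws, those with >= k marked
# elements (marked = 1..K). Exact by integer counting.
hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  sum(overlap >= k) / ncol(draws)
}

# Independent Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q)[order(o)]
}
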