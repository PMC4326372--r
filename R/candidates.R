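# Shared-seed support filtering and signed seed clustering.

tails_of <- function(x) {
  if (inherits(x, "cosreg_simtab")) return(x$tails)
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "cosreg_simtab"))) {
    return(purrr::map_dfr(x, "tails"))
  }
  if (is.data.frame(x)) {
    needed <- c("comparison", "seed_id", "probe_id", "tail")
    missing <- setdiff(needed, names(x))
    if (length(missing) > 0) {
      abort(paste0("tail table is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    return(as_tibble(x))
  }
  abort("expected a cosreg_simtab, a list of them, or a tail tibble.")
}

#' Shortlist probes supported by many seeds
#'
#' Counts, per comparison, the distinct seeds in whose co- or reciprocal
#' tail each probe falls, and retains probes supported by at least
#' `min_seed_support` seeds. Polarity is `"co_dominant"` when co support
#' exceeds reciprocal support, `"recip_dominant"` when it is smaller, and
#' `"mixed"` on a tie.
#'
#' @param x A `cosreg_simtab`, a list of them, or a tail tibble.
#' @param min_seed_support Inclusive support threshold, a positive integer.
#'   Default 10 (i.e. probes correlated with >= 10 seeds are retained).
#' @return Tibble with columns `comparison`, `probe_id`, `n_co_seeds`,
#'   `n_recip_seeds`, `support`, `polarity`, ordered by comparison,
#'   descending support, probe id.
#' @export
build_candidates <- function(x, min_seed_support = 10) {
  if (!is.numeric(min_seed_support) || length(min_seed_support) != 1 ||
      min_seed_support < 1 || min_seed_support != round(min_seed_support)) {
    abort("`min_seed_support` must be a positive integer.")
  }
  tails <- tails_of(x)
  if (nrow(tails) == 0) {
    return(tibble(comparison = character(), probe_id = character(),
                  n_co_seeds = integer(), n_recip_seeds = integer(),
                  support = integer(), polarity = character()))
  }
  tails %>%
    distinct(.data$comparison, .data$seed_id, .data$probe_id, .data$tail) %>%
    group_by(.data$comparison, .data$probe_id) %>%
    summarise(
      n_co_seeds = sum(.data$tail == "co"),
      n_recip_seeds = sum(.data$tail == "reciprocal"),
      .groups = "drop"
    ) %>%
    mutate(
      support = .data$n_co_seeds + .data$n_recip_seeds,
      polarity = case_when(
        .data$n_co_seeds > .data$n_recip_seeds ~ "co_dominant",
        .data$n_co_seeds < .data$n_recip_seeds ~ "recip_dominant",
        TRUE ~ "mixed"
      )
    ) %>%
    filter(.data$support >= min_seed_support) %>%
    arrange(.data$comparison, desc(.data$support), .data$probe_id)
}

#' Distribution of probes by number of supporting seeds
#'
#' For k = 1, 2, ... counts how many probes fall in the tails of exactly k
#' distinct seeds, per comparison. The counts sum to the number of probes
#' appearing in at least one tail.
#'
#' @param x A `cosreg_simtab`, a list of them, or a tail tibble.
#' @return A `cosreg_support` tibble with columns `comparison`, `n_seeds`,
#'   `n_probes`.
#' @export
support_distribution <- function(x) {
  tails <- tails_of(x)
  out <- tails %>%
    distinct(.data$comparison, .data$seed_id, .data$probe_id) %>%
    count(.data$comparison, .data$probe_id, name = "k") %>%
    count(.data$comparison, .data$k, name = "n_probes") %>%
    rename(n_seeds = "k") %>%
    arrange(.data$comparison, .data$n_seeds)
  class(out) <- c("cosreg_support", class(out))
  out
}

# Signed connected components: propagate sign products over seed-seed edges
# from an arbitrary root; any edge contradicting the propagated signs marks
# the component as mixed rather than being resolved.
signed_components <- function(nodes, edges) {
  sign_of <- setNames(rep(NA_real_, length(nodes)), nodes)
  comp_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- split(seq_len(nrow(edges)), edges$from)
  adj2 <- split(seq_len(nrow(edges)), edges$to)
  comp <- 0L
  mixed <- logical(0)
  for (root in nodes) {
    if (!is.na(comp_of[[root]])) next
    comp <- comp + 1L
    mixed[comp] <- FALSE
    comp_of[[root]] <- comp
    sign_of[[root]] <- 1
    queue <- root
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      idx <- c(adj[[v]], adj2[[v]])
      for (e in idx) {
        other <- if (edges$from[e] == v) edges$to[e] else edges$from[e]
        want <- sign_of[[v]] * edges$sign[e]
        if (is.na(comp_of[[other]])) {
          comp_of[[other]] <- comp
          sign_of[[other]] <- want
          queue <- c(queue, other)
        } else if (sign_of[[other]] != want) {
          mixed[comp] <- TRUE
        }
      }
    }
  }
  list(component = comp_of, sign = sign_of, mixed = mixed)
}

#' Cluster seeds with their correlated candidate genes
#'
#' Each seed starts a group holding the candidate probes found in its tails.
#' Two seeds are related when either appears in the other's tail (symmetric
#' OR), with sign +1 for a co tail and -1 for a reciprocal tail; groups merge
#' transitively over this relation, so clusters are the connected components
#' of the seed-seed graph. Member signs are propagated from an arbitrary
#' reference seed; a component whose edges cannot be signed consistently is
#' reported as `"mixed"` rather than resolved. A gene may belong to several
#' clusters. Seeds with no seed-seed relation and no candidate overlap are
#' dropped.
#'
#' @param x A `cosreg_simtab`, a list of them, or a tail tibble.
#' @param candidates Candidate tibble from [build_candidates()].
#' @return Tibble with columns `comparison`, `cluster_id`, `n_seeds`,
#'   `n_genes`, `polarity` (`"coherent"`/`"mixed"`), and list-columns
#'   `seeds`, `seed_signs`, `genes`.
#' @export
build_clusters <- function(x, candidates) {
  tails <- tails_of(x)
  empty <- tibble(comparison = character(), cluster_id = character(),
                  n_seeds = integer(), n_genes = integer(),
                  polarity = character(), seeds = list(),
                  seed_signs = list(), genes = list())
  if (nrow(candidates) == 0 || nrow(tails) == 0) return(empty)
  purrr::map_dfr(split(tails, tails$comparison), function(tl) {
    cmp <- tl$comparison[[1]]
    cand <- candidates$probe_id[candidates$comparison == cmp]
    if (length(cand) == 0) return(empty)
    seed_ids <- sort(unique(tl$seed_id))
    edges <- tl %>%
      filter(.data$probe_id %in% seed_ids) %>%
      transmute(
        from = pmin(.data$seed_id, .data$probe_id),
        to = pmax(.data$seed_id, .data$probe_id),
        sign = ifelse(.data$tail == "co", 1, -1)
      ) %>%
      distinct()
    sc <- signed_components(seed_ids, edges)
    related <- unique(c(edges$from, edges$to))
    tail_cand <- tl %>% filter(.data$probe_id %in% cand)
    genes_of_seed <- split(tail_cand$probe_id, tail_cand$seed_id)
    keep <- vapply(seed_ids, function(s) {
      s %in% related || length(genes_of_seed[[s]]) > 0
    }, logical(1))
    comp_ids <- sort(unique(sc$component[seed_ids[keep]]))
    purrr::map_dfr(seq_along(comp_ids), function(i) {
      members <- seed_ids[keep][sc$component[seed_ids[keep]] == comp_ids[[i]]]
      members <- sort(members)
      genes <- sort(unique(unlist(genes_of_seed[members], use.names = FALSE)))
      tibble(
        comparison = cmp,
        cluster_id = sprintf("%s_C%03d", cmp, i),
        n_seeds = length(members),
        n_genes = length(genes),
        polarity = if (sc$mixed[comp_ids[[i]]]) "mixed" else "coherent",
        seeds = list(members),
        seed_signs = list(sc$sign[members]),
        genes = list(genes)
      )
    })
  })
}
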