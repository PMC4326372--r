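test_that("the canonical design is the 20-array, 8-group layout", {
  d <- canonical_design()
  expect_equal(nrow(d), 20)
  groups <- dplyr::count(d, day, region, compartment, group)
  expect_equal(nrow(groups), 8)
  expect_true(all(groups$n[groups$compartment == "epithelium"] == 2))
  expect_true(all(groups$n[groups$compartment == "mesenchyme"] == 3))
  expect_equal(sort(unique(d$group)),
               sort(c("E7fe", "E7fm", "E9fe", "E9fm",
                      "E9se", "E9sm", "E11se", "E11sm")))
})

test_that("simulation is bit-reproducible from its seed", {
  a <- simulate_expression(small_sim_config(rng_seed = 7))
  b <- simulate_expression(small_sim_config(rng_seed = 7))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$module_members, b$truth$module_members)
  c <- simulate_expression(small_sim_config(rng_seed = 8))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed_fold = 5), "exceed 5")
  expect_error(sim_config(n_probes = 100, n_modules = 5, module_size = 50),
               "exceeds n_probes")
  expect_error(sim_config(noise_sd = 0), "positive")
})

test_that("planted seeds carry the planted fold on the concordant side", {
  sim <- simulate_expression(small_sim_config(rng_seed = 1))
  gm <- group_means(sim$expr)
  info <- sim$truth$seed_info
  cmp <- comparisons()
  offset <- log2(8)
  noise_sd <- 0.25
  for (i in seq_len(nrow(info))) {
    row <- info[i, ]
    pair <- cmp[cmp$comparison == row$comparison, ]
    j <- match(row$probe_id, gm$probe_id)
    diff <- gm[[pair$group_a]][j] - gm[[pair$group_b]][j]
    expect_equal(row$direction == "up_in_a", diff > 0)
    # raw bound: the concordant side never cancels the fold
    expect_gte(abs(diff), offset - 3 * noise_sd)
    # trajectory-adjusted: removing the module contribution leaves the
    # planted offset up to replicate-mean noise
    adj <- abs(diff) - row$loading * abs(row$trajectory_diff)
    expect_lt(abs(adj - offset), 4 * noise_sd)
  }
})

test_that("modules are internally co-regulated and pairwise reciprocal", {
  sim <- simulate_expression(small_sim_config(rng_seed = 2))
  centered <- center_probes(sim$expr)$values
  mcor <- function(ids_a, ids_b) {
    cc <- cor(t(centered[ids_a, ]), t(centered[ids_b, ]))
    if (identical(ids_a, ids_b)) mean(cc[upper.tri(cc)]) else mean(cc)
  }
  mm <- sim$truth$module_members
  expect_gt(mcor(mm$M1, mm$M1), 0.5)  # within-module cosine well above noise
  expect_gt(mcor(mm$M2, mm$M2), 0.5)
  expect_lt(mcor(mm$M1, mm$M2), -0.5) # paired modules are reciprocal
  # background pairs are uncorrelated in comparison
  bg <- setdiff(rownames(centered),
                c(unlist(mm), unlist(sim$truth$planted_seeds)))[1:30]
  expect_lt(abs(mcor(bg[1:15], bg[16:30])), 0.2)
})

test_that("seed allocation reaches every reciprocal axis and respects totals", {
  alloc <- cosreg:::seed_allocation(5, 30, 50)
  expect_true(all(lengths(alloc) == 30))
  # seeds land on the least-crowded side of every axis; the doubled side of
  # an odd module count is supported through its pair's reciprocal tails
  layout <- cosreg:::module_layout(5)
  seeded_axes <- unique(layout$axis[match(unique(unlist(alloc)),
                                          layout$module)])
  expect_equal(sort(seeded_axes), sort(unique(layout$axis)))
  sim <- simulate_expression(small_sim_config(rng_seed = 3))
  truth <- sim$truth
  expect_true(all(lengths(truth$planted_seeds) == 24))
  # every planted seed belongs to exactly one module
  expect_true(all(truth$module_of_seed %in% names(truth$module_members)))
  expect_equal(sort(names(truth$module_of_seed)),
               sort(unname(unlist(truth$planted_seeds))))
  # module member sets are disjoint from each other and from seeds
  all_members <- unlist(truth$module_members)
  expect_false(anyDuplicated(all_members) > 0)
  expect_length(intersect(all_members, names(truth$module_of_seed)), 0)
})

test_that("a null simulation is pure noise with no planted structure", {
  cfg <- sim_config(n_probes = 5000, n_modules = 0, rng_seed = 11)
  sim <- simulate_expression(cfg)
  expect_length(sim$truth$module_members, 0)
  expect_true(all(lengths(sim$truth$planted_seeds) == 0))
  scr <- suppressMessages(run_screen(sim$expr))
  expect_equal(sum(scr$summary$n_seeds), 0)
  expect_equal(nrow(scr$candidates), 0)
})

test_that("recovery scoring follows its conventions", {
  sim <- simulate_expression(small_sim_config(rng_seed = 4))
  planted <- unique(c(unlist(sim$truth$module_members),
                      unlist(sim$truth$planted_seeds)))
  perfect <- tibble::tibble(comparison = "E7fe_vs_E9se", probe_id = planted)
  rec <- score_recovery(perfect, sim$truth)
  expect_equal(rec$mean_recall, 1)
  expect_equal(rec$precision, 1)
  # empty candidate list: recall 0, precision reported 1 with a flag
  rec0 <- score_recovery(perfect[0, ], sim$truth)
  expect_equal(rec0$mean_recall, 0)
  expect_equal(rec0$precision, 1)
  expect_true(rec0$empty_candidates)
})
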