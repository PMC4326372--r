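test_that("cosine similarity matches the closed form", {
  expect_lt(abs(cosine_similarity(c(1, 2, 3), c(3, 2, 1)) - 10 / 14), 1e-12)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 4, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:2, 1:3), "equal length")
})

test_that("cosine is symmetric, scale-invariant, and signs parallels", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(a, b), cosine_similarity(3.7 * a, b),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(a, 2 * a), 1)
    expect_equal(cosine_similarity(a, -0.5 * a), -1)
  }
})

test_that("centering zeroes probe means and flags flat probes", {
  x <- make_expr(rbind(flat = c(5, 5, 5), slope = c(1, 3, 5)),
                 make_design(3))
  cx <- center_probes(x)
  expect_equal(unname(cx$values["flat", ]), c(0, 0, 0))
  expect_equal(unname(cx$values["slope", ]), c(-2, 0, 2))
  expect_equal(attr(cx, "zero_variance"), "flat")
})

test_that("centered cosine equals the Pearson correlation oracle", {
  set.seed(9)
  worst <- 0
  for (i in 1:1000) {
    a <- rnorm(20, 7, 1.5)
    b <- rnorm(20, 7, 1.5)
    got <- cosine_similarity(a - mean(a), b - mean(b))
    worst <- max(worst, abs(got - cor(a, b)))
  }
  expect_lt(worst, 1e-10)
})

test_that("Fisher z is the clipped arctanh", {
  expect_equal(fisher_z(0), 0)
  expect_lt(abs(fisher_z(0.5) - 0.5493061), 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  # poles are clipped at 1 - 1e-7
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_lt(abs(fisher_z(1) - 8.4059), 1e-3)
  expect_true(is.finite(fisher_z(-1)))
  # strictly increasing
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1.01), "\\[-1, 1\\]")
})

test_that("each seed flags exactly ceiling(tail_fraction * P) probes per side", {
  x <- random_expr(1000)
  st <- similarity_table(x, fake_seeds(x, n = 4))
  counts <- dplyr::count(st$tails, seed_id, tail)
  expect_true(all(counts$n == 5))  # ceil(0.005 * 1000) = 5 co + 5 reciprocal
  expect_equal(nrow(st$tails), 4 * 10)
  # the seed itself is never in its own tails
  expect_false(any(st$tails$seed_id == st$tails$probe_id))
  # cosines lie in [-1, 1], z = arctanh(clipped cosine)
  expect_true(all(abs(st$tails$cosine) <= 1))
  expect_equal(st$tails$z, fisher_z(st$tails$cosine))
})

test_that("tail calling is deterministic and rejects bad fractions", {
  x <- random_expr(400)
  s <- fake_seeds(x, n = 3)
  expect_identical(similarity_table(x, s)$tails, similarity_table(x, s)$tails)
  expect_error(similarity_table(x, s, tail_fraction = 0), "strictly between")
  expect_error(similarity_table(x, s, tail_fraction = 0.5), "strictly between")
  expect_error(similarity_table(x, dplyr::bind_rows(
    s, dplyr::mutate(s, comparison = "E7fm_vs_E9sm"))), "one comparison")
})

test_that("pooled tails flag the requested fraction of all pairs", {
  x <- random_expr(500)
  st <- similarity_table(x, fake_seeds(x, n = 4), tail_fraction = 0.01,
                         pooled = TRUE)
  m <- ceiling(0.01 * 4 * 499)
  expect_equal(sum(st$tails$tail == "co"), m)
  expect_equal(sum(st$tails$tail == "reciprocal"), m)
})

test_that("planted module members land in their seeds' co tails", {
  sim <- simulate_expression(small_sim_config(rng_seed = 1))
  scr_x <- quantile_normalize(sim$expr)
  info <- sim$truth$seed_info
  sub <- info[info$comparison == "E7fe_vs_E9se", ]
  st <- suppressWarnings(similarity_table(scr_x, tibble::tibble(
    comparison = "E7fe_vs_E9se", probe_id = sub$probe_id,
    log2_diff = 3, direction = sub$direction)))
  capture <- vapply(seq_len(nrow(sub)), function(i) {
    co <- st$tails$probe_id[st$tails$tail == "co" &
                              st$tails$seed_id == sub$probe_id[i]]
    mean(sim$truth$module_members[[sub$module[i]]] %in% co)
  }, numeric(1))
  # the best-aligned seed carries its whole module in the co tail; a seed
  # whose boosted group sits low on the trajectory captures fewer, but the
  # average dwarfs the 0.5% background rate by two orders of magnitude
  expect_equal(max(capture), 1)
  expect_gte(mean(capture), 0.4)
})

test_that("the pooled cosine histogram uses 16 even bins that conserve counts", {
  x <- random_expr(300)
  st <- similarity_table(x, fake_seeds(x, n = 3))
  h <- cosine_histogram(st)
  expect_equal(nrow(h), 16)
  expect_equal(h$bin_left, seq(-1, 0.875, by = 0.125))
  expect_equal(h$bin_right, seq(-0.875, 1, by = 0.125))
  expect_equal(sum(h$count), 3 * 299)

  # perfectly collinear probes concentrate in the last bin, closed at 1
  base <- seq_len(20)
  v <- rbind(a = base, b = 2 * base, c = 3 * base, d = 1.5 * base)
  xc <- make_expr(v, canonical_design())
  st2 <- similarity_table(xc, tibble::tibble(
    comparison = "E7fe_vs_E9se", probe_id = "a", log2_diff = 3,
    direction = "up_in_a"), tail_fraction = 0.25, center = FALSE)
  h2 <- cosine_histogram(st2)
  expect_equal(h2$count[16], 3)
  expect_equal(sum(h2$count), 3)
})
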