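# A probe supported by 12 seeds (8 co + 4 reciprocal), one by exactly 10,
# one by 9, built by hand.
support_tails <- function() {
  make_tails(data.frame(
    seed_id = sprintf("s%02d", c(1:12, 1:10, 1:9)),
    probe_id = rep(c("hit12", "hit10", "miss9"), c(12, 10, 9)),
    tail = c(rep(c("co", "reciprocal"), c(8, 4)),
             rep(c("co", "reciprocal"), c(5, 5)),
             rep("co", 9))
  ))
}

test_that("candidate support counts distinct seeds over both tails", {
  cand <- build_candidates(support_tails(), min_seed_support = 10)
  expect_equal(sort(cand$probe_id), c("hit10", "hit12"))
  expect_equal(cand$support[cand$probe_id == "hit12"], 12)
  expect_equal(cand$n_co_seeds[cand$probe_id == "hit12"], 8)
  expect_equal(cand$n_recip_seeds[cand$probe_id == "hit12"], 4)
  expect_equal(cand$polarity[cand$probe_id == "hit12"], "co_dominant")
  # a tie between co and reciprocal support is mixed
  expect_equal(cand$polarity[cand$probe_id == "hit10"], "mixed")
  # exactly 10 is retained (inclusive threshold), 9 is dropped
  expect_true("hit10" %in% cand$probe_id)
  expect_false("miss9" %in% cand$probe_id)
})

test_that("raising the support threshold never grows the candidate list", {
  tl <- support_tails()
  sizes <- vapply(1:13, function(k) nrow(build_candidates(tl, k)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(build_candidates(tl, 0), "positive integer")
})

test_that("support distribution counts probes at each k and conserves totals", {
  tl <- support_tails()
  sd <- support_distribution(tl)
  expect_equal(sd$n_probes[sd$n_seeds == 12], 1)
  expect_equal(sd$n_probes[sd$n_seeds == 9], 1)
  expect_equal(sum(sd$n_probes), dplyr::n_distinct(tl$probe_id))
  # every probe in exactly one tail -> all mass at k = 1
  tl1 <- make_tails(data.frame(seed_id = "s1",
                               probe_id = c("a", "b", "c"), tail = "co"))
  sd1 <- support_distribution(tl1)
  expect_equal(sd1$n_seeds, 1)
  expect_equal(sd1$n_probes, 3)
})

test_that("mutually co-tailed seeds merge into one cluster with their genes", {
  tl <- make_tails(data.frame(
    seed_id = c("s1", "s2", "s1", "s1", "s2"),
    probe_id = c("s2", "s1", "g1", "g2", "g3"),
    tail = "co"
  ))
  cand <- tibble::tibble(comparison = "E7fe_vs_E9se",
                         probe_id = c("g1", "g2", "g3", "s1", "s2"))
  cl <- build_clusters(tl, cand)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$seeds[[1]], c("s1", "s2"))
  expect_equal(cl$polarity, "coherent")
  expect_equal(unname(cl$seed_signs[[1]]), c(1, 1))
  expect_true(all(c("g1", "g2", "g3") %in% cl$genes[[1]]))
})

test_that("reciprocally related seeds carry opposite signs; conflicts are mixed", {
  tl <- make_tails(data.frame(
    seed_id = c("s1", "s1", "s2"),
    probe_id = c("s2", "g1", "g2"),
    tail = c("reciprocal", "co", "co")
  ))
  cand <- tibble::tibble(comparison = "E7fe_vs_E9se",
                         probe_id = c("g1", "g2"))
  cl <- build_clusters(tl, cand)
  expect_equal(nrow(cl), 1)
  expect_equal(unname(cl$seed_signs[[1]]), c(1, -1))
  expect_equal(cl$polarity, "coherent")

  # s1-s2 related through both a co and a reciprocal tail: unresolvable
  tl2 <- make_tails(data.frame(
    seed_id = c("s1", "s2", "s1"),
    probe_id = c("s2", "s1", "g1"),
    tail = c("reciprocal", "co", "co")
  ))
  cl2 <- build_clusters(tl2, tibble::tibble(comparison = "E7fe_vs_E9se",
                                            probe_id = "g1"))
  expect_equal(cl2$polarity, "mixed")
})

test_that("unrelated seeds form one cluster each; genes may be shared", {
  tl <- make_tails(data.frame(
    seed_id = c("s1", "s2", "s3"),
    probe_id = c("g1", "g1", "g9"),
    tail = "co"
  ))
  cand <- tibble::tibble(comparison = "E7fe_vs_E9se", probe_id = "g1")
  cl <- build_clusters(tl, cand)
  # s3's tail has no candidate overlap and no seed relation -> dropped
  expect_equal(nrow(cl), 2)
  expect_true(all(vapply(cl$genes, identical, logical(1), "g1")))
  # cluster genes never appear from nowhere: union of member-seed tails
  all_tail_genes <- unique(tl$probe_id)
  expect_true(all(unlist(cl$genes) %in% intersect(all_tail_genes,
                                                  cand$probe_id)))
})

test_that("empty candidates give an empty cluster list", {
  tl <- support_tails()
  empty <- build_candidates(tl, min_seed_support = 99)
  expect_equal(nrow(build_clusters(tl, empty)), 0)
})
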