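others_example <- function() {
  list(
    B = iv("chr1", 0, 1e5),
    C = iv("chr1", 0, 5e4),
    D = iv("chr2", 0, 1e5)
  )
}

test_that("conservation score is the median of per-cell-type best Jaccard", {
  cs <- conservation_score(iv("chr1", 0, 1e5), others_example())
  expect_equal(unname(cs$per_celltype_best), c(1, 0.5, 0))
  expect_equal(cs$score, 0.5)

  # identical in all three cell types -> score 1
  same <- list(iv("chr1", 0, 1e5), iv("chr1", 0, 1e5), iv("chr1", 0, 1e5))
  expect_equal(conservation_score(iv("chr1", 0, 1e5), same)$score, 1)

  # no overlap anywhere -> score 0
  far <- list(iv("chr1", 5e5, 6e5), iv("chr1", 7e5, 8e5), iv("chr2", 0, 1e5))
  expect_equal(conservation_score(iv("chr1", 0, 1e5), far)$score, 0)

  expect_error(conservation_score(iv("chr1", 0, 1e5), list(iv("chr1", 0, 1))),
               "exactly three")
})

test_that("conservation score equals the brute-force oracle on random sets", {
  withr::local_seed(202)
  for (rep in 1:30) {
    basis <- random_interval_set(sample(1:20, 1))
    others <- list(random_interval_set(sample(0:20, 1)),
                   random_interval_set(sample(1:20, 1)),
                   random_interval_set(sample(1:20, 1)))
    scored <- tadlink:::score_tads(basis, others)
    for (i in seq_len(nrow(basis))) {
      expect_equal(scored$score[i],
                   oracle_conservation_score(basis[i, ], others))
    }
  }
})

test_that("permutation p-values follow the (r + 1) / (n + 1) convention", {
  sizes <- c(chr1 = 1e7, chr2 = 1e7)
  # observed score 1: no random same-length interval matches exactly
  same <- list(iv("chr1", 2e6, 2.4e6), iv("chr1", 2e6, 2.4e6),
               iv("chr1", 2e6, 2.4e6))
  p <- permutation_null(iv("chr1", 2e6, 2.4e6), same, sizes, n = 999, seed = 5)
  expect_equal(p, 1 / 1000)

  # observed score 0: every null score is >= 0, so p = 1
  far <- list(iv("chr2", 0, 1e5), iv("chr2", 2e5, 3e5), iv("chr2", 4e5, 5e5))
  p0 <- permutation_null(iv("chr1", 0, 1e5), far, sizes, n = 199, seed = 5)
  expect_equal(p0, 1)

  expect_error(
    permutation_null(iv("chr9", 0, 1e5), same, sizes, n = 199, seed = 5),
    "absent"
  )
})

test_that("BH adjustment matches hand-derived q-values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(numeric()), "at least one")
  expect_error(fdr_adjust(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("intersection and union variants follow max/min boundary rules", {
  tad <- iv("chr1", 0, 1e5)
  bm <- iv("chr1", c(1e4, 0, 5e3), c(1e5, 9e4, 9.5e4))
  expect_equal(build_intersection_tad(tad, bm),
               iv("chr1", 1e4, 9e4))
  expect_equal(build_union_tad(iv("chr1", 0, 1e5),
                               iv("chr1", c(1e4, 0, 5e3), c(1.1e5, 9e4, 9.5e4))),
               iv("chr1", 0, 1.1e5))
  # identity
  same <- iv("chr1", c(0, 0, 0), c(1e5, 1e5, 1e5))
  expect_equal(build_intersection_tad(tad, same), tad)
  expect_equal(build_union_tad(tad, same), tad)
  # disjoint matches -> empty intersection, NULL with warning
  ends_only <- iv("chr1", c(0, 9e4, 0), c(1e4, 1e5, 1e5))
  expect_warning(res <- build_intersection_tad(tad, ends_only), "Empty")
  expect_null(res)
  # union always contains intersection
  expect_true(build_union_tad(tad, bm)$start <=
                build_intersection_tad(tad, bm)$start)
})

test_that("consensus calling applies the length, score and FDR filters", {
  sizes <- c(chr1 = 2e7)
  # three planted TADs identical across cell types + random decoys, no jitter
  planted <- iv("chr1", c(1e6, 5e6, 9e6), c(1.5e6, 5.6e6, 9.7e6),
                id = c("P1", "P2", "P3"))
  withr::local_seed(33)
  decoys <- iv("chr1", s <- floor(runif(20, 11e6, 19e6)), s + 2e5,
               id = sprintf("D%02d", 1:20))
  basis <- dplyr::bind_rows(planted, decoys)
  others <- list(B = planted, C = planted, D = planted)
  cons <- call_consensus_tads(basis, others, sizes, n_permutations = 200,
                              seed = 9)
  expect_setequal(cons$tads$id, c("P1", "P2", "P3"))
  expect_equal(cons$tads$score, rep(1, 3))
  # intersection == union == source for exact copies
  expect_equal(cons$tads$int_start, cons$tads$src_start)
  expect_equal(cons$tads$uni_end, cons$tads$src_end)

  # a TAD whose score is exactly 0.5 is excluded (strict inequality)
  half <- list(B = iv("chr1", 0, 1e5), C = iv("chr1", 0, 1e5),
               D = iv("chr1", 5e6, 6e6))
  cons2 <- call_consensus_tads(iv("chr1", 0, 2e5, id = "H"), half, sizes,
                               n_permutations = 200, seed = 9)
  expect_equal(tadlink:::score_tads(iv("chr1", 0, 2e5), half)$score, 0.5)
  expect_equal(nrow(cons2$tads), 0)

  # a 90 kb TAD is excluded by the minimum length even at score 1
  short <- iv("chr1", 0, 9e4, id = "S")
  cons3 <- suppressWarnings(call_consensus_tads(
    short, list(B = short, C = short, D = short), sizes,
    n_permutations = 200, seed = 9
  ))
  expect_equal(nrow(cons3$tads), 0)
  expect_false(cons3$scores$tested[1])
})

test_that("consensus calling is deterministic for a fixed seed", {
  sizes <- c(chr1 = 1e7, chr2 = 1e7)
  sim <- simulate_tad_calls(sizes, n_tads = 14, conserved_fraction = 0.5,
                            seed = 21)
  run <- function() suppressWarnings(
    call_consensus_tads(sim$tads[[sim$basis]], sim$tads[-1], sizes,
                        n_permutations = 150, seed = 77)
  )
  expect_identical(run()$tads, run()$tads)
})
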