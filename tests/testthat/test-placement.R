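test_that("GC fraction and CpG density count bases and CG dinucleotides", {
  g <- string_genome(c(chrA = "GCGC", chrB = "ATAT", chrC = "CGCG"))
  res <- compute_gc_cpg(iv(c("chrA", "chrB", "chrC"), 0, 4), g)
  expect_equal(res$gc, c(1, 0, 1))
  expect_equal(res$cpg, c(1 / 4, 0, 2 / 4))
  # ambiguous bases count in the denominator only
  gn <- string_genome(c(chrN = "GCNN"))
  rn <- compute_gc_cpg(iv("chrN", 0, 4), gn)
  expect_equal(rn$gc, 0.5)
  expect_error(compute_gc_cpg(iv("chrZ", 0, 4), g), "absent")
  expect_error(compute_gc_cpg(iv("chrA", 0, 10), g), "beyond")
})

test_that("matched randomization preserves length and composition", {
  sizes <- c(chr1 = 4e5, chr2 = 4e5)
  genome <- simulate_genome(sizes, gc = 0.45, cpg_rate = 0.02, seed = 31)
  dmr <- compute_gc_cpg(iv("chr1", 1000, 3000), genome)
  for (s in 1:5) {
    r <- matched_random_interval(dmr, genome, seed = s)
    expect_equal(r$end - r$start, 2000)
    expect_lte(abs(r$gc - dmr$gc), 0.05)
    expect_lte(abs(r$cpg - dmr$cpg), 0.005)
  }
})

test_that("matched random positions are near-uniform on a uniform genome", {
  sizes <- c(chr1 = 4e5)
  genome <- simulate_genome(sizes, gc = 0.40, cpg_rate = 0.01, seed = 32)
  dmr <- compute_gc_cpg(iv("chr1", 1000, 2000), genome)
  draws <- withr::with_seed(99, tadlink:::matched_random_batch(
    tibble::tibble(length = rep(1000, 2000), gc = dmr$gc, cpg = dmr$cpg),
    genome
  ))
  # chi-square uniformity over 8 position bins
  bins <- cut(draws$start, breaks = seq(0, 4e5, length.out = 9))
  chi <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(chi$p.value, 0.001)
})

test_that("inside-TAD fraction counts partial overlap", {
  tads <- iv("chr1", c(0, 2e5), c(1e5, 3e5))
  expect_equal(inside_tad_fraction(iv("chr1", c(10, 2e5), c(20, 2.1e5)), tads), 1)
  expect_equal(inside_tad_fraction(iv("chr2", 0, 100), tads), 0)
  # one DMR overlapping by a single bp still counts
  dmrs <- iv("chr1", c(10, 99999, 150000, 250000),
             c(20, 100100, 150100, 250100))
  expect_equal(inside_tad_fraction(dmrs, tads), 0.75)
  expect_error(inside_tad_fraction(iv(character(), numeric(), numeric()), tads),
               "at least one")
})

test_that("inside-TAD test returns a valid Monte Carlo and chi-square result", {
  sizes <- c(chr1 = 2e6, chr2 = 2e6)
  genome <- simulate_genome(sizes, seed = 41)
  tads <- iv(rep(c("chr1", "chr2"), each = 2),
             c(0, 1e6, 2e5, 1.2e6), c(6e5, 1.4e6, 7e5, 1.7e6))
  withr::local_seed(42)
  dmrs <- compute_gc_cpg(random_interval_set(40, max_len = 2000,
                                             genome_size = 2e6), genome)
  res <- inside_tad_test(dmrs, tads, genome, n_sims = 100, seed = 7)
  expect_s3_class(res, "placement_test")
  expect_length(res$per_sim, 100)
  expect_equal(res$expected, mean(res$per_sim))
  expect_gt(res$mc_p, 0)
  expect_lte(res$mc_p, 1)
  # deterministic under a fixed seed
  res2 <- inside_tad_test(dmrs, tads, genome, n_sims = 100, seed = 7)
  expect_identical(glance(res), glance(res2))

  # degenerate: TADs tile the whole genome, observed equals every simulation
  full <- iv(c("chr1", "chr2"), 0, 2e6)
  sat <- suppressWarnings(inside_tad_test(dmrs, full, genome, n_sims = 100,
                                          seed = 7))
  expect_equal(sat$mc_p, 1)
})

test_that("boundary distance is the clamped minimum over the two anchors", {
  expect_equal(boundary_distance(iv("chr1", 1e4, 1.2e4), iv("chr1", 0, 1e6)),
               1e4)
  expect_equal(boundary_distance(iv("chr1", 4.99e5, 5.01e5), iv("chr1", 0, 1e6)),
               4.99e5)
  # straddling a boundary -> 0
  expect_equal(boundary_distance(iv("chr1", 9.9e5, 1.01e6), iv("chr1", 0, 1e6)),
               0)
  expect_error(boundary_distance(iv("chr1", 0, 10), iv("chr1", 100, 200)),
               "overlap")
})

test_that("DMRs are assigned to their largest-overlap TAD deterministically", {
  tads <- iv("chr1", c(0, 9e5), c(1e6, 2e6), id = c("T1", "T2"))
  dmrs <- iv("chr1", c(9.5e5, 9.9e5), c(9.6e5, 1.2e6), id = c("a", "b"))
  bt <- dmr_boundary_table(dmrs, tads)
  expect_equal(bt$tad_id, c("T1", "T2")) # a inside both, larger overlap in T1&T2 equal -> leftmost; b mostly in T2
  expect_equal(bt$distance[1], 4e4) # 1e6 - 9.6e5 within T1
})

test_that("boundary proximity test detects planted anchor-proximal DMRs", {
  tads <- iv("chr1", c(0, 2e6), c(1e6, 3.5e6), id = c("T1", "T2"))
  # all DMRs within 50 kb of an anchor
  dmrs <- iv("chr1",
             c(1e4, 9.6e5, 2.01e6, 3.46e6, 2e4, 9.7e5),
             c(1.2e4, 9.62e5, 2.012e6, 3.462e6, 2.2e4, 9.72e5))
  res <- boundary_proximity_test(dmrs, tads, n_sims = 500, seed = 13)
  expect_equal(res$observed, 6)
  expect_equal(res$mc_p, 1 / 501)
  expect_lt(res$chi2_p, 0.01)
  # Monte Carlo and chi-square agree in direction
  expect_lt(res$mc_p, 0.05)
  expect_length(res$per_sim, 500)

  # DMR longer than its TAD is excluded with a warning
  tiny_tad <- iv("chr1", c(0, 5e6), c(1e3, 6e6), id = c("small", "big"))
  mix <- iv("chr1", c(0, 5.1e6), c(1500, 5.102e6))
  expect_warning(
    res2 <- boundary_proximity_test(mix, tiny_tad, n_sims = 100, seed = 13),
    "longer than"
  )
  expect_equal(res2$n_units, 1) # the 1.5 kb DMR exceeds its 1 kb TAD
})

test_that("saturated geometry: every position proximal contributes equally", {
  # TAD of 80 kb: every placement is within 50 kb of a boundary
  tads <- iv("chr1", 0, 8e4, id = "T")
  dmrs <- iv("chr1", 4e4, 4.1e4)
  expect_warning(
    res <- boundary_proximity_test(dmrs, tads, n_sims = 100, seed = 3),
    "Degenerate"
  )
  expect_equal(res$observed, 1)
  expect_true(all(res$per_sim == 1))
  expect_equal(res$mc_p, 1)
})
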