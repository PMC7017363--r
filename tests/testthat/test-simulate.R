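test_that("simulated genomes hit the requested GC and CpG composition", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  g <- simulate_genome(sizes, gc = 0.40, cpg_rate = 0.01, seed = 51)
  L <- sum(Biostrings::width(g))
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / L
  cpg <- sum(Biostrings::vcountPattern("CG", g)) / L
  expect_lte(abs(gc - 0.40), 0.02)
  expect_lte(abs(cpg - 0.01) / 0.01, 0.2)

  # CpG creation direction (target above the i.i.d. rate) also converges
  g2 <- simulate_genome(c(chr1 = 5e5), gc = 0.40, cpg_rate = 0.06, seed = 52)
  cpg2 <- sum(Biostrings::vcountPattern("CG", g2)) / 5e5
  gc2 <- sum(Biostrings::letterFrequency(g2, c("G", "C"))) / 5e5
  expect_lte(abs(cpg2 - 0.06) / 0.06, 0.2)
  expect_lte(abs(gc2 - 0.40), 0.02)

  # zero CpG boundary case
  g0 <- simulate_genome(c(chr1 = 2e5), cpg_rate = 0, seed = 53)
  expect_equal(sum(Biostrings::vcountPattern("CG", g0)), 0)

  # byte-for-byte determinism
  expect_identical(as.character(simulate_genome(c(chr1 = 1e5), seed = 54)),
                   as.character(simulate_genome(c(chr1 = 1e5), seed = 54)))
  expect_error(simulate_genome(sizes, gc = 0.4, cpg_rate = 0.5), "cpg_rate")
})

test_that("TAD simulation plants conserved domains with controlled jitter", {
  sizes <- c(chr1 = 2e7, chr2 = 2e7)
  # zero jitter: every planted TAD appears identically -> score exactly 1
  sim0 <- simulate_tad_calls(sizes, n_tads = 30, conserved_fraction = 0.4,
                             boundary_jitter_sd = 0, seed = 61)
  basis <- sim0$tads[[sim0$basis]]
  planted <- basis[basis$id %in% sim0$truth$conserved_tad_ids, ]
  scored <- tadlink:::score_tads(planted, sim0$tads[-1])
  expect_equal(scored$score, rep(1, nrow(planted)))

  # 5 kb jitter on >= 200 kb TADs keeps scores high
  sim5 <- simulate_tad_calls(sizes, n_tads = 30, conserved_fraction = 0.4,
                             boundary_jitter_sd = 5000, seed = 62)
  basis5 <- sim5$tads[[sim5$basis]]
  planted5 <- basis5[basis5$id %in% sim5$truth$conserved_tad_ids, ]
  scored5 <- tadlink:::score_tads(planted5, sim5$tads[-1])
  expect_gt(median(scored5$score), 0.9)

  # TADs never overlap within a cell type
  for (ct in names(sim5$tads)) {
    t <- dplyr::arrange(sim5$tads[[ct]], chrom, start)
    by_chrom <- split(t, t$chrom)
    for (b in by_chrom) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
  expect_equal(nrow(basis), 30)
  expect_error(simulate_tad_calls(sizes, tad_length_range = c(5e4, 2e5)),
               "100 kb")
})

test_that("gene/DMR simulation respects the planted mixture", {
  sizes <- c(chr1 = 8e6, chr2 = 8e6)
  g <- simulate_genome(sizes, seed = 71)
  ts <- simulate_tad_calls(sizes, n_tads = 24, conserved_fraction = 0.5,
                           seed = 71)
  gd <- simulate_genes_and_dmrs(g, ts, n_genes = 80, n_dmrs = 60,
                                frac_dmrs_genic = 0.4,
                                frac_dmrs_boundary_proximal = 0.3,
                                n_spatial_pairs = 3, seed = 71)
  expect_equal(nrow(gd$genes), 80)
  expect_equal(nrow(gd$dmrs), 60)
  expect_equal(sum(gd$dmrs$genic), 24) # 0.4 * 60, genic placement guaranteed
  # planted boundary-proximal DMRs really are proximal to a conserved TAD
  basis <- ts$tads[[ts$basis]]
  cons <- basis[basis$id %in% ts$truth$conserved_tad_ids, ]
  prox <- gd$dmrs[gd$dmrs$id %in% gd$truth$boundary_proximal_dmr_ids, ]
  bt <- dmr_boundary_table(prox, cons)
  expect_equal(nrow(bt), nrow(prox))
  expect_true(all(bt$distance <= 5e4))
  expect_true(all(!prox$genic))
  # planted spatial pairs resolve against emitted ids
  pp <- gd$truth$planted_link_pairs
  expect_true(all(pp$dmr_id %in% gd$dmrs$id))
  expect_true(all(pp$gene_id %in% gd$genes$gene_id))
  expect_true(all(pp$tad_id %in% cons$id))

  # all-non-genic boundary case
  gd0 <- simulate_genes_and_dmrs(g, ts, n_genes = 40, n_dmrs = 20,
                                 frac_dmrs_genic = 0,
                                 frac_dmrs_boundary_proximal = 0.5,
                                 n_spatial_pairs = 2, seed = 72)
  expect_false(any(gd0$dmrs$genic))
  # infeasible mixture errors
  expect_error(
    simulate_genes_and_dmrs(g, ts, frac_dmrs_genic = 0.8,
                            frac_dmrs_boundary_proximal = 0.5, seed = 73),
    "exceed 1"
  )
})

test_that("planted spatial pairs are recovered as spatial links", {
  sizes <- c(chr1 = 1e7, chr2 = 1e7)
  g <- simulate_genome(sizes, seed = 81)
  ts <- simulate_tad_calls(sizes, n_tads = 24, conserved_fraction = 0.5,
                           seed = 81)
  gd <- simulate_genes_and_dmrs(g, ts, n_genes = 80, n_dmrs = 40,
                                frac_dmrs_genic = 0.3,
                                frac_dmrs_boundary_proximal = 0.4,
                                n_spatial_pairs = 4, seed = 81)
  lk <- link_dmrs_to_genes(gd$dmrs[!gd$dmrs$genic, ], gd$genes,
                           ts$tads[[ts$basis]])
  m <- dplyr::inner_join(gd$truth$planted_link_pairs, lk, by = "dmr_id",
                         suffix = c(".true", ".obs"))
  expect_equal(nrow(m), 4)
  expect_equal(m$gene_id.obs, m$gene_id.true)
  expect_equal(m$kind.obs, rep("spatial", 4))
})

test_that("a full synthetic dataset is reproducible byte-for-byte", {
  sizes <- c(chr1 = 2e6, chr2 = 2e6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(chrom_sizes = sizes, n_tads = 10, n_genes = 30, n_dmrs = 20,
               n_spatial_pairs = 1, planted = c(organ_02 = 3), seed = 91)
  s1 <- do.call(simulate_dataset, c(args, list(dir = d1)))
  s2 <- do.call(simulate_dataset, c(args, list(dir = d2)))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # ground truth ids resolve against the emitted tables
  expect_true(all(s1$truth$conserved_tad_ids %in% s1$tads[[s1$basis]]$id))
  expect_true(all(s1$truth$boundary_proximal_dmr_ids %in% s1$dmrs$id))
})
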