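test_that("linear distance requires a shared TAD and measures edge gaps", {
  tad <- iv("chr1", 0, 1e6)
  expect_equal(linear_distance(iv("chr1", 1e5, 1.02e5), iv("chr1", 1.4e5, 1.6e5),
                               tad), 38000)
  # gene outside the TAD -> undefined
  expect_true(is.na(linear_distance(iv("chr1", 1e5, 1.02e5),
                                    iv("chr1", 2e6, 2.1e6), tad)))
  # abutting -> 0
  expect_equal(linear_distance(iv("chr1", 1e5, 1.4e5), iv("chr1", 1.4e5, 1.6e5),
                               tad), 0)
})

test_that("spatial distance takes the best opposite-anchor pairing", {
  tad <- iv("chr1", 0, 1e6)
  # DMR 10 kb from the left anchor, gene ending 20 kb from the right anchor
  dmr <- iv("chr1", 1e4, 1.2e4)
  gene <- iv("chr1", 9.5e5, 9.8e5)
  expect_equal(spatial_distance(dmr, gene, tad), 1e4 + 2e4)
  expect_gt(linear_distance(dmr, gene, tad), 9e5) # linear remains huge
  # both at the left anchor: one must traverse the TAD
  both_left <- spatial_distance(iv("chr1", 0, 2e3), iv("chr1", 3e3, 8e3), tad)
  expect_gte(both_left, 1e6 - 8e3)
  # straddling opposite anchors -> 0
  expect_equal(spatial_distance(iv("chr1", -0 + 0, 2e3), iv("chr1", 9.99e5, 1.01e6), tad), 0)
})

test_that("link assignment equals the brute-force all-pairs oracle", {
  withr::local_seed(303)
  for (rep in 1:30) {
    tads <- random_interval_set(sample(1:10, 1), max_len = 4e5)
    tads$id <- sprintf("T%02d", seq_len(nrow(tads)))
    genes <- random_interval_set(sample(1:50, 1), max_len = 5e4)
    genes$gene_id <- sprintf("g%03d", seq_len(nrow(genes)))
    dmrs <- random_interval_set(sample(1:50, 1), max_len = 3e3)
    dmrs$id <- sprintf("d%03d", seq_len(nrow(dmrs)))
    got <- link_dmrs_to_genes(dmrs, genes, tads) |> dplyr::arrange(dmr_id)
    want <- oracle_links(dmrs, genes, tads)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("anchor-opposite geometry links through space, not along the DNA", {
  # gene and DMR at opposite anchors of a 1.3 Mb TAD; anchor offsets sum
  # to 30 kb while the linear separation exceeds 1 Mb
  tad <- iv("chr1", 2e6, 3.3e6, id = "T1")
  dmr <- iv("chr1", 2.01e6, 2.012e6, id = "d1")
  gene <- iv("chr1", 3.26e6, 3.28e6, gene_id = "far_gene")
  lk <- link_dmrs_to_genes(dmr, gene, tad)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$kind, "spatial")
  expect_equal(lk$distance, 1e4 + 2e4)
  expect_gt(linear_distance(dmr, gene, tad), 1e6)
})

test_that("the 50 kb threshold is strict and links are monotone in it", {
  tad <- iv("chr1", 0, 1e6, id = "T1")
  gene <- iv("chr1", 5e5, 5.2e5, gene_id = "g1")
  # DMR exactly 50 kb away: excluded (strict <)
  dmr50 <- iv("chr1", 4.48e5, 4.5e5, id = "d50")
  expect_equal(nrow(link_dmrs_to_genes(dmr50, gene, tad)), 0)
  expect_equal(nrow(link_dmrs_to_genes(dmr50, gene, tad, max_distance = 50001)), 1)
  # DMR in no TAD: no link
  lonely <- iv("chr2", 0, 2e3, id = "d0")
  expect_equal(nrow(link_dmrs_to_genes(lonely, gene, tad)), 0)
  # monotonicity: enlarging the threshold never removes a link
  withr::local_seed(17)
  tads <- random_interval_set(5, max_len = 4e5); tads$id <- paste0("T", 1:5)
  genes <- random_interval_set(30, max_len = 5e4)
  genes$gene_id <- sprintf("g%02d", 1:30)
  dmrs <- random_interval_set(30, max_len = 3e3)
  dmrs$id <- sprintf("d%02d", 1:30)
  small <- link_dmrs_to_genes(dmrs, genes, tads, max_distance = 2e4)
  big <- link_dmrs_to_genes(dmrs, genes, tads, max_distance = 5e4)
  expect_true(all(small$dmr_id %in% big$dmr_id))
  expect_true(all(big$distance < 5e4))
})

test_that("genic DMRs and duplicate gene ids are rejected", {
  tad <- iv("chr1", 0, 1e6, id = "T1")
  gene <- iv("chr1", 5e5, 5.2e5, gene_id = "g1")
  dmr <- iv("chr1", 1e3, 2e3, id = "d1", genic = TRUE)
  expect_error(link_dmrs_to_genes(dmr, gene, tad), "genic")
  genes2 <- iv("chr1", c(1e5, 2e5), c(1.5e5, 2.5e5), gene_id = c("g1", "g1"))
  expect_error(link_dmrs_to_genes(iv("chr1", 1e3, 2e3, id = "d1"), genes2, tad),
               "unique")
})

test_that("DMG merging separates new from previously identified genes", {
  links <- tibble::tibble(dmr_id = c("d1", "d2"), gene_id = c("B", "C"),
                          tad_id = "T1", distance = 1e3, kind = "linear")
  mg <- merge_dmg_lists(links, prior_dmgs = c("A", "B"))
  expect_setequal(mg$genes$gene_id, c("A", "B", "C"))
  expect_equal(mg$summary$n_new, 1)
  expect_equal(mg$summary$n_already_present, 1)
  expect_equal(mg$genes$source[mg$genes$gene_id == "B"], "both")

  # empty prior list: everything is new
  mg0 <- merge_dmg_lists(links, character())
  expect_true(all(mg0$links$is_new_dmg))

  # many DMRs may share a gene: 70 links -> 69 genes
  links70 <- tibble::tibble(
    dmr_id = sprintf("d%03d", 1:70),
    gene_id = c(sprintf("g%03d", 1:69), "g001"),
    tad_id = "T1", distance = 1e3, kind = "linear"
  )
  expect_equal(merge_dmg_lists(links70)$summary$n_linked_dmrs, 70)
  expect_equal(merge_dmg_lists(links70)$summary$n_dmgs, 69)
})

test_that("spatial links are never beaten by a defined shorter linear route", {
  withr::local_seed(404)
  for (rep in 1:10) {
    tads <- random_interval_set(6, max_len = 4e5)
    tads$id <- paste0("T", 1:6)
    genes <- random_interval_set(25, max_len = 5e4)
    genes$gene_id <- sprintf("g%02d", 1:25)
    dmrs <- random_interval_set(25, max_len = 3e3)
    dmrs$id <- sprintf("d%02d", 1:25)
    lk <- link_dmrs_to_genes(dmrs, genes, tads)
    sp <- lk[lk$kind == "spatial", ]
    for (i in seq_len(nrow(sp))) {
      d <- dmrs[dmrs$id == sp$dmr_id[i], ]
      g <- genes[genes$gene_id == sp$gene_id[i], ]
      t <- tads[tads$id == sp$tad_id[i], ]
      lin <- linear_distance(d, g, t)
      expect_true(is.na(lin) || lin > sp$distance[i])
    }
  }
})
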