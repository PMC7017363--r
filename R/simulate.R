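#' Simulate a genome sequence with controlled GC and CpG composition
#'
#' Chromosome sequences are drawn i.i.d. at the requested GC fraction, then
#' CpG dinucleotide sites are destroyed (G of a CG flipped to C) or created
#' (with a compensating swap that preserves GC content) until the genome-wide
#' CG rate matches `cpg_rate`. Mammalian genomes are strongly CpG-depleted
#' relative to the i.i.d. expectation, which is the regime emulated by the
#' default (`cpg_rate = 0.01` vs an i.i.d. expectation of `(gc/2)^2 = 0.04`).
#'
#' @param chrom_sizes Named numeric vector or two-column data frame of
#'   chromosome lengths (default two 20 Mb chromosomes).
#' @param gc Target genome-wide GC fraction (default 0.40).
#' @param cpg_rate Target CG dinucleotide rate per bp (default 0.01).
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#'
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                            gc = 0.40, cpg_rate = 0.01, seed = 1L) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (gc <= 0 || gc >= 1) abort("`gc` must be in (0, 1).")
  if (cpg_rate < 0 || cpg_rate > gc / 2) {
    abort("`cpg_rate` must be in [0, gc/2].")
  }
  letters4 <- as.raw(c(65L, 67L, 71L, 84L)) # A C G T
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, lapply(chrom_sizes, function(L) {
    L <- as.integer(L)
    idx <- sample.int(4L, L, replace = TRUE, prob = p)
    target <- round(cpg_rate * L)
    for (pass in 1:25) {
      cg <- which(idx[-L] == 2L & idx[-1L] == 3L)
      delta <- length(cg) - target
      if (delta == 0) break
      if (delta > 0) {
        # destroy: flip the G of a CG to C (GC content unchanged)
        kill <- if (delta >= length(cg)) cg else sample(cg, delta)
        idx[kill + 1L] <- 2L
      } else {
        # create: turn C[not G] into CG, swapping a free G elsewhere to the
        # overwritten base so GC content is unchanged
        cand <- which(idx[-L] == 2L & idx[-1L] != 3L)
        cand <- cand[!(cand %in% cg)] # paranoia; cg excluded already
        if (length(cand) == 0) break
        pick <- if (length(cand) <= -delta) cand else sample(cand, -delta)
        pick <- pick[!(pick - 1L) %in% pick] # avoid adjacent interactions
        old <- idx[pick + 1L]
        idx[pick + 1L] <- 3L
        need_swap <- which(old != 2L) # old base was A/T: GC went up by one
        if (length(need_swap) > 0) {
          free_g <- which(idx == 3L)
          free_g <- free_g[idx[pmax(1L, free_g - 1L)] != 2L]
          free_g <- setdiff(free_g, pick + 1L)
          swap <- sample(free_g, min(length(need_swap), length(free_g)))
          idx[swap] <- old[need_swap][seq_along(swap)]
        }
      }
    }
    rawToChar(letters4[idx])
  }))
  Biostrings::DNAStringSet(unlist(seqs))
}

# tile one chromosome with n non-overlapping intervals: lengths drawn from
# `length_range`, gaps from a stick-breaking split of the leftover space
tile_chromosome <- function(L, n, length_range) {
  if (n == 0) return(tibble(start = numeric(), end = numeric()))
  lens <- runif(n, length_range[1], length_range[2])
  if (sum(lens) > 0.95 * L) lens <- lens * (0.95 * L) / sum(lens)
  lens <- floor(lens)
  gap_total <- L - sum(lens)
  g <- runif(n + 1)
  gaps <- floor(g / sum(g) * gap_total)
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
  tibble(start = starts, end = starts + lens)
}

# tile the free space between planted intervals on one chromosome, aiming
# for the basis cell type's TAD density (TADs per bp)
fill_gaps <- function(L, planted, length_range, density) {
  planted <- planted[order(planted$start), , drop = FALSE]
  bounds <- c(0, rbind(planted$start, planted$end), L)
  free <- tibble(start = bounds[seq(1, length(bounds), 2)],
                 end = bounds[seq(2, length(bounds), 2)])
  out <- list()
  for (i in seq_len(nrow(free))) {
    gL <- free$end[i] - free$start[i]
    n <- min(floor(gL * density), floor(gL / mean(length_range)))
    if (n < 1) next
    t <- tile_chromosome(gL, n, c(length_range[1], min(length_range[2], gL)))
    t <- t[t$end - t$start >= length_range[1] / 2, , drop = FALSE]
    if (nrow(t) > 0) out[[length(out) + 1]] <-
        tibble(start = t$start + free$start[i], end = t$end + free$start[i])
  }
  if (length(out) == 0) tibble(start = numeric(), end = numeric())
  else list_rbind(out)
}

#' Simulate per-cell-type TAD calls with a planted conserved fraction
#'
#' Four cell types are emulated. The basis cell type tiles each chromosome
#' with non-overlapping TADs; a `conserved_fraction` of them is replicated in
#' the three other cell types with boundaries jittered by rounded Gaussian
#' noise, and the remaining space in those cell types is tiled with
#' independent random TADs. With zero jitter every planted TAD scores a
#' conservation score of exactly 1.
#'
#' @inheritParams simulate_genome
#' @param n_tads Number of basis-cell-type TADs (default 60), split across
#'   chromosomes proportionally to length.
#' @param conserved_fraction Fraction of basis TADs planted in all four cell
#'   types (default 0.5).
#' @param boundary_jitter_sd Gaussian SD of the boundary jitter in bp applied
#'   to planted TADs in the non-basis cell types (default 5000).
#' @param tad_length_range Uniform range of TAD lengths in bp (default
#'   200-800 kb; planted conserved TADs are always at least 100 kb).
#' @param celltypes Names of the four cell types; the first is the basis.
#'
#' @return A list with `tads` (named list of four interval tibbles with `id`),
#'   `basis` (name of the basis cell type) and `truth` (ids of the planted
#'   conserved basis TADs).
#' @export
simulate_tad_calls <- function(chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                               n_tads = 60, conserved_fraction = 0.5,
                               boundary_jitter_sd = 5000,
                               tad_length_range = c(2e5, 8e5),
                               celltypes = c("cellA", "cellB", "cellC", "cellD"),
                               seed = 1L) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (length(celltypes) != 4) abort("`celltypes` must name four cell types.")
  if (conserved_fraction < 0 || conserved_fraction > 1) {
    abort("`conserved_fraction` must be in [0, 1].")
  }
  if (tad_length_range[1] < 1e5) {
    abort("`tad_length_range` must start at >= 100 kb so planted conserved TADs pass the minimum-length filter.")
  }
  withr::with_seed(seed, {
    n_per_chrom <- round(n_tads * chrom_sizes / sum(chrom_sizes))
    n_per_chrom[1] <- n_tads - sum(n_per_chrom[-1])
    basis <- list_rbind(imap(as.list(n_per_chrom), function(n, ch) {
      t <- tile_chromosome(chrom_sizes[[ch]], n, tad_length_range)
      tibble(chrom = ch, start = t$start, end = t$end)
    }))
    if (nrow(basis) < n_tads) abort("Requested TADs do not fit in the genome.")
    basis$id <- sprintf("%s_%04d", celltypes[1], seq_len(nrow(basis)))

    n_cons <- round(conserved_fraction * nrow(basis))
    cons_idx <- sort(sample.int(nrow(basis), n_cons))
    conserved <- basis[cons_idx, , drop = FALSE]

    others <- lapply(celltypes[-1], function(ct) {
      planted <- conserved
      if (nrow(planted) > 0 && boundary_jitter_sd > 0) {
        planted$start <- planted$start + round(rnorm(nrow(planted), 0, boundary_jitter_sd))
        planted$end <- planted$end + round(rnorm(nrow(planted), 0, boundary_jitter_sd))
        planted$start <- pmax(0, planted$start)
        planted$end <- pmin(chrom_sizes[planted$chrom], planted$end)
        # keep planted TADs valid and non-overlapping within the cell type
        short <- planted$end - planted$start < 1e5
        planted$end[short] <- planted$start[short] + 1e5
        planted <- planted |>
          group_by(.data$chrom) |>
          arrange(.data$start, .by_group = TRUE) |>
          mutate(start = pmax(.data$start, lag(.data$end, default = -1) + 0)) |>
          filter(.data$end > .data$start) |>
          ungroup()
      }
      fill <- list_rbind(lapply(names(chrom_sizes), function(ch) {
        pl <- planted[planted$chrom == ch, c("start", "end")]
        f <- fill_gaps(chrom_sizes[[ch]], pl, tad_length_range,
                       density = n_tads / sum(chrom_sizes))
        if (nrow(f) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
        tibble(chrom = ch, start = f$start, end = f$end)
      }))
      out <- bind_rows(planted[c("chrom", "start", "end")], fill) |>
        arrange(.data$chrom, .data$start)
      out$id <- sprintf("%s_%04d", ct, seq_len(nrow(out)))
      out
    })
    names(others) <- celltypes[-1]

    list(
      tads = c(setNames(list(basis), celltypes[1]), others),
      basis = celltypes[1],
      truth = list(conserved_tad_ids = conserved$id)
    )
  })
}

# place k intervals uniformly, rejecting overlaps with `avoid` (bounded retries)
place_avoiding <- function(k, len_range, chrom_lengths, avoid, max_tries = 1000) {
  out <- list()
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    if (tries >= max_tries) {
      abort(sprintf("Placement failed: %d of %d intervals placed after %d tries.",
                    placed, k, tries))
    }
    len <- floor(runif(1, len_range[1], len_range[2]))
    cand <- draw_uniform_positions(1, len, chrom_lengths)
    ok <- nrow(avoid) == 0 ||
      !any(avoid$chrom == cand$chrom & avoid$start < cand$end & cand$start < avoid$end)
    if (ok) {
      placed <- placed + 1L
      out[[placed]] <- cand
    }
    tries <- tries + 1L
  }
  list_rbind(out)
}

#' Simulate genes and DMRs with planted placement and link structure
#'
#' Genes are placed uniformly over the genome. DMRs are a mixture: a genic
#' fraction placed inside gene bodies, a boundary-proximal fraction placed
#' within `proximal_cutoff` of a planted conserved TAD anchor (fully inside
#' the TAD, avoiding genes), and the remainder uniform avoiding genes. A
#' configurable number of spatial DMR-gene pairs is planted at opposite
#' anchors of large conserved TADs (anchor offsets below 20 kb each, linear
#' separation far above the link threshold), creating ground-truth
#' spatial-only links.
#'
#' @inheritParams simulate_genome
#' @param genome Genome from [simulate_genome()] (used for DMR GC/CpG).
#' @param tad_sim Result of [simulate_tad_calls()] on the same chromosomes.
#' @param n_genes,n_dmrs Counts (defaults 200 genes, 150 DMRs).
#' @param frac_dmrs_genic Fraction of DMRs placed inside gene bodies
#'   (default 0.65, mirroring the observed share of genic DMRs).
#' @param frac_dmrs_boundary_proximal Fraction of DMRs planted near conserved
#'   TAD anchors (default 0.3); together with `frac_dmrs_genic` must not
#'   exceed 1.
#' @param n_spatial_pairs Planted anchor-opposite DMR-gene pairs (default 5);
#'   counted within the boundary-proximal fraction.
#' @param gene_length_range,dmr_length_range Uniform length ranges in bp.
#' @param proximal_cutoff Anchor-proximity window in bp (default 50 kb).
#'
#' @return A list with `genes` (tibble: `chrom`, `start`, `end`, `gene_id`),
#'   `dmrs` (tibble: `chrom`, `start`, `end`, `id`, `gc`, `cpg`, `genic`) and
#'   `truth` (`boundary_proximal_dmr_ids`, `planted_link_pairs`).
#' @export
simulate_genes_and_dmrs <- function(genome, tad_sim,
                                    n_genes = 200, n_dmrs = 150,
                                    frac_dmrs_genic = 0.65,
                                    frac_dmrs_boundary_proximal = 0.3,
                                    n_spatial_pairs = 5,
                                    gene_length_range = c(2e3, 5e4),
                                    dmr_length_range = c(500, 3000),
                                    proximal_cutoff = 5e4, seed = 1L) {
  chrom_lengths <- setNames(vapply(seq_along(genome), function(i)
    length(genome[[i]]), numeric(1)), names(genome))
  n_genic <- round(frac_dmrs_genic * n_dmrs)
  n_prox <- round(frac_dmrs_boundary_proximal * n_dmrs)
  if (n_genic + n_prox > n_dmrs) {
    abort("`frac_dmrs_genic` + `frac_dmrs_boundary_proximal` must not exceed 1.")
  }
  if (n_spatial_pairs > n_prox) {
    abort("`n_spatial_pairs` cannot exceed the boundary-proximal DMR count.")
  }
  basis_tads <- tad_sim$tads[[tad_sim$basis]]
  cons <- basis_tads[basis_tads$id %in% tad_sim$truth$conserved_tad_ids, , drop = FALSE]
  if (n_prox > 0 && nrow(cons) == 0) {
    abort("Boundary-proximal DMRs requested but no conserved TAD was planted.")
  }

  withr::with_seed(seed, {
    # planted spatial pairs first: DMR at the left anchor, gene at the right
    big <- cons[cons$end - cons$start >= 3e5, , drop = FALSE]
    if (n_spatial_pairs > nrow(big)) {
      abort("Not enough large conserved TADs for the requested spatial pairs.")
    }
    sp_tads <- big[sample.int(nrow(big), n_spatial_pairs), , drop = FALSE]
    sp_dmr_len <- floor(runif(n_spatial_pairs, dmr_length_range[1], dmr_length_range[2]))
    sp_dmr_off <- floor(runif(n_spatial_pairs, 0, 2e4))
    sp_gene_len <- floor(runif(n_spatial_pairs, gene_length_range[1], gene_length_range[2]))
    sp_gene_off <- floor(runif(n_spatial_pairs, 0, 2e4))
    sp_dmrs <- tibble(chrom = sp_tads$chrom,
                      start = sp_tads$start + sp_dmr_off,
                      end = sp_tads$start + sp_dmr_off + sp_dmr_len)
    sp_genes <- tibble(chrom = sp_tads$chrom,
                       start = sp_tads$end - sp_gene_off - sp_gene_len,
                       end = sp_tads$end - sp_gene_off)

    # remaining genes uniform, kept out of the planted spatial TADs so the
    # planted partner stays the unique closest gene (ground-truth recovery)
    n_uni_genes <- n_genes - n_spatial_pairs
    uni_genes <- place_avoiding(n_uni_genes, gene_length_range, chrom_lengths,
                                avoid = sp_tads, max_tries = 50 * n_uni_genes)
    genes <- bind_rows(sp_genes, uni_genes)
    perm <- sample.int(nrow(genes)) # shuffle so planted genes get anonymous ids
    genes <- genes[perm, , drop = FALSE]
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    sp_gene_ids <- genes$gene_id[match(seq_len(n_spatial_pairs), perm)]

    # genic DMRs: inside a random gene, overlap guaranteed
    dmr_list <- list()
    if (n_genic > 0) {
      gi <- sample.int(nrow(genes), n_genic, replace = TRUE)
      len <- floor(runif(n_genic, dmr_length_range[1], dmr_length_range[2]))
      lo <- pmax(0, genes$start[gi] - len + 1)
      hi <- pmax(lo, pmin(genes$end[gi] - 1,
                          chrom_lengths[genes$chrom[gi]] - len))
      st <- floor(runif(n_genic) * (hi - lo + 1)) + lo
      dmr_list$genic <- tibble(chrom = genes$chrom[gi], start = st, end = st + len)
    }
    # boundary-proximal non-genic DMRs (beyond the planted spatial ones):
    # fully inside a conserved TAD, edge within proximal_cutoff of an anchor
    n_extra_prox <- n_prox - n_spatial_pairs
    if (n_extra_prox > 0) {
      prox <- list()
      tries <- 0L
      while (length(prox) < n_extra_prox) {
        if (tries > 200 * n_extra_prox) {
          abort(sprintf("Placement failed for boundary-proximal DMRs (%d of %d).",
                        length(prox), n_extra_prox))
        }
        tries <- tries + 1L
        ti <- sample.int(nrow(cons), 1)
        len <- floor(runif(1, dmr_length_range[1], dmr_length_range[2]))
        off <- floor(runif(1, 0, max(1, proximal_cutoff - len)))
        cand <- if (runif(1) < 0.5) {
          tibble(chrom = cons$chrom[ti], start = cons$start[ti] + off,
                 end = cons$start[ti] + off + len)
        } else {
          tibble(chrom = cons$chrom[ti], start = cons$end[ti] - off - len,
                 end = cons$end[ti] - off)
        }
        hit <- any(genes$chrom == cand$chrom & genes$start < cand$end &
                     cand$start < genes$end)
        if (!hit && cand$start >= 0) prox[[length(prox) + 1]] <- cand
      }
      dmr_list$prox <- list_rbind(prox)
    }
    # uniform non-genic remainder
    n_uni <- n_dmrs - n_genic - n_prox
    if (n_uni > 0) {
      dmr_list$uniform <- place_avoiding(n_uni, dmr_length_range, chrom_lengths,
                                         avoid = genes, max_tries = 200 * n_uni)
    }

    dmrs <- bind_rows(c(list(spatial = sp_dmrs), dmr_list))
    dmrs$id <- sprintf("dmr_%04d", seq_len(nrow(dmrs)))
    dmrs <- compute_gc_cpg(dmrs, genome)
    dmrs$genic <- inside_flags(dmrs, genes)

    prox_ids <- dmrs$id[seq_len(n_spatial_pairs)]
    if (n_extra_prox > 0) {
      off0 <- n_spatial_pairs + (if (n_genic > 0) n_genic else 0)
      prox_ids <- c(prox_ids, dmrs$id[off0 + seq_len(n_extra_prox)])
    }
    list(
      genes = genes[c("chrom", "start", "end", "gene_id")],
      dmrs = dmrs[c("chrom", "start", "end", "id", "gc", "cpg", "genic")],
      truth = list(
        boundary_proximal_dmr_ids = prox_ids,
        planted_link_pairs = tibble(
          dmr_id = dmrs$id[seq_len(n_spatial_pairs)],
          gene_id = sp_gene_ids,
          kind = rep("spatial", n_spatial_pairs),
          tad_id = sp_tads$id
        )
      )
    )
  })
}

#' Simulate a gene-to-organ annotation table with planted enrichment
#'
#' Each gene joins each organ independently at `base_rate`. For planted
#' organs, genes of the query list (`dmgs`) join at an elevated rate chosen so
#' that the expected measured enrichment ratio (observed over expected count
#' among the query genes) equals the requested fold, accounting for the
#' query's own contribution to the background frequency.
#'
#' @param genes Character vector of gene ids, or a data frame with `gene_id`.
#' @param dmgs Gene ids of the true differentially methylated genes.
#' @param n_organs Number of body parts (default 20).
#' @param base_rate Baseline gene-organ membership probability (default 0.2).
#' @param planted Named numeric vector of enrichment folds, e.g.
#'   `c(organ_03 = 3)`; names must be among the generated organ labels
#'   `organ_01 ... organ_NN`. `NULL` plants nothing.
#' @param seed Integer seed.
#'
#' @return A list with `annotations` (tibble `gene_id`, `organ`) and `truth`
#'   (`enriched_organs`).
#' @export
simulate_organ_annotations <- function(genes, dmgs = character(),
                                       n_organs = 20, base_rate = 0.2,
                                       planted = NULL, seed = 1L) {
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(as.character(genes))
  organs <- sprintf("organ_%02d", seq_len(n_organs))
  if (!is.null(planted)) {
    bad <- setdiff(names(planted), organs)
    if (length(bad) > 0) {
      abort(sprintf("Planted organ(s) not among generated labels: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  N <- length(genes)
  k <- sum(genes %in% dmgs)
  rates <- matrix(base_rate, nrow = N, ncol = n_organs,
                  dimnames = list(genes, organs))
  for (org in names(planted)) {
    f <- planted[[org]]
    if (N <= k * f) abort("Planted fold too large for the background size.")
    # member rate among query genes such that the expected measured
    # enrichment ratio equals the requested fold
    q <- min(1, f * base_rate * (N - k) / (N - k * f))
    rates[genes %in% dmgs, org] <- q
  }
  withr::with_seed(seed, {
    member <- matrix(runif(N * n_organs), nrow = N) < rates
    idx <- which(member, arr.ind = TRUE)
    ann <- tibble(gene_id = genes[idx[, 1]], organ = organs[idx[, 2]]) |>
      arrange(.data$gene_id, .data$organ)
    list(annotations = ann,
         truth = list(enriched_organs = names(planted) %||% character()))
  })
}

#' Simulate a complete synthetic dataset, optionally writing it to disk
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_tad_calls()],
#' [simulate_genes_and_dmrs()] and [simulate_organ_annotations()] under one
#' seed. With `dir` set, writes `genome.fa`, `chrom.sizes`,
#' `tads_<celltype>.bed`, `genes.bed`, `dmrs.bed`, `annotations.tsv` and
#' `ground_truth.json`; one seed fixes every emitted file byte-for-byte.
#'
#' @inheritParams simulate_genome
#' @inheritParams simulate_tad_calls
#' @inheritParams simulate_genes_and_dmrs
#' @inheritParams simulate_organ_annotations
#' @param dir Output directory (created if needed); `NULL` skips writing.
#'
#' @return A list: `genome`, `chrom_sizes`, `tads`, `basis`, `genes`, `dmrs`,
#'   `annotations`, `truth` (merged ground truth) and, when written, `paths`.
#' @export
simulate_dataset <- function(chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                             gc = 0.40, cpg_rate = 0.01,
                             n_tads = 60, conserved_fraction = 0.5,
                             boundary_jitter_sd = 5000,
                             tad_length_range = c(2e5, 8e5),
                             n_genes = 200, n_dmrs = 150,
                             frac_dmrs_genic = 0.65,
                             frac_dmrs_boundary_proximal = 0.3,
                             n_spatial_pairs = 5,
                             n_organs = 20, base_rate = 0.2, planted = NULL,
                             dir = NULL, seed = 1L) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  genome <- simulate_genome(chrom_sizes, gc = gc, cpg_rate = cpg_rate,
                            seed = derive_seed(seed, 1))
  tad_sim <- simulate_tad_calls(chrom_sizes, n_tads = n_tads,
                                conserved_fraction = conserved_fraction,
                                boundary_jitter_sd = boundary_jitter_sd,
                                tad_length_range = tad_length_range,
                                seed = derive_seed(seed, 2))
  gd <- simulate_genes_and_dmrs(genome, tad_sim, n_genes = n_genes,
                                n_dmrs = n_dmrs,
                                frac_dmrs_genic = frac_dmrs_genic,
                                frac_dmrs_boundary_proximal = frac_dmrs_boundary_proximal,
                                n_spatial_pairs = n_spatial_pairs,
                                seed = derive_seed(seed, 3))
  true_dmgs <- unique(gd$truth$planted_link_pairs$gene_id)
  ann <- simulate_organ_annotations(gd$genes, dmgs = true_dmgs,
                                    n_organs = n_organs, base_rate = base_rate,
                                    planted = planted,
                                    seed = derive_seed(seed, 4))
  out <- list(
    genome = genome,
    chrom_sizes = chrom_sizes,
    tads = tad_sim$tads,
    basis = tad_sim$basis,
    genes = gd$genes,
    dmrs = gd$dmrs,
    annotations = ann$annotations,
    truth = c(tad_sim$truth, gd$truth, ann$truth)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      chrom_sizes = file.path(dir, "chrom.sizes"),
      genes = file.path(dir, "genes.bed"),
      dmrs = file.path(dir, "dmrs.bed"),
      annotations = file.path(dir, "annotations.tsv"),
      ground_truth = file.path(dir, "ground_truth.json")
    )
    Biostrings::writeXStringSet(genome, paths$genome)
    readr::write_tsv(tibble(chrom = names(chrom_sizes), size = chrom_sizes),
                     paths$chrom_sizes, col_names = FALSE)
    for (ct in names(out$tads)) {
      p <- file.path(dir, sprintf("tads_%s.bed", ct))
      write_bed(out$tads[[ct]], p)
      paths[[paste0("tads_", ct)]] <- p
    }
    write_bed(dplyr::rename(gd$genes, id = "gene_id"), paths$genes)
    write_bed(gd$dmrs, paths$dmrs,
              extra = c("id", "gc", "cpg", "genic"))
    readr::write_tsv(ann$annotations, paths$annotations)
    jsonlite::write_json(out$truth, paths$ground_truth, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
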