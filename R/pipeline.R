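#' Run the full DMR-to-gene pipeline from files on disk
#'
#' Orchestrates the four analysis stages end to end: (1) consensus TAD
#' calling from four per-cell-type TAD BED files; (2) placement tests of the
#' DMRs against the consensus TADs (inside-TAD and boundary-proximity, for
#' each requested boundary variant); (3) linking of non-genic DMRs to genes
#' by linear/spatial distance and merging with a prior DMG list; (4)
#' body-part enrichment of the combined gene list. Every intermediate
#' artifact is written under `out_dir` together with a machine-readable
#' `summary.json`; for a fixed `seed` a rerun reproduces identical outputs.
#'
#' @param tad_files Named character vector of four TAD BED paths; names are
#'   cell-type labels.
#' @param basis Name of the basis cell type (default: the file with the most
#'   TADs, the recommended convention).
#' @param dmr_file DMR BED with id, gc, cpg and genic-flag columns (see
#'   [read_dmr_bed()]); `gc`/`cpg` are recomputed from the genome when absent.
#' @param gene_file Gene BED (column 4 = gene id).
#' @param genome_file Genome FASTA.
#' @param chrom_sizes_file Two-column chromosome sizes TSV.
#' @param annotation_file Gene-to-organ TSV (`gene_id`, `organ`); `NULL`
#'   skips the enrichment stage.
#' @param prior_dmg_file Optional text file with one previously identified
#'   DMG gene id per line.
#' @param out_dir Output directory, created if needed.
#' @param tad_variant `"both"` (default), `"intersection"` or `"union"`.
#' @param min_length,score_threshold,q_threshold,n_permutations Consensus
#'   parameters, see [call_consensus_tads()].
#' @param n_sims_inside,n_sims_boundary Simulation counts for the two
#'   placement tests (defaults 200 and 10000).
#' @param proximal_cutoff,max_distance Boundary-proximity window and
#'   DMR-gene link threshold in bp (both default 50 kb).
#' @param n_draws Random gene sets for the enrichment p-value (default 10000).
#' @param seed Integer seed governing all randomness.
#'
#' @return Invisibly, a list with the stage results (`consensus`, per-variant
#'   `placement`, `links`, `dmgs`, `enrichment`) and the `summary` list that
#'   was written to `summary.json`.
#' @export
run_pipeline <- function(tad_files, dmr_file, gene_file, genome_file,
                         chrom_sizes_file, annotation_file = NULL,
                         prior_dmg_file = NULL, out_dir,
                         basis = NULL,
                         tad_variant = c("both", "intersection", "union"),
                         min_length = 1e5, score_threshold = 0.5,
                         q_threshold = 0.05, n_permutations = 1000,
                         n_sims_inside = 200, n_sims_boundary = 10000,
                         proximal_cutoff = 50000, max_distance = 50000,
                         n_draws = 10000, seed = 1L) {
  tad_variant <- match.arg(tad_variant)
  if (length(tad_files) != 4 || is.null(names(tad_files))) {
    abort("`tad_files` must be a named vector of four TAD BED paths.")
  }
  for (f in c(tad_files, dmr_file, gene_file, genome_file, chrom_sizes_file,
              annotation_file, prior_dmg_file)) {
    if (!is.null(f) && !file.exists(f)) abort(sprintf("Input not found: %s", f))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  inform("[consensus] reading inputs")
  tad_sets <- lapply(tad_files, read_bed)
  chrom_sizes <- read_chrom_sizes(chrom_sizes_file)
  genome <- read_genome(genome_file)
  dmrs <- read_dmr_bed(dmr_file)
  genes <- read_gene_bed(gene_file)
  annotations <- if (!is.null(annotation_file)) read_organ_annotations(annotation_file)
  prior_dmgs <- if (!is.null(prior_dmg_file)) {
    unique(readr::read_lines(prior_dmg_file))
  } else character()
  if (!all(c("gc", "cpg") %in% names(dmrs)) || anyNA(dmrs$gc)) {
    dmrs <- compute_gc_cpg(dmrs, genome)
  }
  if (is.null(basis)) {
    basis <- names(tad_sets)[which.max(vapply(tad_sets, nrow, integer(1)))]
  }
  if (!basis %in% names(tad_sets)) abort("`basis` must name one of `tad_files`.")

  inform(sprintf("[consensus] basis = %s (%d TADs)", basis, nrow(tad_sets[[basis]])))
  consensus <- call_consensus_tads(
    tad_sets[[basis]], tad_sets[names(tad_sets) != basis], chrom_sizes,
    min_length = min_length, score_threshold = score_threshold,
    q_threshold = q_threshold, n_permutations = n_permutations,
    seed = derive_seed(seed, 11)
  )
  readr::write_tsv(consensus$tads, file.path(out_dir, "consensus_tads.tsv"))
  write_bed(consensus_variant(consensus, "intersection"),
            file.path(out_dir, "intersection_tads.bed"))
  write_bed(consensus_variant(consensus, "union"),
            file.path(out_dir, "union_tads.bed"))

  variants <- if (tad_variant == "both") c("intersection", "union") else tad_variant
  placement <- list()
  links <- list()
  dmgs <- list()
  enrichment <- list()
  summary <- list(
    seed = seed,
    basis = basis,
    n_basis_tads = nrow(consensus$scores),
    n_tested_tads = sum(consensus$scores$tested),
    n_conserved_tads = nrow(consensus$tads),
    n_dropped_tads = consensus$n_dropped,
    n_dmrs = nrow(dmrs),
    n_ngdmrs = sum(!dmrs$genic)
  )

  for (v in variants) {
    tads_v <- consensus_variant(consensus, v)
    inform(sprintf("[placement:%s] inside-TAD test (%d sims)", v, n_sims_inside))
    it <- inside_tad_test(dmrs, tads_v, genome, n_sims = n_sims_inside,
                          seed = derive_seed(seed, 21))
    inform(sprintf("[placement:%s] boundary-proximity test (%d sims)", v,
                   n_sims_boundary))
    bt_tbl <- dmr_boundary_table(dmrs, tads_v)
    readr::write_tsv(bt_tbl, file.path(out_dir, sprintf("boundary_distances_%s.tsv", v)))
    bp <- boundary_proximity_test(dmrs, tads_v, n_sims = n_sims_boundary,
                                  proximal_cutoff = proximal_cutoff,
                                  seed = derive_seed(seed, 22))
    placement[[v]] <- list(inside = it, boundary = bp)
    jsonlite::write_json(
      list(inside_tad = unclass(glance(it)), boundary_proximity = unclass(glance(bp))),
      file.path(out_dir, sprintf("placement_%s.json", v)),
      auto_unbox = TRUE, digits = NA
    )

    inform(sprintf("[link:%s] linking non-genic DMRs to genes", v))
    lk <- link_dmrs_to_genes(dmrs[!dmrs$genic, , drop = FALSE], genes, tads_v,
                             max_distance = max_distance)
    mg <- merge_dmg_lists(lk, prior_dmgs)
    links[[v]] <- mg$links
    dmgs[[v]] <- mg
    readr::write_tsv(mg$links, file.path(out_dir, sprintf("links_%s.tsv", v)))

    if (!is.null(annotations)) {
      inform(sprintf("[enrich:%s] body-part enrichment (%d draws)", v, n_draws))
      en <- organ_enrichment_test(mg$genes$gene_id, annotations,
                                  n_draws = n_draws,
                                  seed = derive_seed(seed, 31))
      enrichment[[v]] <- en
      readr::write_tsv(as_tibble(en), file.path(out_dir, sprintf("enrichment_%s.tsv", v)))
    }

    summary[[v]] <- list(
      inside_tad = list(observed = it$observed, expected = it$expected,
                        mc_p = it$mc_p, chi2 = it$chi2, chi2_p = it$chi2_p,
                        n_sims = it$n_sims, n_relaxed = it$n_relaxed),
      boundary = list(observed = bp$observed, expected = bp$expected,
                      mc_p = bp$mc_p, chi2 = bp$chi2, chi2_p = bp$chi2_p,
                      n_sims = bp$n_sims, n_participating = bp$n_units,
                      n_excluded = bp$n_excluded),
      n_links = nrow(mg$links),
      n_dmgs = mg$summary$n_dmgs,
      n_new_dmgs = mg$summary$n_new,
      n_spatial_links = sum(mg$links$kind == "spatial"),
      significant_organs = if (!is.null(annotations)) {
        en_tbl <- as_tibble(enrichment[[v]])
        sort(en_tbl$organ[en_tbl$significant])
      } else character()
    )
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(sprintf("[done] summary written to %s", file.path(out_dir, "summary.json")))
  invisible(list(consensus = consensus, placement = placement, links = links,
                 dmgs = dmgs, enrichment = enrichment, summary = summary))
}
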