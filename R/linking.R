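#' Linear distance between a DMR and a gene within a shared TAD
#'
#' The gap in bp between the nearest edges of the DMR and the gene, measured
#' along the chromosome, defined only when both intervals overlap the TAD
#' (otherwise `NA`). Touching or overlapping features have distance 0.
#'
#' @param dmrs,genes,tads Interval data frames of equal row count, paired
#'   row-wise.
#' @return Numeric vector of distances in bp, `NA` where undefined.
#' @export
linear_distance <- function(dmrs, genes, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  genes <- as_intervals(genes, arg = "genes")
  tads <- as_intervals(tads, arg = "tads")
  d <- pmax(0, pmax(genes$start - dmrs$end, dmrs$start - genes$end))
  in_tad <- overlap_length(dmrs$chrom, dmrs$start, dmrs$end,
                           tads$chrom, tads$start, tads$end) > 0 &
    overlap_length(genes$chrom, genes$start, genes$end,
                   tads$chrom, tads$start, tads$end) > 0
  ifelse(in_tad, d, NA_real_)
}

#' Spatial (anchor-mediated) distance between a DMR and a gene
#'
#' Chromatin loops bring the two boundary anchors of a TAD into physical
#' proximity, so a DMR near one anchor can act on a gene near the other. The
#' spatial distance is the smaller, over the two opposite-anchor pairings, of
#' the sum of each feature's clamped distance to its anchor:
#' `min(dL(dmr) + dR(gene), dR(dmr) + dL(gene))`, where `dL`/`dR` are the
#' distances of a feature's nearest edge to the left/right TAD boundary
#' (0 for a feature crossing the boundary). Defined only when both features
#' overlap the TAD (`NA` otherwise).
#'
#' @inheritParams linear_distance
#' @return Numeric vector of distances in bp, `NA` where undefined.
#' @export
spatial_distance <- function(dmrs, genes, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  genes <- as_intervals(genes, arg = "genes")
  tads <- as_intervals(tads, arg = "tads")
  dL <- function(x) pmax(0, x$start - tads$start)
  dR <- function(x) pmax(0, tads$end - x$end)
  d <- pmin(dL(dmrs) + dR(genes), dR(dmrs) + dL(genes))
  in_tad <- overlap_length(dmrs$chrom, dmrs$start, dmrs$end,
                           tads$chrom, tads$start, tads$end) > 0 &
    overlap_length(genes$chrom, genes$start, genes$end,
                   tads$chrom, tads$start, tads$end) > 0
  ifelse(in_tad, d, NA_real_)
}

#' Link non-genic DMRs to genes through consensus TADs
#'
#' For every non-genic DMR (ngDMR) and every gene sharing a consensus TAD with
#' it, two distances are computed: the linear distance along the chromosome
#' and the anchor-mediated spatial distance ([spatial_distance()]). The
#' effective DMR-gene distance is the minimum of the two, minimised over all
#' shared TADs. Each ngDMR is linked to the single closest gene when that
#' distance is strictly below `max_distance`; `kind` records whether the
#' linear or the spatial route achieved the minimum (linear wins ties). Ties
#' between equally close genes break lexicographically by `gene_id`.
#'
#' @param ngdmrs DMR interval data frame with an `id` column; rows flagged
#'   genic (`genic == TRUE`) are rejected.
#' @param genes Gene data frame: `chrom`, `start`, `end`, `gene_id` (unique).
#' @param tads Interval data frame of consensus TADs (one boundary variant,
#'   e.g. from [consensus_variant()]), with an `id` column.
#' @param max_distance Link threshold in bp, strict `<` (default 50 kb).
#' @param gene_anchor `"body"` measures distances to the nearest gene-body
#'   edge (default); `"tss"` measures to the start coordinate (5' end taken as
#'   `start`; gene BED input is unstranded here).
#'
#' @return A tibble with one row per linked ngDMR: `dmr_id`, `gene_id`,
#'   `tad_id`, `distance`, `kind` (`"linear"` or `"spatial"`).
#' @export
link_dmrs_to_genes <- function(ngdmrs, genes, tads, max_distance = 50000,
                               gene_anchor = c("body", "tss")) {
  gene_anchor <- match.arg(gene_anchor)
  ngdmrs <- as_intervals(ngdmrs, arg = "ngdmrs")
  genes <- as_intervals(genes, require = "gene_id", arg = "genes")
  tads <- as_intervals(tads, arg = "tads")
  if (anyDuplicated(genes$gene_id)) abort("`genes$gene_id` must be unique.")
  if ("genic" %in% names(ngdmrs) && any(as.logical(ngdmrs$genic))) {
    abort("`ngdmrs` contains genic DMRs; filter to non-genic DMRs first.")
  }
  if (max_distance <= 0) abort("`max_distance` must be positive.")
  empty <- tibble(dmr_id = character(), gene_id = character(),
                  tad_id = character(), distance = numeric(),
                  kind = character())
  if (nrow(ngdmrs) == 0 || nrow(genes) == 0 || nrow(tads) == 0) return(empty)

  ngdmrs$dmr_id <- if ("id" %in% names(ngdmrs)) as.character(ngdmrs$id) else
    sprintf("DMR_%05d", seq_len(nrow(ngdmrs)))
  tads$tad_id <- if ("id" %in% names(tads)) as.character(tads$id) else
    sprintf("TAD_%05d", seq_len(nrow(tads)))

  gene_iv <- genes
  if (gene_anchor == "tss") {
    # distances measured to the start coordinate; TAD membership still uses
    # the full gene body
    gene_iv$m_start <- genes$start
    gene_iv$m_end <- genes$start + 1
  } else {
    gene_iv$m_start <- genes$start
    gene_iv$m_end <- genes$end
  }

  dp <- interval_overlap_pairs(
    ngdmrs[c("chrom", "start", "end", "dmr_id")],
    tads[c("chrom", "start", "end", "tad_id")], suffix = c(".dmr", ".tad")
  )
  gp <- interval_overlap_pairs(
    gene_iv[c("chrom", "start", "end", "gene_id", "m_start", "m_end")],
    tads[c("chrom", "start", "end", "tad_id")], suffix = c(".gene", ".tad")
  )
  if (nrow(dp) == 0 || nrow(gp) == 0) return(empty)
  cand <- inner_join(
    select(dp, "dmr_id", "tad_id", dmr_start = "start.dmr", dmr_end = "end.dmr",
           tad_start = "start.tad", tad_end = "end.tad"),
    select(gp, "gene_id", "tad_id", gene_start = "m_start", gene_end = "m_end"),
    by = "tad_id", relationship = "many-to-many"
  )
  if (nrow(cand) == 0) return(empty)

  cand$linear <- pmax(0, pmax(cand$gene_start - cand$dmr_end,
                              cand$dmr_start - cand$gene_end))
  cand$spatial <- pmin(
    pmax(0, cand$dmr_start - cand$tad_start) + pmax(0, cand$tad_end - cand$gene_end),
    pmax(0, cand$tad_end - cand$dmr_end) + pmax(0, cand$gene_start - cand$tad_start)
  )
  cand$distance <- pmin(cand$linear, cand$spatial)
  cand$kind <- ifelse(cand$linear <= cand$spatial, "linear", "spatial")

  cand |>
    filter(.data$distance < max_distance) |>
    arrange(.data$dmr_id, .data$distance, .data$kind != "linear",
            .data$gene_id, .data$tad_id) |>
    group_by(.data$dmr_id) |>
    slice(1) |>
    ungroup() |>
    select("dmr_id", "gene_id", "tad_id", "distance", "kind")
}

#' Merge newly linked genes with a prior differentially methylated gene list
#'
#' @param new_links Link table from [link_dmrs_to_genes()].
#' @param prior_dmgs Character vector of previously identified DMG gene ids
#'   (deduplicated internally).
#'
#' @return An object of class `dmg_merge`: the combined unique gene table
#'   (`gene_id`, `source` one of `"prior"`, `"new"`, `"both"`) with the link
#'   table and summary counts attached. [glance()] reports `n_linked_dmrs`,
#'   `n_dmgs` (genes with a link), `n_new`, `n_already_present` and
#'   `n_combined`.
#' @export
merge_dmg_lists <- function(new_links, prior_dmgs = character()) {
  prior_dmgs <- unique(as.character(prior_dmgs))
  linked <- unique(new_links$gene_id)
  new_links$is_new_dmg <- !(new_links$gene_id %in% prior_dmgs)
  genes <- tibble(
    gene_id = union(prior_dmgs, linked),
    source = dplyr::case_when(
      union(prior_dmgs, linked) %in% prior_dmgs &
        union(prior_dmgs, linked) %in% linked ~ "both",
      union(prior_dmgs, linked) %in% linked ~ "new",
      TRUE ~ "prior"
    )
  ) |> arrange(.data$gene_id)
  structure(
    list(
      genes = genes, links = new_links,
      summary = list(
        n_linked_dmrs = length(unique(new_links$dmr_id)),
        n_dmgs = length(linked),
        n_new = sum(!(linked %in% prior_dmgs)),
        n_already_present = sum(linked %in% prior_dmgs),
        n_combined = nrow(genes)
      )
    ),
    class = "dmg_merge"
  )
}

#' @export
print.dmg_merge <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "DMG merge: %d linked DMRs -> %d genes (%d new, %d already present); %d combined DMGs\n",
    s$n_linked_dmrs, s$n_dmgs, s$n_new, s$n_already_present, s$n_combined
  ))
  invisible(x)
}
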