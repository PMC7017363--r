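#' Tidy a consensus TAD result
#'
#' @param x A `tad_consensus` object.
#' @param ... Unused.
#' @return The conserved-TAD tibble (one row per conserved TAD).
#' @method tidy tad_consensus
#' @export
tidy.tad_consensus <- function(x, ...) x$tads

#' One-row summary of a consensus TAD result
#'
#' @inheritParams tidy.tad_consensus
#' @return A one-row tibble: basis TAD count, tested and conserved counts,
#'   conserved fraction, dropped count, and the genome span of each boundary
#'   variant in bp.
#' @method glance tad_consensus
#' @export
glance.tad_consensus <- function(x, ...) {
  tibble(
    n_basis = nrow(x$scores),
    n_tested = sum(x$scores$tested),
    n_conserved = nrow(x$tads),
    frac_conserved = nrow(x$tads) / nrow(x$scores),
    n_dropped = x$n_dropped,
    span_intersection = sum(x$tads$int_end - x$tads$int_start),
    span_union = sum(x$tads$uni_end - x$tads$uni_start)
  )
}

#' Tidy a placement test: one row per simulation
#'
#' @param x A `placement_test` object.
#' @param ... Unused.
#' @return A tibble (`sim`, `stat`) of the null statistics.
#' @method tidy placement_test
#' @export
tidy.placement_test <- function(x, ...) {
  tibble(sim = seq_len(x$n_sims), stat = x$per_sim)
}

#' One-row summary of a placement test
#'
#' @inheritParams tidy.placement_test
#' @return A one-row tibble: statistic name, observed and expected values,
#'   simulation count, Monte Carlo p-value, chi-square statistic and p-value.
#' @method glance placement_test
#' @export
glance.placement_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, observed = x$observed, expected = x$expected,
    n_sims = x$n_sims, n_units = x$n_units,
    mc_p = x$mc_p, chi2 = x$chi2, chi2_p = x$chi2_p
  )
}

#' Tidy an organ enrichment result
#'
#' @param x An `organ_enrichment` object.
#' @param ... Unused.
#' @return The per-organ tibble.
#' @method tidy organ_enrichment
#' @export
tidy.organ_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "organ_enrichment")
  out
}

#' One-row summary of an organ enrichment result
#'
#' @inheritParams tidy.organ_enrichment
#' @return A one-row tibble: query and background sizes, organ count, number
#'   significant at FDR < 0.05, and the p-value method.
#' @method glance organ_enrichment
#' @export
glance.organ_enrichment <- function(x, ...) {
  tibble(
    n_query = attr(x, "n_query"),
    n_background = attr(x, "n_background"),
    n_organs = nrow(x),
    n_significant = sum(x$significant),
    method = attr(x, "method")
  )
}

#' Tidy a DMG merge result
#'
#' @param x A `dmg_merge` object.
#' @param ... Unused.
#' @return The combined gene tibble (`gene_id`, `source`).
#' @method tidy dmg_merge
#' @export
tidy.dmg_merge <- function(x, ...) x$genes

#' One-row summary of a DMG merge
#'
#' @inheritParams tidy.dmg_merge
#' @return A one-row tibble of the merge counts.
#' @method glance dmg_merge
#' @export
glance.dmg_merge <- function(x, ...) as_tibble(x$summary)
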