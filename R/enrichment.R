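#' Enrichment ratio
#'
#' Observed count over expected count, the headline statistic of a body-part
#' enrichment table.
#'
#' @param observed Non-negative observed count(s).
#' @param expected Positive expected count(s).
#' @return `observed / expected`.
#' @examples
#' enrichment_ratio(89, 67.656)
#' @export
enrichment_ratio <- function(observed, expected) {
  if (any(expected <= 0)) abort("`expected` must be positive.")
  observed / expected
}

#' Body-part enrichment of a gene list against a gene-to-organ table
#'
#' Tests whether a gene list (e.g. differentially methylated genes) is
#' enriched for genes annotated to each body part. The background is the set
#' of all genes in the annotation table; list genes absent from the background
#' are discarded with a message. Per organ, `expected` is
#' `|list| * |organ genes| / |background|`, and the one-sided enrichment
#' p-value is either empirical - the probability, over `n_draws` random gene
#' sets of size `|list|` drawn without replacement from the background, of an
#' organ count at least as large as observed, with the `(r + 1) / (n + 1)`
#' convention - or the exact hypergeometric tail. FDR is Benjamini-Hochberg
#' across all organs.
#'
#' @param dmgs Character vector of gene ids, or a data frame with a `gene_id`
#'   column.
#' @param annotations Data frame with columns `gene_id` and `organ`;
#'   duplicated pairs are collapsed with a warning.
#' @param n_draws Random gene sets for the empirical p-value (default 10000).
#' @param method `"permutation"` (empirical, default) or `"hypergeometric"`.
#' @param seed Integer seed (permutation method).
#'
#' @return An object of class `organ_enrichment`: a tibble with one row per
#'   organ (`organ`, `observed`, `expected`, `enrichment_ratio`, `p`, `fdr`,
#'   `significant` at FDR < 0.05, `depleted` flag), sorted by p then organ,
#'   with the test configuration attached as attributes. [tidy()] returns the
#'   rows; [autoplot()] draws the enrichment profile.
#' @export
organ_enrichment_test <- function(dmgs, annotations, n_draws = 10000,
                                  method = c("permutation", "hypergeometric"),
                                  seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(dmgs)) dmgs <- dmgs$gene_id
  dmgs <- unique(as.character(dmgs))
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "organ") %in% names(annotations))) {
    abort("`annotations` must have columns gene_id and organ.")
  }
  ann <- as_tibble(annotations)[c("gene_id", "organ")]
  ndup <- nrow(ann) - nrow(distinct(ann))
  if (ndup > 0) {
    warn(sprintf("%d duplicated (gene, organ) pair(s) collapsed.", ndup))
    ann <- distinct(ann)
  }
  background <- unique(ann$gene_id)
  in_bg <- dmgs %in% background
  if (!all(in_bg)) {
    inform(sprintf("%d gene(s) absent from the annotation background discarded.",
                   sum(!in_bg)))
    dmgs <- dmgs[in_bg]
  }
  if (length(dmgs) == 0) abort("No query gene is present in the annotation background.")

  organs <- sort(unique(ann$organ))
  N <- length(background)
  k <- length(dmgs)
  # gene x organ membership matrix
  M <- matrix(FALSE, nrow = N, ncol = length(organs),
              dimnames = list(background, organs))
  M[cbind(match(ann$gene_id, background), match(ann$organ, organs))] <- TRUE
  organ_sizes <- colSums(M)
  observed <- colSums(M[match(dmgs, background), , drop = FALSE])
  expected <- k * organ_sizes / N

  if (method == "permutation") {
    exceed <- withr::with_seed(seed, {
      e <- integer(length(organs))
      for (b in seq_len(n_draws)) {
        cnt <- colSums(M[sample.int(N, k), , drop = FALSE])
        e <- e + (cnt >= observed)
      }
      e
    })
    p <- (exceed + 1) / (n_draws + 1)
  } else {
    p <- phyper(observed - 1, organ_sizes, N - organ_sizes, k,
                lower.tail = FALSE)
  }

  out <- tibble(
    organ = organs,
    observed = as.integer(unname(observed)),
    expected = unname(expected),
    enrichment_ratio = unname(enrichment_ratio(observed, expected)),
    p = unname(p),
    fdr = fdr_adjust(unname(p))
  ) |>
    mutate(significant = .data$fdr < 0.05,
           depleted = .data$observed < .data$expected) |>
    arrange(.data$p, .data$organ)
  structure(out, class = c("organ_enrichment", class(out)),
            method = method, n_draws = if (method == "permutation") n_draws else NA,
            n_query = k, n_background = N, seed = seed)
}
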