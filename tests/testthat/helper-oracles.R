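# Independent brute-force oracles and tiny fixtures, written as plain loops
# so they share no code path with the package implementation.

iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

# scalar Jaccard by direct base-set arithmetic
oracle_jaccard <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  un <- (a$end - a$start) + (b$end - b$start) - ov
  if (un == 0) 0 else ov / un
}

# Eq.-1 style score: per other set the max Jaccard over an explicit loop,
# median via sort
oracle_conservation_score <- function(tad, others) {
  best <- vapply(others, function(set) {
    if (nrow(set) == 0) return(0)
    m <- 0
    for (j in seq_len(nrow(set))) {
      m <- max(m, oracle_jaccard(tad, set[j, ]))
    }
    m
  }, numeric(1))
  sort(best)[2]
}

# all-pairs DMR-gene linking by explicit triple loop, replicating the stated
# tie-break order (distance, linear before spatial, gene id, tad id)
oracle_links <- function(ngdmrs, genes, tads, max_distance = 50000) {
  rows <- list()
  for (i in seq_len(nrow(ngdmrs))) {
    d <- ngdmrs[i, ]
    cand <- list()
    for (t in seq_len(nrow(tads))) {
      tad <- tads[t, ]
      d_in <- d$chrom == tad$chrom &&
        min(d$end, tad$end) - max(d$start, tad$start) > 0
      if (!d_in) next
      for (g in seq_len(nrow(genes))) {
        gene <- genes[g, ]
        g_in <- gene$chrom == tad$chrom &&
          min(gene$end, tad$end) - max(gene$start, tad$start) > 0
        if (!g_in) next
        lin <- max(0, gene$start - d$end, d$start - gene$end)
        spa <- min(
          max(0, d$start - tad$start) + max(0, tad$end - gene$end),
          max(0, tad$end - d$end) + max(0, gene$start - tad$start)
        )
        dist <- min(lin, spa)
        if (dist < max_distance) {
          cand[[length(cand) + 1]] <- data.frame(
            dmr_id = d$id, gene_id = gene$gene_id, tad_id = tad$id,
            distance = dist,
            kind = if (lin <= spa) "linear" else "spatial"
          )
        }
      }
    }
    if (length(cand) > 0) {
      cand <- do.call(rbind, cand)
      ord <- order(cand$distance, cand$kind != "linear", cand$gene_id,
                   cand$tad_id)
      rows[[length(rows) + 1]] <- cand[ord[1], ]
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(dmr_id = character(), gene_id = character(),
                          tad_id = character(), distance = numeric(),
                          kind = character()))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out[order(out$dmr_id), ]
}

# genome built from literal strings, for composition examples
string_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# random interval set on chr1/chr2 for property tests (uses current RNG)
random_interval_set <- function(n, max_len = 1e5, genome_size = 1e6) {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- floor(runif(n, 0, genome_size - max_len))
  len <- floor(runif(n, 1, max_len))
  iv(chrom, start, start + len)
}
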