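#' GC fraction and CpG density of genomic intervals
#'
#' Computes, from the reference sequence, the fraction of G/C bases and the
#' density of CpG (CG) dinucleotides per bp of each interval. Ambiguous bases
#' count toward interval length but not toward either numerator; dinucleotides
#' straddling the interval edge are not counted.
#'
#' @param intervals Interval data frame (`chrom`, `start`, `end`).
#' @param genome A named [Biostrings::DNAStringSet] of chromosome sequences.
#'
#' @return `intervals` with columns `gc` and `cpg` added (overwritten if
#'   present).
#' @export
compute_gc_cpg <- function(intervals, genome) {
  intervals <- as_intervals(intervals, arg = "intervals")
  gc <- numeric(nrow(intervals))
  cpg <- numeric(nrow(intervals))
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Chromosome(s) absent from genome: %s.",
                  paste(missing_chrom, collapse = ", ")))
  }
  for (ch in unique(intervals$chrom)) {
    i <- which(intervals$chrom == ch)
    L <- length(genome[[ch]])
    if (any(intervals$end[i] > L)) {
      abort(sprintf("Interval(s) extend beyond the end of %s.", ch))
    }
    seqs <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = intervals$start[i] + 1, end = intervals$end[i])
    )
    w <- Biostrings::width(seqs)
    lf <- Biostrings::letterFrequency(seqs, letters = c("G", "C"))
    gc[i] <- rowSums(lf) / w
    cpg[i] <- Biostrings::vcountPattern("CG", seqs) / w
  }
  intervals$gc <- gc
  intervals$cpg <- cpg
  intervals
}

# cumulative GC-base and CG-dinucleotide counts per chromosome, so the
# composition of any interval is two O(1) lookups; built once per test call
composition_index <- function(genome) {
  lapply(setNames(names(genome), names(genome)), function(ch) {
    br <- charToRaw(as.character(genome[[ch]]))
    L <- length(br)
    is_c <- br == as.raw(0x43)
    is_g <- br == as.raw(0x47)
    cg <- if (L > 1) is_c[-L] & is_g[-1] else logical(0)
    list(
      gc = c(0, cumsum(is_c | is_g)),
      cg = c(0, cumsum(c(cg, FALSE))),
      length = L
    )
  })
}

# gc fraction and cpg density of 0-based half-open intervals via the index;
# identical to compute_gc_cpg() by construction (asserted in tests)
indexed_gc_cpg <- function(chrom, start, end, index) {
  n <- length(start)
  gc <- numeric(n)
  cpg <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ix <- index[[ch]]
    w <- end[i] - start[i]
    gc[i] <- (ix$gc[end[i] + 1] - ix$gc[start[i] + 1]) / w
    cpg[i] <- (ix$cg[end[i]] - ix$cg[start[i] + 1]) / w
  }
  list(gc = gc, cpg = cpg)
}

# genome-wide uniform draw of `k` start positions for intervals of length
# `len` (scalar): chromosome chosen with probability proportional to the
# number of admissible starts, then a uniform start.
draw_uniform_positions <- function(k, len, chrom_lengths) {
  nvalid <- pmax(chrom_lengths - len + 1, 0) # first arg keeps the names
  if (sum(nvalid) == 0) {
    abort(sprintf("Interval length %d exceeds every chromosome.", len))
  }
  ch <- sample(names(chrom_lengths), k, replace = TRUE, prob = nvalid)
  start <- floor(runif(k, 0, nvalid[ch]))
  tibble(chrom = ch, start = start, end = start + len)
}

# Batched rejection sampler: one composition-matched random interval per slot.
# `targets` has columns length, gc, cpg (one row per slot, slots may repeat a
# DMR across simulations). Tolerances relax by `relax_factor` for a slot after
# `max_tries` failed candidates. Returns tibble chrom/start/end + n_relaxed
# attribute. Uses the current RNG state (callers seed it).
matched_random_batch <- function(targets, genome, gc_tol = 0.05,
                                 cpg_tol = 0.005, max_tries = 1000,
                                 relax_factor = 2, batch = 8L, index = NULL) {
  n <- nrow(targets)
  if (is.null(index)) index <- composition_index(genome)
  chrom_lengths <- setNames(vapply(index, `[[`, numeric(1), "length"),
                            names(index))
  out <- tibble(chrom = rep(NA_character_, n), start = rep(NA_real_, n),
                end = rep(NA_real_, n))
  tol_mult <- rep(1, n)
  tries <- rep(0L, n)
  pending <- seq_len(n)
  n_relaxed <- 0L
  while (length(pending) > 0) {
    # draw `batch` candidates per pending slot, grouped by interval length
    slot <- rep(pending, each = batch)
    lens <- targets$length[slot]
    cand <- tibble(chrom = character(length(slot)), start = numeric(length(slot)),
                   end = numeric(length(slot)))
    for (len in unique(lens)) {
      j <- which(lens == len)
      d <- draw_uniform_positions(length(j), len, chrom_lengths)
      cand$chrom[j] <- d$chrom
      cand$start[j] <- d$start
      cand$end[j] <- d$end
    }
    comp <- indexed_gc_cpg(cand$chrom, cand$start, cand$end, index)
    ok <- abs(comp$gc - targets$gc[slot]) <= gc_tol * tol_mult[slot] &
      abs(comp$cpg - targets$cpg[slot]) <= cpg_tol * tol_mult[slot]
    # first accepted candidate per slot wins
    acc <- which(ok)
    acc <- acc[!duplicated(slot[acc])]
    if (length(acc) > 0) {
      s <- slot[acc]
      out$chrom[s] <- cand$chrom[acc]
      out$start[s] <- cand$start[acc]
      out$end[s] <- cand$end[acc]
    }
    done <- unique(slot[acc])
    pending <- setdiff(pending, done)
    tries[pending] <- tries[pending] + batch
    relax <- pending[tries[pending] >= max_tries]
    if (length(relax) > 0) {
      tol_mult[relax] <- tol_mult[relax] * relax_factor
      tries[relax] <- 0L
      n_relaxed <- n_relaxed + length(relax)
    }
  }
  attr(out, "n_relaxed") <- n_relaxed
  out
}

#' Composition-matched random interval
#'
#' Draws a uniform-random genome interval of the same length as `dmr` whose GC
#' fraction and CpG density fall within the stated absolute tolerances of the
#' DMR's values, by rejection sampling. If no candidate is accepted within
#' `max_tries` draws, the tolerances are doubled (`relax_factor`) with a
#' warning, until a draw succeeds.
#'
#' @param dmr One-row interval data frame; columns `gc` and `cpg` are used if
#'   present, otherwise computed from `genome`.
#' @inheritParams compute_gc_cpg
#' @param gc_tol,cpg_tol Absolute matching tolerances (default 0.05 GC
#'   fraction; 0.005 CpG per bp).
#' @param max_tries Candidates per relaxation round (default 1000).
#' @param relax_factor Tolerance multiplier applied after `max_tries`
#'   failures (default 2).
#' @param seed Integer seed.
#'
#' @return A one-row tibble (`chrom`, `start`, `end`, `gc`, `cpg`).
#' @export
matched_random_interval <- function(dmr, genome, gc_tol = 0.05,
                                    cpg_tol = 0.005, max_tries = 1000,
                                    relax_factor = 2, seed = 1L) {
  dmr <- as_intervals(dmr, arg = "dmr")
  if (nrow(dmr) != 1) abort("`dmr` must be a single interval (one row).")
  if (!all(c("gc", "cpg") %in% names(dmr))) dmr <- compute_gc_cpg(dmr, genome)
  targets <- tibble(length = dmr$end - dmr$start, gc = dmr$gc, cpg = dmr$cpg)
  res <- withr::with_seed(seed, matched_random_batch(
    targets, genome, gc_tol = gc_tol, cpg_tol = cpg_tol,
    max_tries = max_tries, relax_factor = relax_factor
  ))
  if (attr(res, "n_relaxed") > 0) {
    warn(sprintf("Matching tolerance relaxed %d time(s).", attr(res, "n_relaxed")))
  }
  compute_gc_cpg(res[c("chrom", "start", "end")], genome)
}

#' Fraction of DMRs at least partially inside TADs
#'
#' @param dmrs Interval data frame of DMRs.
#' @param tads Interval data frame of (consensus) TADs.
#' @return The fraction of DMRs with at least 1 bp of overlap with any TAD.
#' @export
inside_tad_fraction <- function(dmrs, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  if (nrow(dmrs) == 0) abort("`dmrs` must contain at least one interval.")
  mean(inside_flags(dmrs, tads))
}

inside_flags <- function(dmrs, tads) {
  dmrs$.row <- seq_len(nrow(dmrs))
  pairs <- interval_overlap_pairs(dmrs[c("chrom", "start", "end", ".row")],
                                  as_intervals(tads)[c("chrom", "start", "end")])
  seq_len(nrow(dmrs)) %in% pairs$.row
}

new_placement_test <- function(statistic, observed, per_sim, n_units,
                               counts_scale = FALSE, extra = list()) {
  n_sims <- length(per_sim)
  expected <- mean(per_sim)
  mc_p <- (sum(per_sim >= observed) + 1) / (n_sims + 1)
  # 2-cell goodness of fit on counts vs the simulation-mean expectation
  obs_count <- if (counts_scale) observed else observed * n_units
  exp_prop <- if (counts_scale) expected / n_units else expected
  if (exp_prop <= 0 || exp_prop >= 1) {
    warn("Degenerate simulation expectation; chi-square undefined.")
    chi2 <- NA_real_; chi2_p <- NA_real_
  } else {
    exp_counts <- c(exp_prop, 1 - exp_prop) * n_units
    obs_counts <- c(obs_count, n_units - obs_count)
    chi2 <- sum((obs_counts - exp_counts)^2 / exp_counts)
    chi2_p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    c(list(statistic = statistic, observed = observed, expected = expected,
           n_sims = n_sims, n_units = n_units, mc_p = mc_p,
           chi2 = chi2, chi2_p = chi2_p, per_sim = per_sim), extra),
    class = "placement_test"
  )
}

#' Monte Carlo test: do DMRs reside inside conserved TADs?
#'
#' The observed statistic is the fraction of DMRs overlapping any TAD by at
#' least 1 bp. Each simulation replaces every DMR by a composition-matched
#' random interval (same length; GC and CpG density within tolerance, see
#' [matched_random_interval()]) and recomputes the fraction. The Monte Carlo
#' p-value uses the `(r + 1) / (n + 1)` convention; a two-cell chi-square
#' goodness-of-fit compares the observed inside/outside counts with the
#' simulation-mean expectation (df = 1, no continuity correction).
#'
#' @param dmrs DMR interval data frame; `gc`/`cpg` columns are computed from
#'   `genome` when absent.
#' @inheritParams matched_random_interval
#' @param tads Interval data frame of consensus TADs (one boundary variant).
#' @param n_sims Number of simulations (default 200).
#'
#' @return A `placement_test` object; see [glance.placement_test()].
#' @export
inside_tad_test <- function(dmrs, tads, genome, n_sims = 200, gc_tol = 0.05,
                            cpg_tol = 0.005, max_tries = 1000,
                            relax_factor = 2, seed = 1L) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  if (nrow(dmrs) == 0) abort("`dmrs` must contain at least one interval.")
  if (n_sims < 100) abort("`n_sims` must be at least 100.")
  if (!all(c("gc", "cpg") %in% names(dmrs))) dmrs <- compute_gc_cpg(dmrs, genome)
  tads <- as_intervals(tads, arg = "tads")
  observed <- inside_tad_fraction(dmrs, tads)

  n <- nrow(dmrs)
  targets <- tibble(
    length = rep(dmrs$end - dmrs$start, times = n_sims),
    gc = rep(dmrs$gc, times = n_sims),
    cpg = rep(dmrs$cpg, times = n_sims)
  )
  rand <- withr::with_seed(seed, matched_random_batch(
    targets, genome, gc_tol = gc_tol, cpg_tol = cpg_tol,
    max_tries = max_tries, relax_factor = relax_factor
  ))
  n_relaxed <- attr(rand, "n_relaxed")
  if (n_relaxed > 0) {
    warn(sprintf("Matching tolerance relaxed for %d draw(s).", n_relaxed))
  }
  inside <- inside_flags(rand, tads)
  per_sim <- vapply(split(inside, rep(seq_len(n_sims), each = n)), mean,
                    numeric(1), USE.NAMES = FALSE)
  new_placement_test("fraction_inside_tads", observed, per_sim, n_units = n,
                     extra = list(n_relaxed = n_relaxed))
}

#' Distance from a DMR to the closest boundary of its TAD
#'
#' For paired DMR and TAD intervals, the distance from the DMR to the nearer
#' TAD boundary (anchor), clamped at 0 for a DMR crossing a boundary.
#'
#' @param dmrs,tads Interval data frames of equal row count, paired row-wise;
#'   each DMR must overlap its TAD.
#' @return Numeric vector of distances in bp.
#' @examples
#' boundary_distance(data.frame(chrom = "chr1", start = 10e3, end = 12e3),
#'                   data.frame(chrom = "chr1", start = 0, end = 1e6))
#' @export
boundary_distance <- function(dmrs, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  tads <- as_intervals(tads, arg = "tads")
  if (nrow(dmrs) != nrow(tads)) abort("`dmrs` and `tads` must pair row-wise.")
  ov <- overlap_length(dmrs$chrom, dmrs$start, dmrs$end,
                       tads$chrom, tads$start, tads$end)
  if (any(ov <= 0)) abort("Every DMR must overlap its paired TAD.")
  pmax(0, pmin(dmrs$start - tads$start, tads$end - dmrs$end))
}

# assign each DMR overlapping any TAD to the TAD with the largest overlap
# (ties: leftmost, then shortest TAD). Returns dmr rows + tad coords +
# boundary distance.
assign_containing_tad <- function(dmrs, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  tads <- as_intervals(tads, arg = "tads")
  dmrs$.row <- seq_len(nrow(dmrs))
  tads2 <- tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
                  tad_id = if ("id" %in% names(tads)) as.character(tads$id)
                  else sprintf("TAD_%05d", seq_len(nrow(tads))))
  pairs <- interval_overlap_pairs(dmrs[c("chrom", "start", "end", ".row")],
                                  tads2, suffix = c(".dmr", ".tad"))
  if (nrow(pairs) == 0) {
    return(tibble(.row = integer(), tad_id = character(),
                  tad_start = numeric(), tad_end = numeric()))
  }
  pairs |>
    arrange(.data$.row, dplyr::desc(.data$overlap), .data$start.tad,
            .data$end.tad - .data$start.tad) |>
    group_by(.data$.row) |>
    slice(1) |>
    ungroup() |>
    select(".row", "tad_id", tad_start = "start.tad", tad_end = "end.tad")
}

#' Per-DMR distances to the closest conserved TAD boundary
#'
#' Assigns every DMR that overlaps a TAD to the TAD with the largest overlap
#' (ties broken by leftmost TAD) and reports its distance to the closest
#' boundary. The output feeds boundary-distance histograms and
#' [boundary_proximity_test()].
#'
#' @inheritParams inside_tad_fraction
#' @return A tibble with one row per inside-TAD DMR: the DMR columns plus
#'   `tad_id`, `tad_start`, `tad_end`, `distance`.
#' @export
dmr_boundary_table <- function(dmrs, tads) {
  dmrs <- as_intervals(dmrs, arg = "dmrs")
  dmrs$.row <- seq_len(nrow(dmrs))
  asg <- assign_containing_tad(dmrs, tads)
  out <- inner_join(dmrs, asg, by = ".row")
  out$distance <- pmax(0, pmin(out$start - out$tad_start, out$tad_end - out$end))
  select(out, -".row")
}

#' Monte Carlo test: do inside-TAD DMRs sit near TAD boundaries?
#'
#' DMRs overlapping a TAD are assigned to their largest-overlap TAD; a DMR
#' within `proximal_cutoff` bp of the nearer boundary counts as proximal. The
#' observed statistic is the number of proximal DMRs. Each simulation
#' repositions every participating DMR uniformly at random fully within its
#' containing TAD (length preserved) and recounts, so the null conditions on
#' TAD membership and isolates boundary preference. Monte Carlo p-value and
#' two-cell chi-square as in [inside_tad_test()]. DMRs longer than their
#' containing TAD are excluded with a warning.
#'
#' @inheritParams inside_tad_fraction
#' @param n_sims Number of repositioning simulations (default 10000).
#' @param proximal_cutoff Proximity cut-off in bp (default 50 kb, inclusive).
#' @param seed Integer seed.
#'
#' @return A `placement_test` object (observed/expected on the count scale).
#' @export
boundary_proximity_test <- function(dmrs, tads, n_sims = 10000,
                                    proximal_cutoff = 50000, seed = 1L) {
  if (n_sims < 100) abort("`n_sims` must be at least 100.")
  bt <- dmr_boundary_table(dmrs, tads)
  if (nrow(bt) == 0) abort("No DMR overlaps any TAD.")
  too_long <- (bt$end - bt$start) > (bt$tad_end - bt$tad_start)
  if (any(too_long)) {
    warn(sprintf("%d DMR(s) longer than their containing TAD excluded.",
                 sum(too_long)))
    bt <- bt[!too_long, , drop = FALSE]
    if (nrow(bt) == 0) abort("No participating DMR left after exclusions.")
  }
  n <- nrow(bt)
  observed <- sum(bt$distance <= proximal_cutoff)
  len <- bt$end - bt$start
  span <- bt$tad_end - bt$tad_start - len # admissible start offsets, >= 0
  per_sim <- withr::with_seed(seed, {
    offs <- matrix(floor(runif(n_sims * n) * rep(span + 1, each = n_sims)),
                   nrow = n_sims)
    dist <- pmin(offs, matrix(rep(span, each = n_sims), nrow = n_sims) - offs)
    rowSums(dist <= proximal_cutoff)
  })
  new_placement_test("n_boundary_proximal", observed, per_sim, n_units = n,
                     counts_scale = TRUE,
                     extra = list(proximal_cutoff = proximal_cutoff,
                                  n_excluded = sum(too_long)))
}

#' @export
print.placement_test <- function(x, ...) {
  cat(sprintf("Placement test: %s\n", x$statistic))
  cat(sprintf("  observed %.4g, expected %.4g (mean of %d simulations)\n",
              x$observed, x$expected, x$n_sims))
  cat(sprintf("  Monte Carlo p = %.4g; chi-square = %.4g (df = 1), p = %.4g\n",
              x$mc_p, x$chi2, x$chi2_p))
  invisible(x)
}
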