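#' Conservation score of one TAD against three other cell types
#'
#' For a TAD of the basis cell type, the conservation score is the median,
#' over the three other cell types, of the maximum Jaccard overlap between the
#' TAD and any TAD of that cell type. A score of 1 means the TAD appears at
#' identical coordinates in all cell types; 0 means it overlaps no TAD in any
#' other cell type.
#'
#' @param tad A one-row data frame with columns `chrom`, `start`, `end`.
#' @param others A list of exactly three interval data frames, one per
#'   non-basis cell type.
#'
#' @return A list with `per_celltype_best` (named numeric of the three maxima),
#'   `score` (their median) and `best_matches` (tibble of the argmax TAD per
#'   cell type; `NA` coordinates where nothing overlaps).
#' @examples
#' tad <- data.frame(chrom = "chr1", start = 0, end = 1e5)
#' others <- list(
#'   B = data.frame(chrom = "chr1", start = 0, end = 1e5),
#'   C = data.frame(chrom = "chr1", start = 0, end = 5e4),
#'   D = data.frame(chrom = "chr2", start = 0, end = 1e5)
#' )
#' conservation_score(tad, others)$score # 0.5
#' @export
conservation_score <- function(tad, others) {
  tad <- as_intervals(tad, arg = "tad")
  if (nrow(tad) != 1) abort("`tad` must be a single interval (one row).")
  others <- check_three_sets(others)
  scored <- score_tads(tad, others)
  best <- tibble(
    celltype = names(others),
    chrom = tad$chrom,
    start = as.numeric(scored[1, paste0("match_start_", 1:3)]),
    end = as.numeric(scored[1, paste0("match_end_", 1:3)]),
    jaccard = as.numeric(scored[1, paste0("best_", 1:3)])
  )
  list(
    per_celltype_best = setNames(best$jaccard, best$celltype),
    score = scored$score[1],
    best_matches = best
  )
}

check_three_sets <- function(others) {
  if (!is.list(others) || is.data.frame(others) || length(others) != 3) {
    abort("`others` must be a list of exactly three interval data frames.")
  }
  if (is.null(names(others)) || any(names(others) == "")) {
    names(others) <- paste0("celltype_", seq_along(others))
  }
  others
}

# Vectorised scoring of all basis TADs against the three other sets.
# Returns one row per basis TAD with best_k, match_start_k, match_end_k for
# k = 1..3 and the median score. Ties in the argmax are broken by leftmost
# start, then shortest interval, for determinism.
score_tads <- function(basis, others) {
  basis <- as_intervals(basis, arg = "basis")
  basis$.i <- seq_len(nrow(basis))
  out <- tibble(.i = basis$.i)
  for (k in seq_along(others)) {
    other <- as_intervals(others[[k]], arg = sprintf("others[[%d]]", k))
    pairs <- interval_overlap_pairs(
      basis[c("chrom", "start", "end", ".i")], other[c("chrom", "start", "end")],
      suffix = c(".a", ".b")
    )
    if (nrow(pairs) > 0) {
      pairs$jaccard <- pairs$overlap /
        ((pairs$end.a - pairs$start.a) + (pairs$end.b - pairs$start.b) - pairs$overlap)
      best <- pairs |>
        arrange(.data$.i, dplyr::desc(.data$jaccard), .data$start.b,
                .data$end.b - .data$start.b) |>
        group_by(.data$.i) |>
        slice(1) |>
        ungroup() |>
        select(".i", best = "jaccard", match_start = "start.b", match_end = "end.b")
    } else {
      best <- tibble(.i = integer(), best = numeric(),
                     match_start = numeric(), match_end = numeric())
    }
    out <- left_join(out, best, by = ".i")
    out$best[is.na(out$best)] <- 0
    names(out)[names(out) %in% c("best", "match_start", "match_end")] <-
      paste0(c("best_", "match_start_", "match_end_"), k)
  }
  b <- as.matrix(out[paste0("best_", 1:3)])
  out$score <- unname(b[, 1] + b[, 2] + b[, 3] -
    pmax(b[, 1], b[, 2], b[, 3]) - pmin(b[, 1], b[, 2], b[, 3]))
  out$chrom <- basis$chrom
  out$start <- basis$start
  out$end <- basis$end
  out
}

# split each interval set by chromosome once, for fast repeated lookup
split_sets_by_chrom <- function(others) {
  lapply(others, function(s) {
    s <- as_intervals(s)
    split(s[c("start", "end")], s$chrom)
  })
}

# conservation scores of n same-length intervals with given starts on one
# chromosome, against pre-split other sets
null_scores <- function(chrom, starts, len, sets_by_chrom) {
  n <- length(starts)
  ends <- starts + len
  best <- matrix(0, nrow = n, ncol = 3)
  for (k in 1:3) {
    cand <- sets_by_chrom[[k]][[chrom]]
    if (is.null(cand) || nrow(cand) == 0) next
    ov <- pmax(0, outer(ends, cand$end, pmin) - outer(starts, cand$start, pmax))
    un <- len + matrix(rep(cand$end - cand$start, each = n), nrow = n) - ov
    j <- ov / un
    best[, k] <- do.call(pmax, as.data.frame(j))
  }
  best[, 1] + best[, 2] + best[, 3] -
    pmax(best[, 1], best[, 2], best[, 3]) - pmin(best[, 1], best[, 2], best[, 3])
}

#' Permutation p-value for one TAD's conservation score
#'
#' The observed TAD is replaced by `n` uniform-random intervals of the same
#' length on the same chromosome; each replacement is scored against the three
#' other cell types and the p-value is `(r + 1) / (n + 1)` where `r` is the
#' number of null scores at least as large as the observed score.
#'
#' @inheritParams conservation_score
#' @param chrom_sizes Named numeric vector or two-column data frame of
#'   chromosome lengths (bp).
#' @param n Number of permutations.
#' @param seed Integer seed for the random placements.
#'
#' @return A single p-value in `(0, 1]`.
#' @export
permutation_null <- function(tad, others, chrom_sizes, n = 1000, seed = 1L) {
  tad <- as_intervals(tad, arg = "tad")
  if (nrow(tad) != 1) abort("`tad` must be a single interval (one row).")
  others <- check_three_sets(others)
  permutation_pvalues(tad, others, chrom_sizes, n = n, seed = seed)$p[1]
}

#' Permutation p-values for a table of basis TADs
#'
#' Vectorised form of [permutation_null()]: every row of `basis` gets an
#' independent null of `n` same-length random intervals on its own chromosome.
#' Per-TAD seeds are derived from `seed` and the row index so results do not
#' depend on evaluation order.
#'
#' @param basis Interval data frame of basis-cell-type TADs.
#' @inheritParams permutation_null
#'
#' @return A tibble with the basis coordinates, `score` and `p`.
#' @export
permutation_pvalues <- function(basis, others, chrom_sizes, n = 1000, seed = 1L) {
  others <- check_three_sets(others)
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  scored <- score_tads(basis, others)
  missing_chrom <- setdiff(unique(scored$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Chromosome(s) absent from chrom_sizes: %s.",
                  paste(missing_chrom, collapse = ", ")))
  }
  sets <- split_sets_by_chrom(others)
  p <- vapply(seq_len(nrow(scored)), function(i) {
    len <- scored$end[i] - scored$start[i]
    L <- chrom_sizes[[scored$chrom[i]]]
    if (len > L) abort(sprintf("TAD %d longer than its chromosome.", i))
    withr::with_seed(derive_seed(seed, i), {
      starts <- floor(runif(n, min = 0, max = L - len + 1))
      ns <- null_scores(scored$chrom[i], starts, len, sets)
      (sum(ns >= scored$score[i]) + 1) / (n + 1)
    })
  }, numeric(1))
  tibble(chrom = scored$chrom, start = scored$start, end = scored$end,
         score = scored$score, p = p)
}

# per-task seed derived from (seed, index), kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Order-preserving wrapper around the step-up false discovery rate
#' adjustment.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return q-values of the same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) abort("`p` must contain at least one p-value.")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) abort("p-values must be in (0, 1].")
  p.adjust(p, method = "BH")
}

#' Call consensus TADs conserved across four cell types
#'
#' Each basis-cell-type TAD is scored against the three other cell types
#' (median of per-cell-type maximum Jaccard overlaps). TADs of at least
#' `min_length` bp with score strictly above `score_threshold` enter a
#' permutation test (random same-length intervals on the same chromosome);
#' Benjamini-Hochberg q-values are computed over the tested set and TADs with
#' `q < q_threshold` are reported as conserved. For every conserved TAD two
#' boundary variants are built from the basis TAD and its three best-match
#' TADs: the intersection (shared section) and the union (full span). TADs
#' whose four intervals share no common section are dropped with a warning.
#'
#' @param basis Interval data frame of TADs for the basis cell type
#'   (conventionally the cell type with the most TAD calls). An optional `id`
#'   column is carried through.
#' @inheritParams permutation_pvalues
#' @param min_length Minimum TAD length in bp (default 100 kb).
#' @param score_threshold Conservation-score cut-off, strict `>` (default 0.5).
#' @param q_threshold FDR cut-off on the permutation q-value (default 0.05).
#' @param n_permutations Permutations per tested TAD (default 1000).
#'
#' @return An object of class `tad_consensus`: a list with `tads` (tibble of
#'   conserved TADs: `id`, `chrom`, `src_start`, `src_end`, `int_start`,
#'   `int_end`, `uni_start`, `uni_end`, `score`, `p`, `q`), `scores` (tibble of
#'   all basis TADs with their score and, where tested, `p` and `q`), `config`,
#'   and `n_dropped` (conserved TADs dropped for an empty intersection).
#'   Use [tidy()] for the conserved table, [glance()] for a one-row summary
#'   and [consensus_variant()] to extract one boundary variant as intervals.
#' @export
call_consensus_tads <- function(basis, others, chrom_sizes,
                                min_length = 1e5, score_threshold = 0.5,
                                q_threshold = 0.05, n_permutations = 1000,
                                seed = 1L) {
  basis <- as_intervals(basis, arg = "basis")
  if (nrow(basis) == 0) abort("`basis` must contain at least one TAD.")
  others <- check_three_sets(others)
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (n_permutations < 100) abort("`n_permutations` must be at least 100.")
  n_other_max <- max(vapply(others, nrow, integer(1)))
  if (nrow(basis) < n_other_max) {
    warn("`basis` has fewer TADs than another cell type; the basis is conventionally the cell type with the most TADs.")
  }

  scored <- score_tads(basis, others)
  scored$id <- if ("id" %in% names(basis)) as.character(basis$id) else
    sprintf("TAD_%05d", seq_len(nrow(basis)))
  scored$length <- scored$end - scored$start
  scored$tested <- scored$length >= min_length & scored$score > score_threshold

  scores_out <- tibble(
    id = scored$id, chrom = scored$chrom, start = scored$start,
    end = scored$end, length = scored$length, score = scored$score,
    tested = scored$tested, p = NA_real_, q = NA_real_
  )

  if (any(scored$tested)) {
    idx <- which(scored$tested)
    sets <- split_sets_by_chrom(others)
    p <- vapply(idx, function(i) {
      len <- scored$length[i]
      L <- chrom_sizes[[scored$chrom[i]]]
      withr::with_seed(derive_seed(seed, i), {
        starts <- floor(runif(n_permutations, min = 0, max = L - len + 1))
        ns <- null_scores(scored$chrom[i], starts, len, sets)
        (sum(ns >= scored$score[i]) + 1) / (n_permutations + 1)
      })
    }, numeric(1))
    scores_out$p[idx] <- p
    scores_out$q[idx] <- fdr_adjust(p)
  }

  keep <- which(scores_out$tested & scores_out$q < q_threshold)
  ms <- as.matrix(scored[paste0("match_start_", 1:3)])
  me <- as.matrix(scored[paste0("match_end_", 1:3)])
  tads <- list()
  n_dropped <- 0L
  for (i in keep) {
    starts4 <- c(scored$start[i], ms[i, ])
    ends4 <- c(scored$end[i], me[i, ])
    if (anyNA(starts4)) { # a cell type with zero overlap: no shared section
      n_dropped <- n_dropped + 1L
      next
    }
    int_s <- max(starts4); int_e <- min(ends4)
    if (int_e <= int_s) {
      n_dropped <- n_dropped + 1L
      next
    }
    tads[[length(tads) + 1]] <- tibble(
      id = scored$id[i], chrom = scored$chrom[i],
      src_start = scored$start[i], src_end = scored$end[i],
      int_start = int_s, int_end = int_e,
      uni_start = min(starts4), uni_end = max(ends4),
      score = scored$score[i], p = scores_out$p[i], q = scores_out$q[i]
    )
  }
  if (n_dropped > 0) {
    warn(sprintf("%d conserved TAD(s) dropped: best matches share no common section.",
                 n_dropped))
  }
  tads <- if (length(tads) > 0) list_rbind(tads) else tibble(
    id = character(), chrom = character(), src_start = numeric(),
    src_end = numeric(), int_start = numeric(), int_end = numeric(),
    uni_start = numeric(), uni_end = numeric(), score = numeric(),
    p = numeric(), q = numeric()
  )

  structure(
    list(
      tads = tads, scores = scores_out,
      config = list(min_length = min_length, score_threshold = score_threshold,
                    q_threshold = q_threshold, n_permutations = n_permutations,
                    seed = seed, chrom_sizes = chrom_sizes),
      n_dropped = n_dropped
    ),
    class = "tad_consensus"
  )
}

#' Extract one boundary variant of a consensus TAD set
#'
#' @param x A `tad_consensus` object (or its tidied tibble).
#' @param variant `"intersection"` (shared section) or `"union"` (full span).
#' @return An interval tibble (`chrom`, `start`, `end`, `id`, `score`, `q`).
#' @export
consensus_variant <- function(x, variant = c("intersection", "union")) {
  variant <- match.arg(variant)
  tads <- if (inherits(x, "tad_consensus")) x$tads else as_tibble(x)
  pre <- if (variant == "intersection") "int_" else "uni_"
  tibble(
    chrom = tads$chrom,
    start = tads[[paste0(pre, "start")]],
    end = tads[[paste0(pre, "end")]],
    id = tads$id, score = tads$score, q = tads$q
  )
}

#' Intersection variant of a conserved TAD
#'
#' The shared section of the basis TAD and its three best-match TADs:
#' `[max(starts), min(ends))`.
#'
#' @param tad One-row data frame: the basis TAD.
#' @param best_matches Data frame of the three best-match intervals.
#' @return A one-row tibble, or `NULL` when the four intervals share no
#'   common section (with a warning).
#' @export
build_intersection_tad <- function(tad, best_matches) {
  tad <- as_intervals(tad, arg = "tad")
  bm <- as_intervals(best_matches, arg = "best_matches")
  s <- max(c(tad$start, bm$start)); e <- min(c(tad$end, bm$end))
  if (e <= s) {
    warn("Empty intersection: the matched TADs share no common section.")
    return(NULL)
  }
  tibble(chrom = tad$chrom[1], start = s, end = e)
}

#' Union variant of a conserved TAD
#'
#' The full span of the basis TAD and its three best-match TADs:
#' `[min(starts), max(ends))`.
#'
#' @inheritParams build_intersection_tad
#' @return A one-row tibble.
#' @export
build_union_tad <- function(tad, best_matches) {
  tad <- as_intervals(tad, arg = "tad")
  bm <- as_intervals(best_matches, arg = "best_matches")
  tibble(chrom = tad$chrom[1],
         start = min(c(tad$start, bm$start)),
         end = max(c(tad$end, bm$end)))
}

#' @export
print.tad_consensus <- function(x, ...) {
  cat(sprintf(
    "Consensus TADs: %d conserved of %d basis TADs (%d tested at S > %g; q < %g)\n",
    nrow(x$tads), nrow(x$scores), sum(x$scores$tested),
    x$config$score_threshold, x$config$q_threshold
  ))
  if (x$n_dropped > 0) cat(sprintf("  %d dropped (empty intersection)\n", x$n_dropped))
  print(x$tads, ...)
  invisible(x)
}
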