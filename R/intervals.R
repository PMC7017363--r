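#' Validate a table of genomic intervals
#'
#' Intervals are represented throughout the package as data frames with at
#' least the columns `chrom` (character), `start` and `end` (integer-valued,
#' 0-based half-open, BED convention). 1-based inputs must be converted at the
#' I/O layer. Every interval must have positive length.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param require Additional column names that must be present.
#' @param arg Name used in error messages.
#'
#' @return `x` as a tibble, invisibly validated (errors on violation).
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
as_intervals <- function(x, require = character(), arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end", require), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(sprintf("`%s`: start/end must be numeric (bp).", arg))
  }
  bad <- which(!(x$end > x$start) | x$start < 0 |
                 !is.finite(x$start) | !is.finite(x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s`: %d invalid interval(s) (need 0 <= start < end), first at row %d (%s:%s-%s).",
      arg, length(bad), bad[1],
      x$chrom[bad[1]], format(x$start[bad[1]]), format(x$end[bad[1]])
    ))
  }
  x
}

#' Interval length in base pairs
#'
#' @param start,end Vectors of 0-based half-open coordinates.
#' @return `end - start`, a non-negative numeric vector.
#' @examples
#' interval_length(0, 100)
#' @export
interval_length <- function(start, end) {
  end - start
}

#' Overlap length of two intervals
#'
#' Vectorised over paired intervals. Intervals on different chromosomes do not
#' overlap.
#'
#' @param chrom1,start1,end1 First interval(s).
#' @param chrom2,start2,end2 Second interval(s).
#' @return Non-negative overlap in bp.
#' @examples
#' overlap_length("chr1", 0, 100, "chr1", 50, 150)
#' @export
overlap_length <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  ov[chrom1 != chrom2] <- 0
  ov
}

#' Jaccard overlap of two intervals
#'
#' Intersection length divided by union length, where the union of two
#' intervals is taken as a set of bases: `len(a) + len(b) - overlap`. For
#' disjoint same-chromosome intervals the union does not include the gap, and
#' the Jaccard value is 0. Vectorised over paired intervals.
#'
#' @inheritParams overlap_length
#' @return Values in `[0, 1]`; 1 iff the intervals are identical.
#' @examples
#' interval_jaccard("chr1", 0, 100, "chr1", 50, 150) # 50 / 150
#' @export
interval_jaccard <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ov <- overlap_length(chrom1, start1, end1, chrom2, start2, end2)
  un <- (end1 - start1) + (end2 - start2) - ov
  ifelse(un > 0, ov / un, 0)
}

# overlap join of two interval tables; returns pairs with >= 1 bp overlap and
# the overlap width. Suffixes disambiguate shared column names.
interval_overlap_pairs <- function(a, b, suffix = c(".a", ".b")) {
  a <- as_intervals(a, arg = "a")
  b <- as_intervals(b, arg = "b")
  pairs <- inner_join(a, b, by = "chrom", suffix = suffix,
                      relationship = "many-to-many")
  s1 <- pairs[[paste0("start", suffix[1])]]
  e1 <- pairs[[paste0("end", suffix[1])]]
  s2 <- pairs[[paste0("start", suffix[2])]]
  e2 <- pairs[[paste0("end", suffix[2])]]
  pairs$overlap <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pairs[pairs$overlap > 0, , drop = FALSE]
}

# normalise chrom sizes input (named numeric vector or two-column data frame)
# to a named numeric vector
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    if (ncol(chrom_sizes) < 2) abort("`chrom_sizes` needs columns chrom, size.")
    out <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    out <- chrom_sizes
  } else {
    abort("`chrom_sizes` must be a named numeric vector or a two-column data frame.")
  }
  if (any(out <= 0) || anyNA(out)) abort("Chromosome sizes must be positive.")
  out
}
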