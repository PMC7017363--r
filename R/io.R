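#' Read a BED-like interval file
#'
#' Reads tab-separated BED (0-based half-open) into an interval tibble.
#' Track/browser/comment lines are skipped; malformed lines raise
#' line-numbered errors. Column 4, when present, is taken as the feature id;
#' further columns can be named through `extra_cols`.
#'
#' @param path File path.
#' @param min_columns Minimum number of columns required (default 3).
#' @param extra_cols Names for columns beyond the fourth (id), in order.
#' @param add_chr_prefix If `TRUE`, prefix bare chromosome names with
#'   `"chr"`. Chromosome names are otherwise compared as exact strings.
#'
#' @return An interval tibble (`chrom`, `start`, `end`, and optionally `id`
#'   plus `extra_cols`). An empty file yields an empty tibble with a warning.
#' @export
read_bed <- function(path, min_columns = 3, extra_cols = NULL,
                     add_chr_prefix = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    warn(sprintf("Empty BED file: %s", path))
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_columns)) {
    i <- which(ncols < min_columns)[1]
    abort(sprintf("%s line %d: %d column(s), need >= %d.",
                  path, lineno[i], ncols[i], min_columns))
  }
  get_col <- function(j) vapply(fields, function(f)
    if (length(f) >= j) f[j] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: non-integer coordinates.", path, lineno[bad[1]]))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval %s:%s-%s (need 0 <= start < end).",
                  path, lineno[bad[1]], get_col(1)[bad[1]],
                  get_col(2)[bad[1]], get_col(3)[bad[1]]))
  }
  out <- tibble(chrom = get_col(1), start = start, end = end)
  if (add_chr_prefix) {
    out$chrom <- ifelse(grepl("^chr", out$chrom), out$chrom,
                        paste0("chr", out$chrom))
  }
  if (max(ncols) >= 4) out$id <- get_col(4)
  if (!is.null(extra_cols)) {
    for (j in seq_along(extra_cols)) {
      out[[extra_cols[j]]] <- get_col(4 + j)
    }
  }
  out
}

#' Write an interval tibble as BED
#'
#' @param x Interval data frame; `id` (or the column named first in `extra`)
#'   becomes column 4.
#' @param path Output path.
#' @param extra Names of columns to write after `chrom`/`start`/`end`
#'   (default: `id` if present).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = intersect("id", names(x))) {
  x <- as_intervals(x, require = extra)
  cols <- x[c("chrom", "start", "end", extra)]
  if ("genic" %in% names(cols)) cols$genic <- as.integer(cols$genic)
  cols$start <- format(cols$start, scientific = FALSE, trim = TRUE)
  cols$end <- format(cols$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(cols, path, col_names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with chromosome name and length, no header.
#' @return A tibble (`chrom`, `size`).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = "cd", progress = FALSE)
  as_chrom_sizes(x) # validates
  x
}

#' Read a genome FASTA
#'
#' @param path FASTA path; sequence names are truncated at the first
#'   whitespace.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a DMR BED with composition and genic-flag columns
#'
#' Expects BED columns `chrom`, `start`, `end`, `id`, `gc`, `cpg`, `genic`
#' (the format written by [simulate_dataset()]). Missing `gc`/`cpg` can be
#' recomputed with [compute_gc_cpg()].
#'
#' @inheritParams read_bed
#' @return A DMR tibble.
#' @export
read_dmr_bed <- function(path, add_chr_prefix = FALSE) {
  x <- read_bed(path, min_columns = 4, extra_cols = c("gc", "cpg", "genic"),
                add_chr_prefix = add_chr_prefix)
  if (nrow(x) == 0) return(x)
  x$gc <- as.numeric(x$gc)
  x$cpg <- as.numeric(x$cpg)
  x$genic <- as.logical(as.integer(x$genic))
  x
}

#' Read a gene BED (name column = gene id)
#'
#' @inheritParams read_bed
#' @return A gene tibble (`chrom`, `start`, `end`, `gene_id`).
#' @export
read_gene_bed <- function(path, add_chr_prefix = FALSE) {
  x <- read_bed(path, min_columns = 4, add_chr_prefix = add_chr_prefix)
  dplyr::rename(x, gene_id = "id")
}

#' Read a gene-to-organ annotation table
#'
#' @param path TSV with header columns `gene_id` and `organ`.
#' @return A tibble (`gene_id`, `organ`).
#' @export
read_organ_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("gene_id", "organ") %in% names(x))) {
    abort(sprintf("%s must have header columns gene_id and organ.", path))
  }
  x[c("gene_id", "organ")]
}
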