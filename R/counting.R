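#' Assign mapped reads to restriction fragments
#'
#' Credits each read to the fragment containing its 5' position (the `start`
#' for `+` reads, `end - 1` for `-` reads): 4C reads begin at restriction
#' sites, so the 5' end identifies the ligated fragment. Reads on chromosomes
#' absent from the map, or falling outside the tiled span, are tallied as
#' discarded; malformed reads (`start >= end`) are tallied as rejected with a
#' warning. Read order never affects the result.
#'
#' @param reads A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"`/`"-"`), or a path to a BED file.
#' @param fragments A `fourc_fragments` tibble from [digest_genome()].
#'
#' @return A `fourc_counts` tibble: the fragment table plus a `count` column,
#'   with attributes `total_reads` (assigned), `n_discarded`, `n_rejected`
#'   and `n_input`.
#' @export
assign_reads <- function(reads, fragments) {
  if (is.character(reads) && length(reads) == 1) reads <- read_bed(reads)
  reads <- as_tibble(reads)
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (is.null(reads$strand)) reads$strand <- "+"

  bad <- reads$start >= reads$end
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warn(sprintf("%d read(s) with start >= end rejected.", n_rejected))
    reads <- reads[!bad, , drop = FALSE]
  }

  pos5 <- ifelse(reads$strand == "-", reads$end - 1, reads$start)
  counts <- numeric(nrow(fragments))
  n_discarded <- 0L
  for (ch in unique(reads$chrom)) {
    in_ch <- reads$chrom == ch
    frag_idx <- which(fragments$chrom == ch)
    if (length(frag_idx) == 0) {
      n_discarded <- n_discarded + sum(in_ch)
      next
    }
    starts <- fragments$start[frag_idx]
    chrom_end <- fragments$end[frag_idx[length(frag_idx)]]
    p <- pos5[in_ch]
    inside <- p >= starts[1] & p < chrom_end
    n_discarded <- n_discarded + sum(!inside)
    hit <- findInterval(p[inside], starts)
    tab <- tabulate(hit, nbins = length(frag_idx))
    counts[frag_idx] <- counts[frag_idx] + tab
  }

  new_fourc_counts(fragments, counts,
                   n_discarded = n_discarded, n_rejected = n_rejected,
                   n_input = n_rejected + length(pos5))
}

new_fourc_counts <- function(fragments, counts, n_discarded = 0L,
                             n_rejected = 0L, n_input = sum(counts)) {
  stopifnot(length(counts) == nrow(fragments), all(counts >= 0))
  x <- as_tibble(fragments)
  x$count <- as.numeric(counts)
  attr(x, "enzymes") <- attr(fragments, "enzymes")
  attr(x, "genome_id") <- attr(fragments, "genome_id")
  attr(x, "total_reads") <- sum(counts)
  attr(x, "n_discarded") <- as.integer(n_discarded)
  attr(x, "n_rejected") <- as.integer(n_rejected)
  attr(x, "n_input") <- as.integer(n_input)
  class(x) <- unique(c("fourc_counts", class(x)))
  x
}

#' Load precomputed per-fragment counts
#'
#' Aligns a `(chrom, start, end, count)` table to a fragment map by exact
#' interval match. Fragments absent from the table get a count of 0; a table
#' row whose interval is not in the map is a hard error naming the row.
#'
#' @param table A data frame with columns `chrom`, `start`, `end`, `count`,
#'   or a path to a tab-delimited file with those columns.
#' @param fragments A `fourc_fragments` tibble.
#' @return A `fourc_counts` tibble (see [assign_reads()]).
#' @export
load_counts <- function(table, fragments) {
  if (is.character(table) && length(table) == 1) {
    table <- readr::read_tsv(table, show_col_types = FALSE)
  }
  table <- as_tibble(table)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(table)))
  if (any(table$count < 0)) {
    abort(sprintf("negative count in row %d.", which(table$count < 0)[1]))
  }
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  idx <- match(key(table), key(fragments))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf(
      "row %d (%s:%s-%s) does not match any fragment in the map.",
      bad, table$chrom[bad], table$start[bad], table$end[bad]))
  }
  counts <- numeric(nrow(fragments))
  counts[idx] <- table$count
  new_fourc_counts(fragments, counts)
}
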