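#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition motif and its role in
#' the double digestion: the primary enzyme defines the viewpoint-containing
#' fragment ends, the secondary enzyme trims the circles before inverse PCR.
#' The classic 4C pair is DpnII (`GATC`, primary) and Csp6I (`GTAC`,
#' secondary), both 4-bp cutters.
#'
#' @param name Short identifier, e.g. `"DpnII"`.
#' @param motif Recognition motif over `{A,C,G,T}`, length >= 4.
#' @param role One of `"primary"` or `"secondary"`.
#' @param cut_offset Offset of the cut position from the motif start, in bp.
#'   Fragment boundaries are placed at `motif_start + cut_offset`. The default
#'   0 puts every boundary at a motif start; downstream results depend only on
#'   the boundaries, not on this convention.
#'
#' @return An object of class `fourc_enzyme`.
#' @examples
#' enzyme_dpnii()
#' fourc_enzyme("Csp6I", "GTAC", "secondary")
#' @export
fourc_enzyme <- function(name, motif, role = c("primary", "secondary"),
                         cut_offset = 0L) {
  role <- match.arg(role)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    abort("`motif` must be a non-empty string over {A,C,G,T}.")
  }
  if (nchar(motif) < 4) {
    abort("`motif` must be at least 4 bp (4C uses 4-bp cutters).")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset >= nchar(motif)) {
    abort("`cut_offset` must lie within the motif.")
  }
  structure(
    list(name = name, motif = motif, role = role, cut_offset = cut_offset),
    class = "fourc_enzyme"
  )
}

#' @rdname fourc_enzyme
#' @export
enzyme_dpnii <- function() fourc_enzyme("DpnII", "GATC", "primary")

#' @rdname fourc_enzyme
#' @export
enzyme_csp6i <- function() fourc_enzyme("Csp6I", "GTAC", "secondary")

#' @export
print.fourc_enzyme <- function(x, ...) {
  cat(sprintf("<fourc_enzyme> %s (%s, %s enzyme, cut offset %d)\n",
              x$name, x$motif, x$role, x$cut_offset))
  invisible(x)
}

#' Locate restriction cut sites in a sequence
#'
#' Scans one DNA sequence for all (possibly overlapping) occurrences of the
#' enzyme motif and returns the 0-based cut positions
#' (`motif start + cut_offset`). Motifs never match across `N` bases.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}` (character or
#'   [Biostrings::DNAString]).
#' @param enzyme A [fourc_enzyme()].
#'
#' @return Strictly increasing integer vector of 0-based cut positions; empty
#'   when the sequence is empty or shorter than the motif.
#' @examples
#' find_cut_sites("AAGATCAA", enzyme_dpnii())
#' @export
find_cut_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "fourc_enzyme"))
  if (inherits(sequence, "DNAString")) {
    subject <- sequence
  } else {
    sequence <- as.character(sequence)
    if (length(sequence) != 1) abort("`sequence` must be a single string.")
    if (!nzchar(sequence)) return(integer(0))
    subject <- Biostrings::DNAString(toupper(sequence))
  }
  if (length(subject) < nchar(enzyme$motif)) return(integer(0))
  hits <- Biostrings::matchPattern(enzyme$motif, subject, fixed = TRUE)
  sort(BiocGenerics::start(hits) - 1L + enzyme$cut_offset)
}
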