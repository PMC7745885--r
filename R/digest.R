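#' In-silico double digestion of a genome
#'
#' Cuts every chromosome at each occurrence of the primary and secondary
#' enzyme motifs and returns the resulting restriction fragments, classified
#' by their flanking sites. Fragments flanked by a primary and a secondary
#' site (in either order) are `valid` 4C fragments; fragments flanked by two
#' sites of the same enzyme are `blind_primary` / `blind_secondary`
#' (uninformative in 4C and filtered downstream); fragments touching a
#' chromosome end are `terminal`.
#'
#' Coordinates are 0-based half-open throughout. Fragments tile each
#' chromosome exactly: sorted, non-overlapping, no gaps.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param primary,secondary [fourc_enzyme()] objects with the matching roles.
#' @param genome_id Label recorded on the result; defaults to the FASTA file
#'   name or `"genome"`.
#'
#' @return A `fourc_fragments` tibble with columns `chrom`, `start`, `end`,
#'   `length`, `midpoint`, `left_flank`, `right_flank` (`"primary"`,
#'   `"secondary"` or `"end"`) and `frag_class` (`"valid"`, `"blind_primary"`,
#'   `"blind_secondary"`, `"terminal"`), plus attributes `enzymes` and
#'   `genome_id`.
#' @examples
#' digest_genome(c(chrA = "AAGATCAAAAAAGTACAAAAGATCAA"),
#'               enzyme_dpnii(), enzyme_csp6i())
#' @export
digest_genome <- function(genome, primary = enzyme_dpnii(),
                          secondary = enzyme_csp6i(), genome_id = NULL) {
  stopifnot(inherits(primary, "fourc_enzyme"),
            inherits(secondary, "fourc_enzyme"))
  if (primary$role != "primary" || secondary$role != "secondary") {
    abort("Need exactly one primary and one secondary enzyme.")
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      is.null(names(genome))) {
    if (is.null(genome_id)) genome_id <- basename(genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      abort("character `genome` must be named by chromosome.")
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!inherits(genome, "DNAStringSet")) {
    abort("`genome` must be a named character vector, DNAStringSet or FASTA path.")
  }
  if (length(genome) == 0) abort("`genome` is empty.")
  genome_id <- genome_id %||% "genome"

  per_chrom <- purrr::map2(as.character(names(genome)), seq_along(genome),
    function(chrom, i) {
      seq_i <- genome[[i]]
      len <- length(seq_i)
      if (len == 0) abort(sprintf("chromosome '%s' has zero length.", chrom))
      cuts_p <- find_cut_sites(seq_i, primary)
      cuts_s <- find_cut_sites(seq_i, secondary)
      # a coinciding primary/secondary cut (possible only with nonzero cut
      # offsets) is labelled primary
      role_of <- c(setNames(rep("secondary", length(cuts_s)), cuts_s),
                   setNames(rep("primary", length(cuts_p)), cuts_p))
      cuts <- sort(unique(c(cuts_p, cuts_s)))
      inner <- cuts[cuts > 0 & cuts < len]
      bounds <- c(0, inner, len)
      starts <- bounds[-length(bounds)]
      ends <- bounds[-1]
      flank_label <- function(pos, boundary_is_cut) {
        ifelse(boundary_is_cut, unname(role_of[as.character(pos)]), "end")
      }
      left <- flank_label(starts, starts %in% cuts)
      right <- flank_label(ends, ends %in% cuts)
      tibble(chrom = chrom, start = starts, end = ends,
             left_flank = left, right_flank = right)
    })

  frags <- bind_rows(per_chrom) |>
    mutate(
      length = .data$end - .data$start,
      midpoint = floor((.data$start + .data$end) / 2),
      frag_class = classify_fragment(.data$left_flank, .data$right_flank)
    ) |>
    select("chrom", "start", "end", "length", "midpoint",
           "left_flank", "right_flank", "frag_class")

  new_fourc_fragments(frags,
                      enzymes = list(primary = primary, secondary = secondary),
                      genome_id = genome_id)
}

classify_fragment <- function(left, right) {
  dplyr::case_when(
    left == "end" | right == "end" ~ "terminal",
    left == "primary" & right == "primary" ~ "blind_primary",
    left == "secondary" & right == "secondary" ~ "blind_secondary",
    TRUE ~ "valid"
  )
}

new_fourc_fragments <- function(x, enzymes, genome_id) {
  x <- as_tibble(x)
  attr(x, "enzymes") <- enzymes
  attr(x, "genome_id") <- genome_id
  class(x) <- c("fourc_fragments", class(x))
  x
}

#' Fragment midpoints
#'
#' The midpoint `floor((start + end) / 2)` is the coordinate at which a
#' fragment's signal is placed in the viewpoint profile.
#'
#' @param fragments A `fourc_fragments` tibble (or any tibble with `start`
#'   and `end`).
#' @return Numeric vector of midpoints, one per fragment.
#' @export
fragment_midpoints <- function(fragments) {
  stopifnot(all(c("start", "end") %in% names(fragments)))
  floor((fragments$start + fragments$end) / 2)
}
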