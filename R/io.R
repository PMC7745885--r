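#' Read a BED file into a tibble
#'
#' Reads BED3/BED6 (0-based half-open, tab-delimited, optional `track`/`#`
#' header lines) into a tibble with columns `chrom`, `start`, `end` and,
#' when present, `name`, `score`, `strand`.
#'
#' @param path Path to a BED file.
#' @return A tibble.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  x <- x[!grepl("^(track|browser)", x[[1]]), , drop = FALSE]
  names(x) <- cols[seq_len(ncol(x))]
  as_tibble(x)
}

write_tsv_plain <- function(x, path, col_names = FALSE) {
  readr::write_tsv(x, path, col_names = col_names, progress = FALSE)
  invisible(path)
}

#' Write a fragment map as BED6 with a JSON sidecar
#'
#' BED columns: chrom, start, end, name = `frag_class`, score = fragment
#' length, strand = `.`. The sidecar `<path>.json` records the enzyme pair
#' and the genome label.
#'
#' @param fragments A `fourc_fragments` tibble.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- tibble(chrom = fragments$chrom,
                start = format_coord(fragments$start),
                end = format_coord(fragments$end),
                name = fragments$frag_class,
                score = fragments$length,
                strand = ".")
  write_tsv_plain(bed, path)
  enz <- attr(fragments, "enzymes")
  sidecar <- list(genome_id = attr(fragments, "genome_id"))
  if (!is.null(enz)) {
    sidecar$enzymes <- purrr::map(enz, function(e) {
      list(name = e$name, motif = e$motif, role = e$role,
           cut_offset = e$cut_offset)
    })
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fragment-map BED (+ sidecar) written by [write_fragments_bed()]
#'
#' @param path BED path; the `<path>.json` sidecar is read when present.
#' @return A `fourc_fragments` tibble.
#' @export
read_fragments_bed <- function(path) {
  bed <- read_bed(path)
  frags <- tibble(chrom = as.character(bed$chrom),
                  start = as.numeric(bed$start),
                  end = as.numeric(bed$end)) |>
    mutate(length = .data$end - .data$start,
           midpoint = floor((.data$start + .data$end) / 2),
           frag_class = bed$name,
           left_flank = NA_character_, right_flank = NA_character_) |>
    select("chrom", "start", "end", "length", "midpoint",
           "left_flank", "right_flank", "frag_class")
  enzymes <- NULL
  genome_id <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    genome_id <- meta$genome_id %||% genome_id
    if (!is.null(meta$enzymes)) {
      enzymes <- purrr::map(meta$enzymes, function(e) {
        fourc_enzyme(e$name, e$motif, e$role, e$cut_offset %||% 0L)
      })
    }
  }
  new_fourc_fragments(frags, enzymes = enzymes, genome_id = genome_id)
}

#' Write per-fragment counts as TSV
#'
#' Columns: chrom, start, end, frag_class, count (with a header line).
#'
#' @param counts A `fourc_counts` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- tibble(chrom = counts$chrom, start = counts$start,
                end = counts$end, frag_class = counts$frag_class,
                count = counts$count)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a normalized profile as bedGraph with a JSON sidecar
#'
#' The bedGraph holds `(chrom, start, end, signal)` for every retained
#' fragment; `<path>.json` records the viewpoint, the in-window raw total
#' `W`, the normalization constant and the filter report.
#'
#' @param profile A `fourc_profile`.
#' @param path Output bedGraph path.
#' @return Invisibly, `path`.
#' @export
write_profile_bedgraph <- function(profile, path) {
  bg <- tibble(chrom = profile$chrom,
               start = format_coord(profile$start),
               end = format_coord(profile$end),
               signal = profile$signal)
  write_tsv_plain(bg, path)
  vp <- attr(profile, "viewpoint")
  report <- attr(profile, "filter_report")
  sidecar <- list(
    viewpoint = list(chrom = vp$chrom, start = vp$start, end = vp$end,
                     centre = vp$centre,
                     exclusion_radius = vp$exclusion_radius,
                     norm_radius = vp$norm_radius),
    W = attr(profile, "W"),
    norm_constant = attr(profile, "norm_constant"),
    target_total = attr(profile, "target_total"),
    filter_report = as.data.frame(report)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a profile bedGraph written by [write_profile_bedgraph()]
#'
#' @param path bedGraph path; requires the `<path>.json` sidecar for the
#'   viewpoint and normalization metadata.
#' @return A `fourc_profile` tibble (without raw counts).
#' @export
read_profile_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "signal"),
                       comment = "#", show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort("profile sidecar JSON not found; cannot restore the viewpoint.")
  }
  meta <- jsonlite::read_json(sidecar)
  vp <- viewpoint(meta$viewpoint$chrom, meta$viewpoint$start,
                  meta$viewpoint$end,
                  exclusion_radius = meta$viewpoint$exclusion_radius,
                  norm_radius = meta$viewpoint$norm_radius)
  out <- x |>
    mutate(length = .data$end - .data$start,
           midpoint = floor((.data$start + .data$end) / 2),
           frag_class = "valid",
           count = NA_real_) |>
    select("chrom", "start", "end", "length", "midpoint", "frag_class",
           "count", "signal")
  attr(out, "viewpoint") <- vp
  attr(out, "W") <- meta$W
  attr(out, "norm_constant") <- meta$norm_constant
  attr(out, "target_total") <- meta$target_total
  class(out) <- unique(c("fourc_profile", class(out)))
  out
}

#' Write peak calls as BED and the fit as JSON
#'
#' Significant peaks become BED intervals `[centre - 2*sigma,
#' centre + 2*sigma]` with `score = -10 * log10(p)` (capped at 10000) and
#' `name = peak_<i>`. The full fit (background parameters, noise scale,
#' every candidate with its p-value, diagnostics) goes to `<path>.json`.
#'
#' @param fit A `fourc_fit`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(fit, path) {
  sig <- fit$peaks[fit$peaks$significant, , drop = FALSE]
  bed <- tibble(
    chrom = sig$chrom,
    start = format_coord(pmax(0, sig$centre - 2 * sig$sigma)),
    end = format_coord(sig$centre + 2 * sig$sigma),
    name = sprintf("peak_%d", seq_len(nrow(sig))),
    score = round(pmin(10000, -10 * log10(pmax(sig$p_value, 1e-300)))),
    strand = "."
  )
  write_tsv_plain(bed, path)
  sidecar <- list(
    background = list(B = fit$background$B, I_v = fit$background$I_v,
                      lambda = fit$background$lambda,
                      converged = fit$background$converged),
    residual_scale = fit$residual_scale,
    alpha = fit$alpha, sigma = fit$sigma,
    viewpoint = list(chrom = fit$viewpoint$chrom,
                     centre = fit$viewpoint$centre),
    peaks = as.data.frame(fit$peaks),
    diagnostics = fit$diagnostics
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write significant interactions as UCSC interact records
#'
#' One record per significant peak, anchoring the viewpoint region to the
#' peak interval, with the interaction score `-10 * log10(p)`.
#'
#' @param fit A `fourc_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interact <- function(fit, path) {
  sig <- fit$peaks[fit$peaks$significant, , drop = FALSE]
  vp <- fit$viewpoint
  lo <- pmin(vp$start, pmax(0, sig$centre - 2 * sig$sigma))
  hi <- pmax(vp$end, sig$centre + 2 * sig$sigma)
  rec <- tibble(
    chrom = sig$chrom,
    chromStart = format_coord(lo),
    chromEnd = format_coord(hi),
    name = sprintf("interaction_%d", seq_len(nrow(sig))),
    score = round(pmin(1000, -10 * log10(pmax(sig$p_value, 1e-100)))),
    value = sig$amplitude,
    exp = ".",
    color = "0",
    sourceChrom = sig$chrom,
    sourceStart = format_coord(vp$start),
    sourceEnd = format_coord(vp$end),
    sourceName = "viewpoint",
    sourceStrand = ".",
    targetChrom = sig$chrom,
    targetStart = format_coord(pmax(0, sig$centre - 2 * sig$sigma)),
    targetEnd = format_coord(sig$centre + 2 * sig$sigma),
    targetName = sprintf("peak_%d", seq_len(nrow(sig))),
    targetStrand = "."
  )
  write_tsv_plain(rec, path)
  invisible(path)
}

#' Write consensus regions as BED
#'
#' Score column holds the support count; the name lists the supporting
#' samples separated by `,`.
#'
#' @param regions Output of [consensus_regions()].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_consensus_bed <- function(regions, path) {
  bed <- tibble(chrom = regions$chrom,
                start = format_coord(regions$start),
                end = format_coord(regions$end),
                name = purrr::map_chr(regions$samples, paste, collapse = ","),
                score = regions$support,
                strand = ".")
  write_tsv_plain(bed, path)
  invisible(path)
}

format_coord <- function(x) {
  format(round(x), scientific = FALSE, trim = TRUE)
}
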