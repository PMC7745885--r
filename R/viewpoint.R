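#' Define a 4C viewpoint
#'
#' The viewpoint is the anchor locus (in practice the inverse-PCR primer
#' region) whose chromatin contacts the 4C library measures. Its centre
#' `x_v = floor((start + end) / 2)` is the origin of the distance axis.
#' Fragments within `exclusion_radius` of the centre are removed from the
#' profile (the self-ligation / over-digestion zone); normalization and
#' background fitting use fragments within `norm_radius` of the centre.
#'
#' @param chrom Chromosome name.
#' @param start,end Primer-region coordinates, 0-based half-open.
#' @param exclusion_radius Radius of the excluded window around the centre,
#'   in bp (default 10 kb).
#' @param norm_radius Radius of the normalization window, in bp
#'   (default 2 Mb).
#' @return An object of class `fourc_viewpoint` with a `centre` field.
#' @examples
#' viewpoint("chr10", 54427977, 54428133)  # the DpnII primer region near rs1373004
#' @export
viewpoint <- function(chrom, start, end, exclusion_radius = 1e4,
                      norm_radius = 2e6) {
  stopifnot(start < end, exclusion_radius >= 0, norm_radius > 0,
            exclusion_radius < norm_radius)
  structure(
    list(chrom = as.character(chrom), start = as.numeric(start),
         end = as.numeric(end), centre = floor((start + end) / 2),
         exclusion_radius = as.numeric(exclusion_radius),
         norm_radius = as.numeric(norm_radius)),
    class = "fourc_viewpoint"
  )
}

#' @export
print.fourc_viewpoint <- function(x, ...) {
  cat(sprintf(
    "<fourc_viewpoint> %s:%s-%s (centre %s; exclude +/-%g kb; normalize +/-%g Mb)\n",
    x$chrom, format(x$start, scientific = FALSE),
    format(x$end, scientific = FALSE),
    format(x$centre, scientific = FALSE),
    x$exclusion_radius / 1e3, x$norm_radius / 1e6))
  invisible(x)
}

#' Apply the standard 4C fragment filters
#'
#' Flags for removal, in this fixed attribution order: (1) fragments flanked
#' by two sites of the same enzyme or touching a chromosome end
#' (`frag_class != "valid"`); (2) fragments shorter than `min_len` bp;
#' (3) fragments whose midpoint lies within the viewpoint exclusion window.
#' A fragment failing several rules is attributed to the first. The operation
#' is idempotent: re-filtering a filtered table changes nothing.
#'
#' @param counts A `fourc_counts` tibble.
#' @param vp A [viewpoint()].
#' @param min_len Minimum fragment length in bp (default 40).
#' @return The `counts` tibble with logical `retained` and character
#'   `filter_reason` columns, plus a `filter_report` attribute (tibble of
#'   removals per rule).
#' @export
apply_filters <- function(counts, vp, min_len = 40) {
  stopifnot(inherits(vp, "fourc_viewpoint"))
  if (!vp$chrom %in% counts$chrom) {
    abort(sprintf("viewpoint chromosome '%s' is absent from the fragment map.",
                  vp$chrom))
  }
  near_vp <- counts$chrom == vp$chrom &
    abs(counts$midpoint - vp$centre) <= vp$exclusion_radius
  reason <- dplyr::case_when(
    counts$frag_class != "valid" ~ "class",
    counts$length < min_len ~ "length",
    near_vp ~ "proximity",
    TRUE ~ NA_character_
  )
  out <- counts
  out$retained <- is.na(reason)
  out$filter_reason <- reason
  report <- tibble(
    rule = c("class", "length", "proximity"),
    removed = c(sum(reason == "class", na.rm = TRUE),
                sum(reason == "length", na.rm = TRUE),
                sum(reason == "proximity", na.rm = TRUE))
  )
  attr(out, "filter_report") <- report
  attr(out, "viewpoint") <- vp
  attr(out, "min_len") <- min_len
  out
}

#' Normalize a filtered profile to the in-window total
#'
#' Scales retained-fragment counts so that their sum over the normalization
#' window (`|midpoint - centre| <= norm_radius` on the viewpoint chromosome)
#' equals `target_total`: `s(x) = count(x) * target_total / W`, with
#' `W` the in-window sum of retained counts. The default target of 1e6 makes
#' profiles read as "signal per million in-window reads" and comparable
#' across libraries.
#'
#' @param filtered Output of [apply_filters()].
#' @param vp A [viewpoint()]; defaults to the one recorded by
#'   [apply_filters()].
#' @param target_total In-window total after scaling (default 1e6).
#' @return A `fourc_profile` tibble of the retained fragments with a
#'   `signal` column, plus attributes `viewpoint`, `W`, `norm_constant`,
#'   `target_total` and the pass-through `filter_report`.
#' @export
normalize_profile <- function(filtered, vp = NULL, target_total = 1e6) {
  vp <- vp %||% attr(filtered, "viewpoint")
  stopifnot(inherits(vp, "fourc_viewpoint"), target_total > 0)
  if (is.null(filtered$retained)) {
    abort("`filtered` must come from apply_filters().")
  }
  kept <- filtered[filtered$retained, , drop = FALSE]
  in_window <- kept$chrom == vp$chrom &
    abs(kept$midpoint - vp$centre) <= vp$norm_radius
  W <- sum(kept$count[in_window])
  if (W <= 0) abort("no signal in normalization window.")
  norm_constant <- target_total / W
  out <- kept |>
    mutate(signal = .data$count * norm_constant) |>
    select("chrom", "start", "end", "length", "midpoint", "frag_class",
           "count", "signal")
  out <- as_tibble(out)
  attr(out, "viewpoint") <- vp
  attr(out, "W") <- W
  attr(out, "norm_constant") <- norm_constant
  attr(out, "target_total") <- target_total
  attr(out, "filter_report") <- attr(filtered, "filter_report")
  attr(out, "n_fragments_total") <- nrow(filtered)
  class(out) <- unique(c("fourc_profile", class(out)))
  out
}
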