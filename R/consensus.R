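peak_intervals <- function(fit, label) {
  sig <- fit$peaks[fit$peaks$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble(sample = character(), chrom = character(),
                  start = numeric(), end = numeric(), p_value = numeric()))
  }
  tibble(sample = label, chrom = sig$chrom,
         start = pmax(0, sig$centre - 2 * sig$sigma),
         end = sig$centre + 2 * sig$sigma,
         p_value = sig$p_value)
}

#' Consensus interacting regions across samples
#'
#' Converts each sample's significant peaks to genomic intervals
#' `[centre - 2*sigma, centre + 2*sigma]` and reports the regions of the
#' genome covered by at least `min_support` samples, merging regions
#' separated by at most `merge_gap` bp. Base-level coverage intersection is
#' robust to peak-width differences between samples. Each region records its
#' supporting samples and their best (smallest) p-value among overlapping
#' peaks.
#'
#' @param results A named list of `fourc_fit` objects (>= 2 samples), or a
#'   tibble with columns `sample`, `chrom`, `start`, `end`, `p_value` of
#'   per-sample significant peak intervals.
#' @param min_support Minimum number of supporting samples.
#' @param merge_gap Merge consensus regions closer than this many bp
#'   (default 0).
#' @return A tibble of non-overlapping regions: `chrom`, `start`, `end`,
#'   `support`, `samples` (list of labels), `sample_p` (list of named best
#'   p-values), `min_p`.
#' @export
consensus_regions <- function(results, min_support, merge_gap = 0) {
  if (is.data.frame(results)) {
    intervals <- as_tibble(results)
    stopifnot(all(c("sample", "chrom", "start", "end", "p_value") %in%
                    names(intervals)))
  } else {
    if (length(results) < 2) abort("need at least 2 samples.")
    labels <- names(results) %||% paste0("sample", seq_along(results))
    if (anyDuplicated(labels)) abort("sample labels must be unique.")
    intervals <- purrr::imap(results, peak_intervals) |> bind_rows()
    attr(intervals, "n_samples") <- length(results)
  }
  n_samples <- attr(intervals, "n_samples") %||%
    length(unique(intervals$sample))
  if (!is.data.frame(results)) n_samples <- length(results)
  if (min_support > n_samples) {
    abort("`min_support` exceeds the number of samples.")
  }
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  support = integer(), samples = list(),
                  sample_p = list(), min_p = numeric())
  if (nrow(intervals) == 0) return(empty)

  out <- purrr::map(split(intervals, intervals$chrom), function(iv) {
    # per-sample reduce so overlapping peaks within one sample count once
    per_sample <- purrr::map(split(iv, iv$sample), function(s) {
      IRanges::reduce(IRanges::IRanges(start = s$start + 1, end = s$end))
    })
    w <- max(iv$end) + 1
    cov <- Reduce(`+`, purrr::map(per_sample, IRanges::coverage, width = w))
    hits <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    if (merge_gap > 0 && length(hits) > 1) {
      hits <- IRanges::reduce(hits, min.gapwidth = merge_gap + 1)
    }
    if (length(hits) == 0) return(NULL)
    regions <- tibble(chrom = iv$chrom[1],
                      start = BiocGenerics::start(hits) - 1,
                      end = BiocGenerics::end(hits))
    supp <- purrr::map(seq_len(nrow(regions)), function(i) {
      ov <- iv$start < regions$end[i] & iv$end > regions$start[i]
      sub <- iv[ov, ]
      best <- sub |> group_by(.data$sample) |>
        summarise(p = min(.data$p_value), .groups = "drop")
      setNames(best$p, best$sample)
    })
    regions$support <- purrr::map_int(supp, length)
    regions$samples <- purrr::map(supp, names)
    regions$sample_p <- supp
    regions$min_p <- purrr::map_dbl(supp, min)
    regions
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$start)
}
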