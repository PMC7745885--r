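#' Simulate a random genome sequence
#'
#' I.i.d. bases at a given GC content. The GC default of 0.41 is human-like;
#' what matters downstream is the density of 4-bp cutter sites it implies
#' (about one GATC per 270 bp).
#'
#' @param length Sequence length in bp (> 0).
#' @param seed Integer seed; the same seed gives the identical sequence.
#' @param gc GC fraction in `[0, 1]` (default 0.41).
#' @return A single character string over `{A,C,G,T}`.
#' @export
simulate_genome <- function(length, seed, gc = 0.41) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste(bases, collapse = "")
  })
}

#' Ground truth for a simulated 4C experiment
#'
#' Bundles the generative parameters of the synthetic 4C model: the
#' constant + exponential-decay background, the Gaussian interaction peaks,
#' the sequencing depth, and the negative-binomial inverse-dispersion
#' (`dispersion -> Inf` recovers Poisson counts). The defaults emulate the
#' geometry of a viewpoint with a strong promoter-like interaction ~350 kb
#' away and a second, broader enhancer-like interaction ~430 kb away — for
#' demonstration only, no real coordinates claimed.
#'
#' @param vp A [viewpoint()].
#' @param B,I_v,lambda Background parameters in (arbitrary) signal units and
#'   bp: constant level, decay amplitude at the viewpoint, decay length.
#' @param peaks A tibble/data.frame with columns `centre` (bp, absolute),
#'   `amplitude` (signal units) and `sigma` (bp); must lie outside the
#'   viewpoint exclusion window. `NULL` for a peakless (null) truth.
#' @param depth Expected total in-window read count (> 0).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param seed Integer seed driving every random draw.
#' @return A `fourc_truth` object.
#' @export
simulation_truth <- function(vp, B = 0.5, I_v = 20, lambda = 5e4,
                             peaks = default_truth_peaks(vp),
                             depth = 2e5, dispersion = 5, seed = 1) {
  stopifnot(inherits(vp, "fourc_viewpoint"), depth > 0, dispersion > 0,
            B >= 0, I_v >= 0, lambda > 0)
  if (is.null(peaks)) {
    peaks <- tibble(centre = numeric(), amplitude = numeric(),
                    sigma = numeric())
  }
  peaks <- as_tibble(peaks)
  stopifnot(all(c("centre", "amplitude", "sigma") %in% names(peaks)))
  if (nrow(peaks) > 0) {
    stopifnot(all(peaks$amplitude > 0), all(peaks$sigma > 0))
    if (any(abs(peaks$centre - vp$centre) <= vp$exclusion_radius)) {
      abort("truth peaks must lie outside the viewpoint exclusion window.")
    }
  }
  structure(
    list(viewpoint = vp, B = B, I_v = I_v, lambda = lambda, peaks = peaks,
         depth = depth, dispersion = dispersion, seed = as.integer(seed)),
    class = "fourc_truth"
  )
}

#' @rdname simulation_truth
#' @export
default_truth_peaks <- function(vp) {
  tibble(centre = vp$centre + c(350e3, 430e3),
         amplitude = c(15, 8),
         sigma = c(2e4, 3e4))
}

truth_signal <- function(truth, x) {
  s <- truth$B + truth$I_v * exp(-abs(x - truth$viewpoint$centre) / truth$lambda)
  pk <- truth$peaks
  for (i in seq_len(nrow(pk))) {
    s <- s + pk$amplitude[i] * exp(-(x - pk$centre[i])^2 / (2 * pk$sigma[i]^2))
  }
  s
}

#' Simulate per-fragment 4C counts from a known truth
#'
#' Fragments that would survive the standard filters (valid class, length
#' >= `min_len`, outside the exclusion window) draw counts with mean
#' proportional to the truth signal `S(x)` at their midpoint, scaled so the
#' expected total over the normalization window equals `depth`. Blind and
#' short fragments draw background-rate noise counts (mean proportional to
#' `B`) so the filters have real work to do; valid fragments inside the
#' exclusion window keep the full (viewpoint-inflated) mean. Counts are
#' negative binomial with the truth's `dispersion`; every draw flows from
#' the truth's single seed.
#'
#' @param fragments A `fourc_fragments` tibble.
#' @param truth A [simulation_truth()].
#' @param min_len Length threshold mirrored from the filter stage
#'   (default 40).
#' @return A `fourc_counts` tibble.
#' @export
simulate_counts <- function(fragments, truth, min_len = 40) {
  stopifnot(inherits(truth, "fourc_truth"))
  vp <- truth$viewpoint
  if (!vp$chrom %in% fragments$chrom) {
    abort("viewpoint chromosome is absent from the fragment map.")
  }
  x <- fragments$midpoint
  on_chrom <- fragments$chrom == vp$chrom
  dist <- ifelse(on_chrom, abs(x - vp$centre), Inf)
  in_window <- on_chrom & dist <= vp$norm_radius
  if (!any(in_window)) abort("no fragments in the normalization window.")
  eligible <- fragments$frag_class == "valid" & fragments$length >= min_len &
    dist > vp$exclusion_radius

  S <- ifelse(on_chrom, truth_signal(truth, x), truth$B)
  near_vp_valid <- fragments$frag_class == "valid" &
    fragments$length >= min_len & dist <= vp$exclusion_radius
  mu_unscaled <- ifelse(eligible | near_vp_valid, S, truth$B)
  denom <- sum(mu_unscaled[in_window & eligible])
  if (denom <= 0) abort("truth signal sums to zero over the window.")
  mu <- mu_unscaled * truth$depth / denom

  counts <- withr::with_seed(truth$seed,
    rnbinom(length(mu), mu = mu, size = truth$dispersion))
  new_fourc_counts(fragments, counts)
}

#' Simulate a complete normalized 4C profile
#'
#' Convenience wrapper: simulate (or reuse) a genome, digest it, draw counts
#' from the truth, filter and normalize. When `fragments` is supplied the
#' genome/digestion steps are skipped, which makes replicate studies cheap.
#'
#' @param truth A [simulation_truth()].
#' @param genome_length Genome length in bp (default 5 Mb); ignored when
#'   `fragments` is given.
#' @param fragments Optional pre-computed `fourc_fragments`.
#' @param target_total Normalization target (default 1e6).
#' @param min_len Filter length threshold (default 40).
#' @return A list with `profile` (a `fourc_profile`), `fragments`, `counts`
#'   and `truth`.
#' @export
simulate_profile <- function(truth, genome_length = 5e6, fragments = NULL,
                             target_total = 1e6, min_len = 40) {
  if (is.null(fragments)) {
    seq <- simulate_genome(genome_length, seed = truth$seed)
    fragments <- digest_genome(setNames(seq, truth$viewpoint$chrom),
                               genome_id = "synthetic")
  }
  counts <- simulate_counts(fragments, truth, min_len = min_len)
  filtered <- apply_filters(counts, truth$viewpoint, min_len = min_len)
  profile <- normalize_profile(filtered, target_total = target_total)
  list(profile = profile, fragments = fragments, counts = counts,
       truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Produces the full input set for an end-to-end pipeline run: the genome
#' FASTA, the fragment-map BED (+ JSON sidecar), the per-fragment counts TSV
#' and the generative truth as JSON. Outputs carry no timestamps, so the same
#' specification and seed give byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param truth A [simulation_truth()]; default truth on a 5 Mb synthetic
#'   chromosome when omitted.
#' @param genome_length Genome length in bp (default 5 Mb).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
make_fixture <- function(out_dir, truth = NULL, genome_length = 5e6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(truth)) {
    vp <- viewpoint("chrS", genome_length / 2 - 78, genome_length / 2 + 78)
    truth <- simulation_truth(vp)
  }
  vp <- truth$viewpoint
  seq <- simulate_genome(genome_length, seed = truth$seed)
  names(seq) <- vp$chrom
  fragments <- digest_genome(seq, genome_id = "synthetic")
  counts <- simulate_counts(fragments, truth)

  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    fragments = file.path(out_dir, "fragments.bed"),
    counts = file.path(out_dir, "counts.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seq), paths["genome"])
  write_fragments_bed(fragments, paths["fragments"])
  write_counts_tsv(counts, paths["counts"])
  truth_json <- list(
    viewpoint = list(chrom = vp$chrom, start = vp$start, end = vp$end,
                     exclusion_radius = vp$exclusion_radius,
                     norm_radius = vp$norm_radius),
    background = list(B = truth$B, I_v = truth$I_v, lambda = truth$lambda),
    peaks = as.data.frame(truth$peaks),
    depth = truth$depth, dispersion = truth$dispersion, seed = truth$seed
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
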