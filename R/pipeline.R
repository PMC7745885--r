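#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object. Defaults
#' are the standard 4C constants: 40 bp minimum fragment length, a 10 kb
#' exclusion radius and a 2 Mb normalization radius around the viewpoint,
#' and a peak significance threshold of p < 0.0005.
#'
#' @param viewpoint A [viewpoint()] or a `"chr:start-end"` string.
#' @param primary,secondary The restriction enzymes.
#' @param min_len Minimum fragment length, bp.
#' @param exclusion_radius,norm_radius Viewpoint radii, bp.
#' @param target_total Normalization target.
#' @param sigma Peak width, bp.
#' @param alpha Peak significance threshold.
#' @param smooth_k Residual smoothing window, fragments.
#' @param bin_width Folding bin width, bp.
#' @param seed Seed for any simulation step.
#' @return A `fourc_config` list.
#' @export
fourc_config <- function(viewpoint, primary = enzyme_dpnii(),
                         secondary = enzyme_csp6i(), min_len = 40,
                         exclusion_radius = 1e4, norm_radius = 2e6,
                         target_total = 1e6, sigma = 2e4, alpha = 5e-4,
                         smooth_k = 5, bin_width = 5000, seed = 1L) {
  if (is.character(viewpoint)) viewpoint <- parse_region(viewpoint)
  if (inherits(viewpoint, "fourc_viewpoint")) {
    viewpoint <- viewpoint(viewpoint$chrom, viewpoint$start, viewpoint$end,
                           exclusion_radius = exclusion_radius,
                           norm_radius = norm_radius)
  } else {
    abort("`viewpoint` must be a fourc_viewpoint or 'chr:start-end' string.")
  }
  stopifnot(min_len >= 0, target_total > 0, sigma > 0,
            alpha > 0, alpha < 1, smooth_k >= 1, bin_width > 0)
  structure(
    list(viewpoint = viewpoint, primary = primary, secondary = secondary,
         min_len = min_len, exclusion_radius = exclusion_radius,
         norm_radius = norm_radius, target_total = target_total,
         sigma = sigma, alpha = alpha, smooth_k = smooth_k,
         bin_width = bin_width, seed = as.integer(seed)),
    class = "fourc_config"
  )
}

parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) abort("region must look like 'chr:start-end'.")
  viewpoint(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip: `read_config(write_config(cfg, path))` reconstructs an
#' equal configuration.
#'
#' @param config A `fourc_config`.
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `fourc_config`.
#' @export
write_config <- function(config, path) {
  vp <- config$viewpoint
  x <- list(
    viewpoint = sprintf("%s:%s-%s", vp$chrom,
                        format_coord(vp$start), format_coord(vp$end)),
    primary = list(name = config$primary$name, motif = config$primary$motif,
                   cut_offset = config$primary$cut_offset),
    secondary = list(name = config$secondary$name,
                     motif = config$secondary$motif,
                     cut_offset = config$secondary$cut_offset),
    min_len = config$min_len, exclusion_radius = config$exclusion_radius,
    norm_radius = config$norm_radius, target_total = config$target_total,
    sigma = config$sigma, alpha = config$alpha, smooth_k = config$smooth_k,
    bin_width = config$bin_width, seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path)
  fourc_config(
    viewpoint = x$viewpoint,
    primary = fourc_enzyme(x$primary$name, x$primary$motif, "primary",
                           x$primary$cut_offset %||% 0L),
    secondary = fourc_enzyme(x$secondary$name, x$secondary$motif,
                             "secondary", x$secondary$cut_offset %||% 0L),
    min_len = x$min_len, exclusion_radius = x$exclusion_radius,
    norm_radius = x$norm_radius, target_total = x$target_total,
    sigma = x$sigma, alpha = x$alpha, smooth_k = x$smooth_k,
    bin_width = x$bin_width, seed = x$seed
  )
}

#' Run the full 4C analysis pipeline
#'
#' Executes digest -> count -> filter/normalize -> call (and, with several
#' samples, -> consensus), writing every intermediate in its standard format
#' plus a JSON manifest with the configuration echo, the filter report, fit
#' diagnostics and md5 checksums of the outputs. Rerunning with identical
#' inputs and configuration reproduces byte-identical files (the manifest
#' carries no timestamps; stage timings go to stderr).
#'
#' @param config A [fourc_config()].
#' @param fasta Path to the genome FASTA (or a named character genome).
#' @param reads Per-sample read BED path(s), named by sample label, or
#'   `NULL` when `counts` is given.
#' @param counts Per-sample counts TSV path(s) (chrom, start, end, count),
#'   named by sample label; alternative to `reads`.
#' @param out_dir Output directory.
#' @param min_support Consensus support threshold when several samples are
#'   given (default: all samples).
#' @return Invisibly, a list with the per-sample fits, the consensus tibble
#'   (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(config, fasta, reads = NULL, counts = NULL,
                         out_dir, min_support = NULL) {
  stopifnot(inherits(config, "fourc_config"))
  if (is.null(reads) && is.null(counts)) {
    abort("supply `reads` or `counts`.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[fourcall] stage %-10s %6.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  fragments <- stage("digest", digest_genome(fasta, config$primary,
                                             config$secondary))
  write_fragments_bed(fragments, file.path(out_dir, "fragments.bed"))

  inputs <- if (!is.null(reads)) reads else counts
  labels <- names(inputs) %||% paste0("sample", seq_along(inputs))
  fits <- list()
  for (i in seq_along(inputs)) {
    lab <- labels[i]
    cnt <- stage(paste0("count:", lab), {
      if (!is.null(reads)) assign_reads(inputs[[i]], fragments)
      else load_counts(inputs[[i]], fragments)
    })
    write_counts_tsv(cnt, file.path(out_dir, paste0(lab, ".counts.tsv")))
    prof <- stage(paste0("normalize:", lab), {
      filt <- apply_filters(cnt, config$viewpoint, min_len = config$min_len)
      normalize_profile(filt, target_total = config$target_total)
    })
    write_profile_bedgraph(prof, file.path(out_dir,
                                           paste0(lab, ".profile.bedgraph")))
    fit <- stage(paste0("call:", lab),
                 call_interactions(prof, sigma = config$sigma,
                                   alpha = config$alpha,
                                   smooth_k = config$smooth_k,
                                   bin_width = config$bin_width))
    write_peaks_bed(fit, file.path(out_dir, paste0(lab, ".peaks.bed")))
    write_interact(fit, file.path(out_dir, paste0(lab, ".interact.tsv")))
    fits[[lab]] <- fit
  }

  consensus <- NULL
  if (length(fits) >= 2) {
    ms <- min_support %||% length(fits)
    consensus <- stage("consensus", consensus_regions(fits, ms))
    write_consensus_bed(consensus, file.path(out_dir, "consensus.bed"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "fourcall",
    version = as.character(utils::packageVersion("fourcall")),
    config = jsonlite::read_json(cfg_path),
    stages = c("digest", "count", "normalize", "call",
               if (!is.null(consensus)) "consensus"),
    samples = labels,
    fits = purrr::map(fits, ~ as.list(glance(.x))),
    checksums = setNames(
      as.list(tools::md5sum(file.path(out_dir, sort(outputs)))),
      sort(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, consensus = consensus, manifest = manifest))
}
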