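# Shared synthetic setup: one 4.6 Mb genome digested once per test run, with
# the viewpoint at the centre, reused across replicate studies for speed.

shared_sim_env <- new.env(parent = emptyenv())

shared_fragments <- function() {
  if (is.null(shared_sim_env$fragments)) {
    len <- 4.6e6
    seq <- simulate_genome(len, seed = 20260901)
    shared_sim_env$fragments <- digest_genome(
      c(chrS = seq), genome_id = "shared-synthetic")
    shared_sim_env$vp <- viewpoint("chrS", len / 2 - 78, len / 2 + 78)
  }
  shared_sim_env$fragments
}

shared_viewpoint <- function() {
  shared_fragments()
  shared_sim_env$vp
}

# one simulated profile on the shared map (default truth, given seed)
local_sim_profile <- function(seed, peaks = NULL, depth = 2e5,
                              dispersion = 5) {
  frags <- shared_fragments()
  vp <- shared_viewpoint()
  truth <- if (is.null(peaks)) {
    simulation_truth(vp, depth = depth, dispersion = dispersion, seed = seed)
  } else {
    simulation_truth(vp, peaks = peaks, depth = depth,
                     dispersion = dispersion, seed = seed)
  }
  simulate_profile(truth, fragments = frags)
}

# a tiny hand-checkable fragment map: chrom tiled as
#   [0,2) terminal | [2,12) valid | [12,20) valid | [20,26) terminal
toy_sequence <- function() "NNGATCAAAAAAGTACAAAAGATCNN"

# 6-fragment toy map tiling [0, 60000) that exercises every filter rule:
# f1 terminal (class), f2 valid far from the viewpoint (kept), f3
# blind_primary (class), f4 valid but 30 bp (length), f5 valid at the
# viewpoint (proximity), f6 valid far (kept). Viewpoint centre = 30230.
toy_filter_map <- function() {
  frags <- tibble::tibble(
    chrom = "chrT",
    start = c(0, 100, 25100, 25200, 25230, 35230),
    end = c(100, 25100, 25200, 25230, 35230, 60000),
    left_flank = c("end", "primary", "primary", "primary", "secondary",
                   "primary"),
    right_flank = c("primary", "primary", "primary", "secondary", "primary",
                    "end"),
    frag_class = c("terminal", "valid", "blind_primary", "valid", "valid",
                   "terminal")
  )
  # f6 is genuinely valid despite flanking the chromosome end in the toy
  # bookkeeping above; override classes to the intended test design
  frags$frag_class <- c("terminal", "valid", "blind_primary", "valid",
                        "valid", "valid")
  frags$length <- frags$end - frags$start
  frags$midpoint <- floor((frags$start + frags$end) / 2)
  fourcall:::new_fourc_fragments(frags, enzymes = NULL, genome_id = "toy")
}

toy_filter_viewpoint <- function() viewpoint("chrT", 30200, 30260)
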