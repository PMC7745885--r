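toy_counts <- function(counts = c(5, 10, 4, 3, 8, 6)) {
  fourcall:::new_fourc_counts(toy_filter_map(), counts)
}

test_that("the three filter rules remove exactly the expected toy fragments", {
  filt <- apply_filters(toy_counts(), toy_filter_viewpoint(), min_len = 40)
  expect_equal(sum(filt$retained), 2)
  expect_equal(filt$retained,
               c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(filt$filter_reason,
               c("class", NA, "class", "length", "proximity", NA))
  report <- attr(filt, "filter_report")
  expect_equal(sum(report$removed), 4)
  expect_equal(report$removed[report$rule == "class"], 2)
  expect_equal(report$removed[report$rule == "length"], 1)
  expect_equal(report$removed[report$rule == "proximity"], 1)
})

test_that("a fragment failing several rules is attributed to the first rule", {
  # make the blind fragment also short: still attributed to 'class'
  map <- toy_filter_map()
  cnt <- fourcall:::new_fourc_counts(map, rep(1, 6))
  filt <- apply_filters(cnt, toy_filter_viewpoint(), min_len = 200)
  expect_equal(filt$filter_reason[3], "class")
  # f4 (30 bp) now fails length before proximity would ever see it
  expect_equal(filt$filter_reason[4], "length")
})

test_that("disabled length filter shifts the short fragment to the proximity rule", {
  # the 30-bp fragment sits 5 kb from the viewpoint, so with min_len = 0 it
  # is still removed, but now attributed to proximity
  filt <- apply_filters(toy_counts(), toy_filter_viewpoint(), min_len = 0)
  report <- attr(filt, "filter_report")
  expect_equal(report$removed[report$rule == "length"], 0)
  expect_equal(report$removed[report$rule == "proximity"], 2)
  expect_equal(sum(filt$retained), 2)
})

test_that("filtering is idempotent and a clean map passes untouched", {
  filt1 <- apply_filters(toy_counts(), toy_filter_viewpoint())
  filt2 <- apply_filters(filt1, toy_filter_viewpoint())
  expect_equal(as.data.frame(filt1), as.data.frame(filt2))

  clean <- toy_filter_map()[c(2, 6), ]
  cnt <- fourcall:::new_fourc_counts(clean, c(4, 9))
  filt <- apply_filters(cnt, toy_filter_viewpoint())
  expect_true(all(filt$retained))
  expect_equal(sum(attr(filt, "filter_report")$removed), 0)
})

test_that("viewpoint chromosome absent from the map is a hard error", {
  expect_error(
    apply_filters(toy_counts(), viewpoint("chrZ", 100, 200)),
    "absent")
})

test_that("normalization rescales the in-window sum to target_total", {
  frags <- tibble::tibble(
    chrom = "chrT", start = c(0, 1000, 40000), end = c(1000, 2000, 41000),
    left_flank = "primary", right_flank = "secondary",
    frag_class = "valid")
  frags$length <- frags$end - frags$start
  frags$midpoint <- floor((frags$start + frags$end) / 2)
  frags <- fourcall:::new_fourc_fragments(frags, enzymes = NULL,
                                          genome_id = "toy")
  vp2 <- viewpoint("chrT", 2400, 2600, exclusion_radius = 10,
                   norm_radius = 20000)

  # counts [2, 3, 5] with everything in the window, target 10: W = 10,
  # signal unchanged
  vp_wide <- viewpoint("chrT", 2400, 2600, exclusion_radius = 10)
  cnt0 <- fourcall:::new_fourc_counts(frags, c(2, 3, 5))
  prof0 <- normalize_profile(apply_filters(cnt0, vp_wide), target_total = 10)
  expect_equal(prof0$signal, c(2, 3, 5))
  expect_equal(attr(prof0, "norm_constant"), 1)

  # [1, 1] in-window and [7] outside the window: W = 2
  cnt <- fourcall:::new_fourc_counts(frags, c(1, 1, 7))
  filt2 <- apply_filters(cnt, vp2)
  prof2 <- normalize_profile(filt2, target_total = 1)
  expect_equal(prof2$signal, c(0.5, 0.5, 3.5))

  # single in-window fragment, count 4, target 1e6
  cnt3 <- fourcall:::new_fourc_counts(frags[1, ], 4)
  filt3 <- apply_filters(cnt3, vp2)
  prof3 <- normalize_profile(filt3, target_total = 1e6)
  expect_equal(prof3$signal, 1e6)
})

test_that("zero in-window signal is a hard error", {
  cnt <- toy_counts(c(0, 0, 0, 0, 0, 0))
  filt <- apply_filters(cnt, toy_filter_viewpoint())
  expect_error(normalize_profile(filt), "no signal")
})

test_that("normalization conserves the in-window total on random inputs", {
  map <- shared_fragments()
  vp <- shared_viewpoint()
  withr::with_seed(555, {
    for (i in 1:20) {
      cnt <- fourcall:::new_fourc_counts(map, rpois(nrow(map), runif(1, 0.5, 5)))
      filt <- apply_filters(cnt, vp)
      target <- runif(1, 1, 1e7)
      prof <- normalize_profile(filt, target_total = target)
      in_win <- prof$chrom == vp$chrom &
        abs(prof$midpoint - vp$centre) <= vp$norm_radius
      expect_equal(sum(prof$signal[in_win]), target, tolerance = 1e-9)
    }
  })
})

test_that("profiles are invariant under count rescaling", {
  map <- toy_filter_map()
  vp <- toy_filter_viewpoint()
  base <- c(5, 10, 4, 3, 8, 6)
  p1 <- normalize_profile(apply_filters(
    fourcall:::new_fourc_counts(map, base), vp))
  p2 <- normalize_profile(apply_filters(
    fourcall:::new_fourc_counts(map, base * 17), vp))
  expect_equal(p1$signal, p2$signal)
})

test_that("profile bedGraph round-trips with its sidecar", {
  prof <- normalize_profile(apply_filters(toy_counts(),
                                          toy_filter_viewpoint()))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile_bedgraph(prof, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_profile_bedgraph(path)
  expect_equal(back$signal, prof$signal)
  expect_equal(back$midpoint, prof$midpoint)
  expect_equal(attr(back, "W"), attr(prof, "W"))
})
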