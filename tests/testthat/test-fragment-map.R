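test_that("find_cut_sites locates motif occurrences at 0-based positions", {
  dpnii <- enzyme_dpnii()
  expect_identical(find_cut_sites("AAGATCAA", dpnii), 2L)
  expect_identical(find_cut_sites("GATCGATC", dpnii), c(0L, 4L))
  expect_identical(find_cut_sites("AAAA", dpnii), integer(0))
  expect_identical(find_cut_sites("", dpnii), integer(0))
  expect_identical(find_cut_sites("GAT", dpnii), integer(0))
  # motifs never match across N
  expect_identical(find_cut_sites("GANC", dpnii), integer(0))
})

test_that("overlapping motif occurrences are all reported", {
  enz <- fourc_enzyme("toy", "ATAT", "primary")
  expect_identical(find_cut_sites("ATATAT", enz), c(0L, 2L))
})

test_that("cut offset shifts reported positions within the motif", {
  enz <- fourc_enzyme("toy", "GATC", "primary", cut_offset = 2L)
  expect_identical(find_cut_sites("AAGATCAA", enz), 4L)
})

test_that("digestion of a hand-enumerated chromosome gives the expected fragments", {
  # NN GATC AAAAAA GTAC AAAA GATC NN: cuts at 2 (P), 12 (S), 20 (P)
  map <- digest_genome(c(chr1 = toy_sequence()),
                       enzyme_dpnii(), enzyme_csp6i())
  expect_equal(nrow(map), 4)
  expect_equal(map$start, c(0, 2, 12, 20))
  expect_equal(map$end, c(2, 12, 20, 26))
  expect_equal(map$frag_class, c("terminal", "valid", "valid", "terminal"))
  expect_equal(map$left_flank, c("end", "primary", "secondary", "primary"))
  expect_equal(map$right_flank, c("primary", "secondary", "primary", "end"))
})

test_that("fragment between two primary cuts with no secondary is blind_primary", {
  map <- digest_genome(c(chr1 = "AAGATCAAAAGATCAAGTACAA"),
                       enzyme_dpnii(), enzyme_csp6i())
  expect_equal(map$frag_class[map$start == 2], "blind_primary")
})

test_that("chromosome with a single cut yields two terminal fragments", {
  map <- digest_genome(c(chr1 = "ACGTACGT"), enzyme_dpnii(), enzyme_csp6i())
  expect_equal(nrow(map), 2)
  expect_equal(map$start, c(0, 2))  # GTAC starts at 0-based position 2
  expect_true(all(map$frag_class == "terminal"))
})

test_that("chromosome with no cut sites becomes a single terminal fragment", {
  map <- digest_genome(c(chr1 = "AAAAAAAA"), enzyme_dpnii(), enzyme_csp6i())
  expect_equal(nrow(map), 1)
  expect_equal(map$frag_class, "terminal")
  expect_equal(map$end - map$start, 8)
})

test_that("digestion matches the naive per-offset scan on random sequences", {
  withr::with_seed(4711, {
    for (i in 1:25) {
      n <- sample(200:5000, 1)
      seq <- random_dna(n, n_frac = if (i %% 5 == 0) 0.01 else 0)
      map <- digest_genome(c(chrR = seq), enzyme_dpnii(), enzyme_csp6i())
      oracle <- naive_fragment_bounds(seq, c("GATC", "GTAC"))
      expect_equal(map$start, unname(oracle[, "start"]))
      expect_equal(map$end, unname(oracle[, "end"]))
    }
  })
})

test_that("fragments tile each chromosome exactly with closed classes", {
  withr::with_seed(99, {
    seqs <- c(chrA = random_dna(3000), chrB = random_dna(1500))
    map <- digest_genome(seqs, enzyme_dpnii(), enzyme_csp6i())
    for (ch in names(seqs)) {
      m <- map[map$chrom == ch, ]
      expect_equal(m$start, c(0, head(m$end, -1)))  # no gaps, no overlaps
      expect_equal(sum(m$length), nchar(seqs[[ch]]))
      expect_equal(m$end[nrow(m)], nchar(seqs[[ch]]))
    }
    expect_true(all(map$frag_class %in%
      c("valid", "blind_primary", "blind_secondary", "terminal")))
    expect_true(all(map$start < map$end))
    # class is a pure function of the flanks
    expect_equal(map$frag_class,
                 fourcall:::classify_fragment(map$left_flank, map$right_flank))
  })
})

test_that("digestion is deterministic", {
  withr::with_seed(7, seq <- random_dna(2000))
  m1 <- digest_genome(c(chr = seq), enzyme_dpnii(), enzyme_csp6i())
  m2 <- digest_genome(c(chr = seq), enzyme_dpnii(), enzyme_csp6i())
  expect_identical(m1, m2)
})

test_that("fragment midpoints follow floor((start+end)/2) and increase", {
  frags <- tibble::tibble(start = c(100, 0, 0, 10), end = c(200, 1, 10, 30))
  expect_equal(fragment_midpoints(frags), c(150, 0, 5, 20))
  map <- digest_genome(c(chr1 = toy_sequence()), enzyme_dpnii(), enzyme_csp6i())
  expect_equal(map$midpoint, fragment_midpoints(map))
  expect_true(all(diff(map$midpoint) > 0))
})

test_that("enzyme validation rejects malformed motifs and roles", {
  expect_error(fourc_enzyme("bad", "GAXC", "primary"), "A,C,G,T")
  expect_error(fourc_enzyme("bad", "GAT", "primary"), "4 bp")
  expect_error(fourc_enzyme("bad", "GATC", "primary", cut_offset = 4), "within")
  expect_error(
    digest_genome(c(chr = "ACGT"), enzyme_dpnii(), enzyme_dpnii()),
    "primary and one secondary")
})

test_that("FASTA round-trip: digesting a written genome equals in-memory digestion", {
  withr::with_seed(11, seq <- random_dna(2500))
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(chrF = seq)), fa)
  m_file <- digest_genome(fa, enzyme_dpnii(), enzyme_csp6i(), genome_id = "g")
  m_mem <- digest_genome(c(chrF = seq), enzyme_dpnii(), enzyme_csp6i(),
                         genome_id = "g")
  expect_equal(as.data.frame(m_file), as.data.frame(m_mem))
})
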