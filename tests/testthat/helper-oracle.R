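# Independent oracles used across the suite.

# naive per-offset motif scan: checks every start offset with substring
# comparison; deliberately independent of the Biostrings-based matcher
naive_cut_sites <- function(sequence, motif, cut_offset = 0L) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1)) {
    if (substr(sequence, i, i + m - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits + cut_offset
}

# random DNA over {A,C,G,T} (optionally salted with N)
random_dna <- function(n, n_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (n_frac > 0) {
    idx <- sample(n, max(1, round(n_frac * n)))
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# naive digestion from oracle cut sites: fragment boundaries only
naive_fragment_bounds <- function(sequence, motifs) {
  n <- nchar(sequence)
  cuts <- sort(unique(unlist(lapply(motifs, function(m) {
    naive_cut_sites(sequence, m)
  }))))
  cuts <- cuts[cuts > 0 & cuts < n]
  cbind(start = c(0, cuts), end = c(cuts, n))
}
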