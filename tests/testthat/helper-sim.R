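# Small-genome configuration for structural tests (not the default study
# conditions; recovery-rate tests use sim_config() defaults).
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_genes_per_class = c(housekeeping = 6L, bivalent = 6L,
                                   super_bivalent = 4L, active = 6L,
                                   silent = 6L),
             chrom_length = 2e6, ...)
}

# Deterministic toy reads: one read of length `len` starting at each
# element of `starts`.
toy_reads <- function(starts, chrom = "chr1", len = 50,
                      mark = "H3K4me3", sample_id = "s1") {
  n <- length(starts)
  data.frame(chrom = rep(chrom, n), start = starts, end = starts + len,
             mark = rep(mark, n), sample_id = rep(sample_id, n),
             stringsAsFactors = FALSE)
}

# Brute-force midpoint oracle: per-window scan over all reads.
brute_force_counts <- function(reads, windows) {
  mids <- (reads$start + reads$end) %/% 2
  vapply(seq_len(nrow(windows)), function(i) {
    sum(reads$chrom == windows$chrom[i] &
          mids >= windows$start[i] & mids < windows$end[i])
  }, integer(1))
}

# Do two leaves sit in the same 2-clade split of an hclust tree?
same_clade <- function(hc, a, b) {
  k <- stats::cutree(hc, 2)
  k[[a]] == k[[b]]
}
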