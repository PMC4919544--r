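# shared desk-scale fixtures, built fresh per test run

# oriented window midpoints without reaching into internals
window_midpoints_of <- function(spec) {
  -spec$span + (seq_len(spec$n_windows) - 1L) * spec$width + spec$width / 2
}

toy <- make_toy_genome(50, 2e5, min_gap = 1700, seed = 1)
toy_ann <- toy$annotation
toy_sizes <- toy$chrom_sizes
toy_spec <- window_spec()
toy_mid <- window_midpoints_of(toy_spec)

# a small deterministic alignment table on one chromosome
random_records <- function(n, len = 2e4, seed = 1, chrom = "chrT") {
  set.seed(seed)
  data.frame(chrom = chrom,
             start = sample.int(len, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             mapq = sample(0:60, n, replace = TRUE),
             read_id = sprintf("r%05d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# plain data.frame -> tss_matrix with no masking, for statistics tests
unmasked_tss_matrix <- function(vals, spec = toy_spec) {
  mask <- matrix(FALSE, nrow(vals), ncol(vals))
  rownames(mask) <- rownames(vals)
  tss_matrix(vals, mask, spec)
}
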