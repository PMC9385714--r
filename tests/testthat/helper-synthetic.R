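# Shared fixture builders; everything is generated in code under fixed
# seeds so no data files are needed.

random_genotype <- function(L) {
  paste(sample(RNA_BASES, L, replace = TRUE), collapse = "")
}

# every sequence at exactly Hamming distance d from seq, by brute force
# over the full 4^L space; only usable for tiny L
brute_force_at_distance <- function(seq, d) {
  L <- nchar(seq)
  grid <- expand.grid(rep(list(RNA_BASES), L), stringsAsFactors = FALSE)
  all_seqs <- do.call(paste0, grid)
  all_seqs[hamming(seq, all_seqs) == d]
}

# an additive (epistasis-free) activity landscape over random mutants of
# wt: ln RA of a variant is the sum of independent per-site effects
additive_activity <- function(wt, seqs, effect_sd = 0.6, effect_mean = -0.3) {
  L <- nchar(wt)
  eff <- matrix(stats::rnorm(4L * L, effect_mean, effect_sd), 4L, L)
  wt_ch <- strsplit(wt, "")[[1]]
  ra <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(ch != wt_ch)
    exp(sum(eff[cbind(match(ch[idx], RNA_BASES), idx)]))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(sequence = seqs, ra = ra, stringsAsFactors = FALSE)
}

# complete biallelic landscape as a sequence table, from a binary RA
# vector and a locus map
binary_landscape_df <- function(ra, map) {
  N <- map$N
  seqs <- vapply(0:(2^N - 1L), function(i)
    decode_binary(index_to_bits(i, N), map), character(1))
  data.frame(sequence = seqs, ra = ra, stringsAsFactors = FALSE)
}

# default locus map over a small core: loci at positions 1..N
toy_locus_map <- function(N, L = 2L * N) {
  wt <- paste(rep_len(RNA_BASES, L), collapse = "")
  ch <- strsplit(wt, "")[[1]]
  ch[seq_len(N)] <- RNA_BASES[match(ch[seq_len(N)], RNA_BASES) %% 4L + 1L]
  locus_map(wt, paste(ch, collapse = ""))
}
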