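# Shared fixtures and independent oracles, built in code at test time.

# small default transcriptome (20 genes incl. the SRSF5-like one), memoised
small_txome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_transcriptome(seed = 1)
    cache
  }
})

# tiny transcriptome (<= 20 transcripts) for exhaustive oracle checks
tiny_txome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_transcriptome(
        toy_config(n_background_genes = 3L, bg_isoform_range = c(2L, 3L)),
        seed = 7)
    cache
  }
})

# brute-force pseudoalignment oracle, independent of the k-mer index:
# the compatible set is {t : every indexed k-mer of the read occurs in t},
# where "indexed" means present in at least one transcript.
kmers_of <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

brute_force_ec <- function(txome, read, k) {
  tx_kmers <- lapply(as.character(txome$tx_seq), kmers_of, k = k)
  indexed <- unique(unlist(tx_kmers, use.names = FALSE))
  rk <- kmers_of(read, k)
  rk <- rk[rk %in% indexed]
  if (length(rk) == 0L) return(NULL)
  hit <- names(tx_kmers)[vapply(tx_kmers, function(tk) all(rk %in% tk),
                                logical(1))]
  if (length(hit) == 0L) NULL else hit
}

# read sequence at a 0-based start of a transcript
tx_read <- function(txome, txid, start0, L) {
  substr(as.character(txome$tx_seq[[txid]]), start0 + 1L, start0 + L)
}

# error-free uniform-start reads with fixed per-transcript counts
sim_reads_fixed <- function(txome, ids, counts, L) {
  reads <- unlist(lapply(seq_along(ids), function(i) {
    if (counts[i] == 0L) return(character(0))
    s <- as.character(txome$tx_seq[[ids[i]]])
    npos <- nchar(s) - L + 1L
    st <- sample.int(npos, counts[i], replace = TRUE)
    substring(s, st, st + L - 1L)
  }), use.names = FALSE)
  stats::setNames(reads, sprintf("r%06d", seq_along(reads)))
}

expect_prob <- function(p) {
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
}
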