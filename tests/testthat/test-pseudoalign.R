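test_that("a transcript of length n contributes n - k + 1 k-mer occurrences", {
  # one 300 nt transcript, k = 21 -> 280 occurrences; and the 7-mer arithmetic
  # of the invariant holds on every indexed transcript
  tx <- tiny_txome()
  idx <- build_index(tx, k = 21)
  st <- index_stats(idx)
  expect_equal(st$n_kmer_occurrences,
               sum(tx$transcripts$length - 21 + 1))
})

test_that("k-mers of a shared exon map to both transcripts", {
  # two transcripts sharing a 30 nt exon, k = 21: each of the 10 exon-internal
  # k-mers maps to both transcripts
  set.seed(42)
  core <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  u1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  u2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  idx <- build_index(c(t1 = paste0(u1, core), t2 = paste0(u2, core)), k = 21)
  internal <- substring(core, 1:10, 21:30)
  for (km in internal) {
    expect_setequal(pseudoalign_read(idx, km), c("t1", "t2"))
  }
})

test_that("k below 8 or above the shortest transcript is rejected", {
  tx <- tiny_txome()
  expect_error(build_index(tx, k = 7), "at least 8")
  expect_error(build_index(tx, k = min(tx$transcripts$length) + 1L),
               "shortest transcript")
  expect_error(pseudoalign_read(build_index(tx, k = 21), "ACGTACGT"),
               "shorter than k")
})

test_that("reads from characteristic regions resolve to the expected ECs", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  all9 <- c(poison_transcripts(tx), productive_transcripts(tx))
  # read wholly inside constitutive exon 1 -> all nine isoforms
  r_const <- tx_read(tx, "SRSF5L-201", 10, 90)
  expect_setequal(pseudoalign_read(idx, r_const), all9)
  # read spanning the exon5 -> intron5 boundary -> exactly the poison trio
  r_pois <- tx_read(tx, "SRSF5L-207", 5 * 120 - 40, 90)
  expect_setequal(pseudoalign_read(idx, r_pois), poison_transcripts(tx))
  # random sequence sharing no k-mer with the index -> unassigned
  set.seed(99)
  repeat {
    rnd <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
    if (is.null(brute_force_ec(tx, rnd, 21))) break
  }
  expect_null(pseudoalign_read(idx, rnd))
})

test_that("pseudoalignment equals the brute-force oracle on sampled reads", {
  # spot-check the oracle equivalence on random reads with simulated errors;
  # the exhaustive sweep over every start position is in the acceptance suite
  tx <- tiny_txome()
  idx <- build_index(tx, k = 21)
  set.seed(31)
  txids <- tx$transcripts$transcript_id
  for (i in 1:120) {
    t <- sample(txids, 1)
    len <- tx$transcripts$length[txids == t]
    s0 <- sample.int(len - 90 + 1L, 1L) - 1L
    rd <- tx_read(tx, t, s0, 90)
    if (i %% 3 == 0) { # inject a substitution
      pos <- sample.int(90, 1)
      substr(rd, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- pseudoalign_read(idx, rd)
    want <- brute_force_ec(tx, rd, 21)
    if (is.null(want)) expect_null(got) else expect_setequal(got, want)
  }
})

test_that("bulk TCC counting tallies identical reads into one EC", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  rd <- tx_read(tx, "SRSF5L-201", 10, 90)
  reads <- list(s1 = setNames(rep(rd, 7), sprintf("r%d", 1:7)))
  tcc <- suppressMessages(count_tccs(idx, reads, mode = "bulk"))
  expect_equal(dim(tcc$counts), c(1L, 1L))
  expect_equal(sum(tcc$counts), 7)
  expect_equal(tcc$ec_info$n_tx, 9L)
})

test_that("single-cell counting deduplicates UMIs and drops multi-gene ECs", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  rd <- tx_read(tx, "SRSF5L-201", 10, 90)
  other <- tx$transcripts$transcript_id[tx$transcripts$gene_id != "SRSF5L"][1]
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    barcode = c("AAAA", "AAAA", "AAAA", "AAAA"),
    umi = c("TT", "TT", "GG", "CC"),
    cdna = c(rd, rd, rd, tx_read(tx, other, 5, 90)),
    stringsAsFactors = FALSE)
  tcc <- suppressMessages(count_tccs(idx, reads, mode = "single_cell"))
  # r1/r2 collapse to one molecule; r3 and r4 stay
  expect_equal(sum(tcc$counts), 3)
  # dedup is idempotent: re-counting already-deduplicated molecules is identity
  tcc3 <- suppressMessages(count_tccs(idx, reads[c(1, 3, 4), ],
                                      mode = "single_cell"))
  expect_equal(as.matrix(tcc3$counts), as.matrix(tcc$counts))
  # mode errors
  expect_error(suppressMessages(count_tccs(idx, list(a = rd), mode = "single_cell")),
               "barcodes")

  # a read whose EC spans two genes is excluded from the matrix: build a
  # two-gene reference sharing a common segment so the EC genuinely spans both
  set.seed(12)
  core <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  u1 <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  u2 <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  idx2 <- build_index(c(x = paste0(u1, core), y = paste0(u2, core)), k = 21,
                      tx2gene = data.frame(transcript_id = c("x", "y"),
                                           gene_id = c("gx", "gy")))
  reads2 <- data.frame(read_id = c("c1", "c2"), barcode = "CCCC",
                       umi = c("AA", "GG"),
                       cdna = c(core, substr(paste0(u1, core), 1, 90)),
                       stringsAsFactors = FALSE)
  tcc2 <- suppressMessages(count_tccs(idx2, reads2, mode = "single_cell"))
  # the shared-core read (EC {x, y}, two genes) is dropped; the unique read kept
  expect_equal(sum(tcc2$counts), 1)
  expect_equal(tcc2$ec_info$genes, "gx")
})

test_that("filter_sc applies the cell and EC quality filters in order", {
  counts <- Matrix::Matrix(0, 200, 3, sparse = TRUE,
                           dimnames = list(sprintf("c%03d", 1:200),
                                           c("1", "2", "3")))
  counts[, 1] <- 5                       # healthy EC
  counts[1, 2] <- 1                      # detected in 0.5% of cells, mean 0.005
  counts[1:10, 3] <- c(rep(1, 9), 3)     # 5% detection, mean 0.06
  mat <- structure(list(counts = counts,
                        ec_info = data.frame(ec_id = 1:3,
                                             transcripts = c("a", "b", "c"),
                                             genes = c("g", "g", "g"),
                                             n_tx = 1L, n_genes = 1L),
                        mode = "single_cell"), class = "tcc_matrix")
  f <- filter_sc(mat, min_cell_total = 0, min_detect_frac = 0.01,
                 min_mean = 0.01)
  expect_setequal(colnames(f$counts), c("1", "3"))
  # identity when all thresholds are zero
  f0 <- filter_sc(mat, 0, 0, 0)
  expect_equal(dim(f0$counts), dim(mat$counts))
  # cell filter removes low-UMI cells first
  f2 <- filter_sc(mat, min_cell_total = 6, min_detect_frac = 0,
                  min_mean = 0)
  expect_lt(nrow(f2$counts), 200L)
  expect_error(filter_sc(mat, min_cell_total = 1e6), "all cells")
})
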