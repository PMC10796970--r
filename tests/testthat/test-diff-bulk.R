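# Bulk differential testing: Wald machinery, Lancaster aggregation, BH.

# build a minimal abundance_set by hand
fake_abundance <- function(est, boots, genes = NULL) {
  tx_ids <- rownames(est)
  if (is.null(genes)) genes <- tx_ids
  structure(list(
    est_counts = est,
    proportions = sweep(est, 2, colSums(est), "/"),
    boots = boots,
    transcripts = data.frame(transcript_id = tx_ids, gene_id = genes,
                             length = 300L, stringsAsFactors = FALSE),
    eff_length = setNames(rep(211, nrow(est)), tx_ids),
    read_length = 90L), class = "abundance_set")
}

test_that("identical observations in both groups give beta = 0 and p = 1", {
  units <- c("A1", "A2", "B1", "B2")
  est <- matrix(rep(c(100, 50), 4), 2, 4,
                dimnames = list(c("t1", "t2"), units))
  boots <- setNames(lapply(units, function(u)
    matrix(rep(c(100, 50), 10), 2, 10,
           dimnames = list(c("t1", "t2"), NULL)) +
      matrix(c(1, -1), 2, 10) * rep(seq(-2, 2, length.out = 10), each = 2)),
    units)
  design <- make_design(2, 2)
  res <- transcript_wald_test(fake_abundance(est, boots), design,
                              shrink = FALSE)
  expect_equal(res$beta, c(0, 0))
  expect_equal(res$pval, c(1, 1))
  expect_true(all(res$se > 0))
})

test_that("biological variance is floored when the bootstrap variance exceeds the total", {
  units <- c("A1", "A2", "B1", "B2")
  est <- matrix(c(100, 101, 100.5, 99.5), 1, 4,
                dimnames = list("t1", units))
  # huge inferential spread
  set.seed(2)
  boots <- setNames(lapply(units, function(u)
    matrix(exp(rnorm(30, log(100), 1)), 1, 30,
           dimnames = list("t1", NULL))), units)
  res <- transcript_wald_test(fake_abundance(est, boots), make_design(2, 2),
                              shrink = FALSE)
  expect_equal(res$sigma2_bio, 1e-6, tolerance = 1e-9)
  expect_prob(res$pval)
  expect_true(is.finite(res$stat))
})

test_that("a strong simulated switch ranks among the smallest transcript p-values", {
  tx <- tiny_txome()
  design <- make_design(4, 4)
  idx <- build_index(tx, k = 21)
  hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    truth <- sim_truth(tx, seed = s, poison_fraction = c(A = 0.15, B = 0.6),
                       phi = 0.05)
    sim <- simulate_bulk_reads(tx, truth, design, 30000, seed = 100 + s)
    tcc <- suppressMessages(count_tccs(idx, sim))
    ab <- quantify_units(tcc, idx, read_length = 90, B = 30, seed = s)
    res <- transcript_wald_test(ab, design)
    # poison isoforms jump 4x: at least one of them in the global top 5
    rnk <- rank(res$pval)[res$transcript_id %in% poison_transcripts(tx)]
    hits <- hits + (min(rnk) <= 5)
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("Lancaster aggregation matches its closed forms", {
  # single component: gene p equals the transcript p for any weight
  for (w in c(0.5, 1, 2, 7.3)) {
    expect_equal(lancaster_aggregate(0.037, w), 0.037, tolerance = 1e-12)
  }
  # all weights 2 reduce to Fisher: p = p1 p2 (1 - ln(p1 p2))
  expect_equal(lancaster_aggregate(c(0.5, 0.5), c(2, 2)), 0.5966,
               tolerance = 1e-4)
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    pp <- prod(p)
    k <- length(p)
    fisher <- pchisq(-2 * log(pp), df = 2 * k, lower.tail = FALSE)
    expect_equal(lancaster_aggregate(p, rep(2, k)), fisher, tolerance = 1e-10)
  }
  # monotone limit: a vanishing component drives the gene p to zero
  expect_lt(lancaster_aggregate(c(1e-14, 0.8), c(3, 1)), 1e-9)
  # empty input is untested
  expect_true(is.na(lancaster_aggregate(numeric(0), numeric(0))))
  expect_error(lancaster_aggregate(0.5, 0), "positive")
})

test_that("BH adjustment reproduces the step-up arithmetic and rejects NaN", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  # monotone in p and invariant to input order
  set.seed(3)
  p <- runif(40)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("single-isoform gene p equals its transcript p under count aggregation", {
  units <- c("A1", "A2", "B1", "B2")
  set.seed(8)
  est <- matrix(exp(rnorm(8, log(200), 0.3)), 2, 4,
                dimnames = list(c("t1", "t2"), units))
  boots <- setNames(lapply(units, function(u)
    matrix(exp(rnorm(2 * 20, log(200), 0.05)), 2, 20,
           dimnames = list(c("t1", "t2"), NULL))), units)
  ab <- fake_abundance(est, boots, genes = c("g1", "g2"))
  tx_res <- transcript_wald_test(ab, make_design(2, 2), shrink = FALSE)
  g_res <- gene_count_test(ab, make_design(2, 2), shrink = FALSE)
  expect_equal(g_res$pval[g_res$gene_id == "g1"],
               tx_res$pval[tx_res$transcript_id == "t1"], tolerance = 1e-10)
})

test_that("a doubled gene mean is caught by the count-aggregation test", {
  units <- c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4")
  set.seed(14)
  base <- exp(rnorm(8, log(400), 0.15)) * rep(c(1, 2), each = 4)
  est <- rbind(t1 = base * 0.6, t2 = base * 0.4)
  colnames(est) <- units
  boots <- setNames(lapply(units, function(u)
    matrix(exp(rnorm(2 * 20, log(200), 0.03)), 2, 20,
           dimnames = list(c("t1", "t2"), NULL))), units)
  ab <- fake_abundance(est, boots, genes = c("g1", "g1"))
  g <- gene_count_test(ab, make_design(4, 4), shrink = FALSE)
  expect_lt(g$pval, 0.01)
  expect_gt(g$beta, 0.5)
})

test_that("fewer than two samples per condition is an error", {
  units <- c("A1", "B1", "B2")
  est <- matrix(100, 1, 3, dimnames = list("t1", units))
  boots <- setNames(lapply(units, function(u)
    matrix(100 + rnorm(10), 1, 10, dimnames = list("t1", NULL))), units)
  ab <- fake_abundance(est, boots)
  design <- data.frame(unit_id = units, condition = c("A", "B", "B"),
                       kind = "bulk_sample")
  expect_error(transcript_wald_test(ab, design), "at least two samples")
})

test_that("pure isoform switch at conserved totals: gene count test stays null, Lancaster fires", {
  tx <- tiny_txome()
  design <- make_design(4, 4)
  idx <- build_index(tx, k = 21)
  n_null <- 0L
  n_lanc <- 0L
  n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    truth <- sim_truth(tx, seed = 11, poison_fraction = c(A = 0.15, B = 0.6),
                       phi = 0.05)
    sim <- simulate_bulk_reads(tx, truth, design, 30000, seed = 300 + s)
    tcc <- suppressMessages(count_tccs(idx, sim))
    ab <- quantify_units(tcc, idx, read_length = 90, B = 30, seed = s)
    res <- diff_bulk(ab, design)
    gc <- res$genes_count
    gl <- res$genes_lancaster
    n_null <- n_null + (gc$pval[gc$gene_id == "SRSF5L"] > 0.05)
    n_lanc <- n_lanc + (gl$pval[gl$gene_id == "SRSF5L"] < 0.01)
  }
  expect_gte(n_null, n_seeds - 1L)
  expect_gte(n_lanc, n_seeds - 1L)
})
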