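# Single-cell switching inference: EC selection, logistic LRT, bootstrap CIs.

# fabricate a filtered single-cell tcc_matrix with given per-condition means
fake_sc_matrix <- function(n_per_cond = 100, means_A, means_B, gene = "g1",
                           seed = 1) {
  set.seed(seed)
  E <- length(means_A)
  cells <- c(sprintf("A%03d", seq_len(n_per_cond)),
             sprintf("B%03d", seq_len(n_per_cond)))
  m <- rbind(
    matrix(rpois(n_per_cond * E, rep(means_A, each = n_per_cond)), n_per_cond),
    matrix(rpois(n_per_cond * E, rep(means_B, each = n_per_cond)), n_per_cond))
  dimnames(m) <- list(cells, as.character(seq_len(E)))
  mat <- structure(list(
    counts = Matrix::Matrix(m, sparse = TRUE),
    ec_info = data.frame(ec_id = seq_len(E),
                         transcripts = sprintf("%s-t%d", gene, seq_len(E)),
                         genes = gene, n_tx = 1L, n_genes = 1L),
    mode = "single_cell"), class = "tcc_matrix")
  design <- data.frame(unit_id = cells,
                       condition = rep(c("A", "B"), each = n_per_cond),
                       kind = "cell")
  list(mat = mat, design = design)
}

test_that("EC selection applies the both-condition mean threshold", {
  # deterministic counts with exact per-condition means: EC1 = (0.06, 0.07)
  # kept, EC2 = (0.20, 0.01) dropped, EC3 = (2, 2) kept, EC4 = (0.001 = 0
  # here, 0) dropped
  n <- 100L
  cells <- c(sprintf("A%03d", 1:n), sprintf("B%03d", 1:n))
  m <- matrix(0, 2 * n, 4, dimnames = list(cells, as.character(1:4)))
  m[1:6, 1] <- 1; m[n + 1:7, 1] <- 1
  m[1:20, 2] <- 1; m[n + 1, 2] <- 1
  m[, 3] <- 2
  mat <- structure(list(
    counts = Matrix::Matrix(m, sparse = TRUE),
    ec_info = data.frame(ec_id = 1:4, transcripts = sprintf("g1-t%d", 1:4),
                         genes = "g1", n_tx = 1L, n_genes = 1L),
    mode = "single_cell"), class = "tcc_matrix")
  design <- data.frame(unit_id = cells, condition = rep(c("A", "B"), each = n),
                       kind = "cell")
  sl <- select_gene_tccs(mat, "g1", design, min_mean = 0.05)
  expect_setequal(sl$ec_ids, c(1L, 3L))
  # min_mean = 0 retains every EC of the gene with a positive mean somewhere
  sl0 <- select_gene_tccs(mat, "g1", design, min_mean = 0)
  expect_setequal(sl0$ec_ids, c(1L, 2L, 3L))
  # untestable gene reported as NULL
  expect_message(out <- select_gene_tccs(mat, "nope", design), "untestable")
  expect_null(out)
})

test_that("constant features give LRT 0 and p 1; nesting holds numerically", {
  fx <- fake_sc_matrix(60, means_A = c(2, 1), means_B = c(2, 1), seed = 7)
  sl <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  sl$counts[] <- 3 # all-constant features
  st <- tcc_logistic_test(sl)
  expect_equal(st$lrt, 0, tolerance = 1e-8)
  expect_equal(st$pval, 1)
  gt0 <- gene_total_test(sl)
  expect_equal(gt0$pval, 1)
  # adding features never increases the deviance
  sl2 <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  st2 <- tcc_logistic_test(sl2)
  gt <- gene_total_test(sl2)
  expect_gte(st2$lrt, -1e-6)
  expect_gte(gt$lrt, -1e-6)
  D_full <- st2$null_deviance - st2$lrt
  expect_lte(D_full, st2$null_deviance + 1e-6)
})

test_that("label swap leaves the switching p-value unchanged", {
  fx <- fake_sc_matrix(80, means_A = c(0.5, 2), means_B = c(1.5, 1), seed = 9)
  sl <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  p1 <- tcc_logistic_test(sl)$pval
  design2 <- fx$design
  design2$condition <- ifelse(design2$condition == "A", "B", "A")
  sl2 <- select_gene_tccs(fx$mat, "g1", design2, min_mean = 0)
  p2 <- tcc_logistic_test(sl2)$pval
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("permuted labels give approximately uniform p-values", {
  fx <- fake_sc_matrix(100, means_A = c(1, 0.5, 2), means_B = c(1, 0.5, 2),
                       seed = 11)
  set.seed(12)
  pv <- replicate(200, {
    d <- fx$design
    d$condition <- sample(d$condition)
    sl <- select_gene_tccs(fx$mat, "g1", d, min_mean = 0)
    tcc_logistic_test(sl)$pval
  })
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.01)
})

test_that("complete separation is detected and flagged", {
  fx <- fake_sc_matrix(30, means_A = 1, means_B = 1, seed = 3)
  sl <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  # a feature that perfectly predicts the condition
  sl$counts[, 1] <- rep(c(0, 50), each = 30)
  st <- tcc_logistic_test(sl)
  expect_true(st$separated)
  expect_prob(st$pval)
})

test_that("isoform switch at conserved totals: TCC test fires, gene total test does not", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  truth <- sim_truth(tx, seed = 2, poison_fraction = c(A = 0.2, B = 0.6),
                     error_rate = 0.005)
  # SRSF5L mean UMIs per cell ~ 3 at umis_per_cell = 3 * sum(mu) / mu_SRSF5L
  mu <- truth$mu$A
  upc <- 3 * sum(mu) / mu[["SRSF5L"]]
  sim <- simulate_sc_reads(tx, truth, n_cells_per_condition = 250,
                           umis_per_cell = upc, seed = 31, dup_rate = 0.1)
  tcc <- suppressMessages(count_tccs(idx, sim))
  tcc <- filter_sc(tcc, min_cell_total = 5)
  sl <- select_gene_tccs(tcc, "SRSF5L", sim$design, min_mean = 0.05)
  st <- tcc_logistic_test(sl)
  gt <- gene_total_test(sl)
  expect_lt(st$pval, 1e-6)
  expect_gt(gt$pval, 0.01)
  # the poison EC is enriched in the switched condition
  pois_ec <- which(vapply(strsplit(sl$ec_transcripts, ","), function(s)
    setequal(s, poison_transcripts(tx)), logical(1)))
  expect_length(pois_ec, 1L)
  expect_gt(st$direction[pois_ec], 0)
})

test_that("doubling the gene mean makes the total test significant", {
  fx <- fake_sc_matrix(250, means_A = c(1, 1), means_B = c(2, 2), seed = 21)
  sl <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  gt <- gene_total_test(sl)
  expect_lt(gt$pval, 0.01)
})

test_that("bootstrap CIs behave on constant, fixed-seed and degenerate input", {
  fx <- fake_sc_matrix(40, means_A = c(2, 1), means_B = c(2, 1), seed = 5)
  sl <- select_gene_tccs(fx$mat, "g1", fx$design, min_mean = 0)
  sl$counts[, 1] <- 5 # constant column
  ci <- ec_bootstrap_ci(sl, B = 200, seed = 2)
  c1 <- ci[ci$ec_id == sl$ec_ids[1], ]
  expect_equal(c1$lower, c(5, 5))
  expect_equal(c1$upper, c(5, 5))
  expect_true(all(ci$lower <= ci$mean + 1e-12 & ci$mean <= ci$upper + 1e-12))
  ci2 <- ec_bootstrap_ci(sl, B = 200, seed = 2)
  expect_identical(ci, ci2)
  # single-cell condition: degenerate flagged CI
  sl1 <- sl
  keep <- c(which(sl$y == "A")[1], which(sl$y == "B"))
  sl1$counts <- sl$counts[keep, , drop = FALSE]
  sl1$y <- droplevels(sl$y[keep])
  ci3 <- ec_bootstrap_ci(sl1, B = 50, seed = 1)
  expect_true(all(ci3$degenerate[ci3$condition == "A"]))
})

test_that("Bonferroni correction spans the genes tested in the run", {
  fx <- fake_sc_matrix(100, means_A = c(0.5, 2), means_B = c(2, 0.5), seed = 6)
  res <- test_isoform_switching(fx$mat, fx$design, min_mean = 0)
  expect_equal(res$p_bonf, pmin(1, res$pval * sum(!is.na(res$pval))))
})
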