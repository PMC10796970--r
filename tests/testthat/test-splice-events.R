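# Event enumeration, inclusion levels and the binomial LRT.

test_that("the SRSF5-like gene yields an RI event on intron 5 plus SE/A5SS/A3SS/MXE", {
  tx <- small_txome()
  ev <- enumerate_events(tx)
  srs <- ev[ev$gene_id == "SRSF5L", ]
  pi <- tx$poison[tx$poison$gene_id == "SRSF5L", ]
  # the poison-intron RI is reported (a second RI variant also exists
  # relative to the shifted acceptor of the A3SS isoform)
  ri <- srs[srs$type == "RI" & srs$var_start == pi$start &
              srs$var_end == pi$end, ]
  expect_equal(nrow(ri), 1L)
  expect_setequal(strsplit(ri$inclusion, ",")[[1]], poison_transcripts(tx))
  expect_true(all(c("SE", "A5SS", "A3SS", "MXE") %in% srs$type))
  # inclusion and skipping sets are disjoint and non-empty for every event
  for (i in seq_len(nrow(ev))) {
    a <- strsplit(ev$inclusion[i], ",")[[1]]
    b <- strsplit(ev$skipping[i], ",")[[1]]
    expect_gt(length(a), 0); expect_gt(length(b), 0)
    expect_length(intersect(a, b), 0L)
  }
})

test_that("single-isoform genes yield no events; an SE pair yields exactly one", {
  cfg1 <- toy_config(n_background_genes = 1L, include_srsf5_like = FALSE,
                     bg_isoform_range = c(1L, 1L))
  expect_equal(nrow(enumerate_events(make_toy_transcriptome(cfg1, seed = 2))), 0L)
  # hand-built two-isoform gene differing by one internal exon
  cfg2 <- toy_config(n_background_genes = 2L, include_srsf5_like = FALSE,
                     bg_isoform_range = c(2L, 2L))
  tx2 <- make_toy_transcriptome(cfg2, seed = 5) # gene 1 forced SE pair
  ev2 <- enumerate_events(tx2)
  expect_equal(sum(ev2$gene_id == "BG001" & ev2$type == "SE"), 1L)
})

test_that("effective lengths match brute-force enumeration of uniquely-resolving reads", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  ev <- enumerate_events(tx, idx, read_length = 90)
  pi <- tx$poison[tx$poison$gene_id == "SRSF5L", ]
  ri <- ev[ev$gene_id == "SRSF5L" & ev$type == "RI" &
             ev$var_start == pi$start & ev$var_end == pi$end, ]
  incl <- strsplit(ri$inclusion, ",")[[1]]
  skip <- strsplit(ri$skipping, ",")[[1]]
  brute_count <- function(form) {
    per_iso <- vapply(form, function(t) {
      s <- as.character(tx$tx_seq[[t]])
      n <- nchar(s) - 90 + 1
      rd <- substring(s, 1:n, 90:nchar(s))
      sum(vapply(rd, function(r) {
        ec <- brute_force_ec(tx, r, 21)
        !is.null(ec) && all(ec %in% form)
      }, logical(1)))
    }, numeric(1))
    round(mean(per_iso))
  }
  expect_equal(ri$l_I, brute_count(incl))
  expect_equal(ri$l_S, brute_count(skip))
  expect_gte(ri$l_I, 1)
  expect_gte(ri$l_S, 1)
})

test_that("event-informative reads are classified I / S / ambiguous correctly", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  ev <- enumerate_events(tx, idx, read_length = 90)
  pi <- tx$poison[tx$poison$gene_id == "SRSF5L", ]
  ri <- ev[ev$gene_id == "SRSF5L" & ev$type == "RI" &
             ev$var_start == pi$start & ev$var_end == pi$end, ]
  # exon5 end is at transcript position 600 of the canonical isoform
  r_skip <- tx_read(tx, "SRSF5L-201", 600 - 45, 90)   # spans exon5-exon6 junction
  r_incl <- tx_read(tx, "SRSF5L-207", 600 + 10, 90)   # inside retained intron 5
  r_amb <- tx_read(tx, "SRSF5L-201", 130, 90)         # constitutive exon 2
  reads <- list(u1 = setNames(c(r_skip, r_incl, r_amb), c("a", "b", "c")))
  tcc <- suppressMessages(count_tccs(idx, reads, mode = "bulk"))
  cnt <- count_event_reads(tcc, ri, idx)
  expect_equal(cnt$I, 1)
  expect_equal(cnt$S, 1)
  expect_equal(cnt$ambiguous, 1)
  # unknown transcripts in an event are rejected
  bad <- ri; bad$inclusion <- "nope-1"
  expect_error(count_event_reads(tcc, bad, idx), "unknown")
})

test_that("psi follows its closed form and symmetry properties", {
  expect_equal(psi(0, 10, 100, 100), 0)
  expect_equal(psi(7, 7, 120, 120), 0.5)
  expect_equal(psi(30, 10, 150, 100), 0.2 / (0.2 + 0.1), tolerance = 1e-12)
  expect_true(is.na(psi(0, 0, 10, 10)))
  # invariance to scaling and complementarity under swapping
  expect_equal(psi(30, 10, 150, 100), psi(300, 100, 150, 100))
  expect_equal(psi(30, 10, 150, 100) + psi(10, 30, 100, 150), 1)
})

test_that("the event LRT is zero for identical groups and calibrated under the null", {
  design <- make_design(4, 4)
  cnt <- data.frame(unit_id = design$unit_id, I = 30, S = 70)
  r <- event_group_lrt(cnt, design, l_I = 150, l_S = 100)
  expect_equal(r$lrt, 0, tolerance = 1e-10)
  expect_equal(r$pval, 1)
  expect_equal(r$psi_A, r$psi_B)
  # type-I rate at a common psi: simulate read-scale binomials
  set.seed(17)
  l_I <- 180; l_S <- 120
  th <- tccsplice:::.theta_of_psi(0.3, l_I, l_S)
  n_rej <- 0L
  B <- 400L
  for (b in seq_len(B)) {
    cb <- data.frame(unit_id = design$unit_id,
                     I = rbinom(8, 300, th))
    cb$S <- 300 - cb$I
    n_rej <- n_rej + (event_group_lrt(cb, design, l_I, l_S)$pval < 0.05)
  }
  expect_gt(n_rej / B, 0.02)
  expect_lt(n_rej / B, 0.09)
})

test_that("psi is recovered within 0.05 from simulated retained-intron reads", {
  tx <- small_txome()
  idx <- build_index(tx, k = 21)
  ev <- enumerate_events(tx, idx, read_length = 90)
  pi <- tx$poison[tx$poison$gene_id == "SRSF5L", ]
  ri <- ev[ev$gene_id == "SRSF5L" & ev$type == "RI" &
             ev$var_start == pi$start & ev$var_end == pi$end, ]
  truth <- sim_truth(tx, seed = 2, poison_fraction = c(A = 0.4, B = 0.4),
                     phi = 0, error_rate = 0)
  # true inclusion level = molecule fraction of the inclusion form among the
  # event-informative forms, from the known isoform proportions
  th <- truth$theta$A$SRSF5L
  incl <- strsplit(ri$inclusion, ",")[[1]]
  skip <- strsplit(ri$skipping, ",")[[1]]
  psi_true <- sum(th[incl]) / (sum(th[incl]) + sum(th[skip]))
  design <- make_design(2, 2)
  sim <- simulate_bulk_reads(tx, truth, design, 120000, seed = 13)
  tcc <- suppressMessages(count_tccs(idx, sim))
  cnt <- count_event_reads(tcc, ri, idx)
  expect_gte(sum(cnt$I + cnt$S), 1000)
  psi_hat <- psi(sum(cnt$I), sum(cnt$S), ri$l_I, ri$l_S)
  expect_lt(abs(psi_hat - psi_true), 0.05)
})

test_that("degenerate groups are reported untested", {
  design <- make_design(2, 2)
  cnt <- data.frame(unit_id = design$unit_id, I = c(0, 0, 3, 4),
                    S = c(0, 0, 5, 6))
  r <- event_group_lrt(cnt, design, 100, 100)
  expect_true(is.na(r$pval))
})
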