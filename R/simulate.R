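#' Simulation truth: isoform proportions, gene means and noise parameters
#'
#' Collects, per condition, the isoform proportion vectors (theta, summing to
#' one within each gene), the per-gene relative mean expression mu, the
#' replicate-level dispersion phi (gamma-multiplicative on gene means, shape
#' 1/phi; phi = 0 means pure multinomial sampling), the read length L and the
#' per-base substitution error rate.
#'
#' The default truth reproduces the study contrast on the SRSF5-like gene: the
#' poison-retained isoforms carry a total proportion of `poison_fraction[1]`
#' in condition A and `poison_fraction[2]` in condition B, while the gene mean
#' is identical in both conditions (conserved total gene expression).
#' Additional background genes can be switched between conditions by listing
#' them in `switch_genes` (their isoform proportion vector is reversed in
#' condition B).
#'
#' @param txome a `toy_transcriptome`.
#' @param seed integer seed controlling the randomly drawn proportions/means.
#' @param poison_fraction length-2 numeric: total poison-isoform proportion in
#'   conditions A and B for the SRSF5-like gene.
#' @param switch_genes character vector of background gene ids whose isoform
#'   proportions differ between conditions (reversed vector), at conserved
#'   gene mean.
#' @param phi replicate-level dispersion of the gamma perturbation.
#' @param read_length read length L (nt).
#' @param error_rate per-base substitution error rate.
#' @param conserve_total if TRUE (default) switching genes keep identical mean
#'   expression mu in both conditions.
#' @return a list of class `sim_truth` with elements `theta` (list `A`/`B`,
#'   each a list of named per-gene proportion vectors), `mu` (list `A`/`B` of
#'   named per-gene means), `phi`, `read_length`, `error_rate`,
#'   `switch_genes`, `conserve_total`.
#' @export
sim_truth <- function(txome, seed = 1L,
                      poison_fraction = c(A = 0.2, B = 0.6),
                      switch_genes = character(0),
                      phi = 0.1,
                      read_length = txome$config$read_length,
                      error_rate = 0.005,
                      conserve_total = TRUE) {
  set.seed(seed)
  tx <- txome$transcripts
  gene_ids <- unique(tx$gene_id)
  theta_A <- theta_B <- list()
  for (g in gene_ids) {
    ids <- tx$transcript_id[tx$gene_id == g]
    th <- rgamma(length(ids), shape = 1.5) # Dirichlet(1.5) draw
    th <- th / sum(th)
    names(th) <- ids
    if (g == "SRSF5L" && any(tx$biotype[tx$gene_id == g] == "poison_retained")) {
      pois <- tx$biotype[tx$gene_id == g] == "poison_retained"
      mk <- function(pf) {
        v <- numeric(length(ids))
        v[pois] <- pf / sum(pois)
        v[!pois] <- (1 - pf) / sum(!pois)
        names(v) <- ids
        v
      }
      theta_A[[g]] <- mk(poison_fraction[[1]])
      theta_B[[g]] <- mk(poison_fraction[[2]])
    } else if (g %in% switch_genes && length(ids) >= 2L) {
      theta_A[[g]] <- th
      thB <- rev(th)
      names(thB) <- ids
      theta_B[[g]] <- thB
    } else {
      theta_A[[g]] <- theta_B[[g]] <- th
    }
  }
  mu <- exp(rnorm(length(gene_ids), mean = 0, sd = 0.7))
  names(mu) <- gene_ids
  if ("SRSF5L" %in% gene_ids) mu[["SRSF5L"]] <- 1
  out <- list(theta = list(A = theta_A, B = theta_B),
              mu = list(A = mu, B = mu),
              phi = phi, read_length = as.integer(read_length),
              error_rate = error_rate,
              switch_genes = union(switch_genes,
                                   if ("SRSF5L" %in% gene_ids &&
                                       poison_fraction[[1]] != poison_fraction[[2]])
                                     "SRSF5L" else character(0)),
              conserve_total = conserve_total)
  class(out) <- "sim_truth"
  out
}

#' Two-group design table
#'
#' @param n_A,n_B number of units per condition.
#' @param kind `"bulk_sample"` or `"cell"`.
#' @return data.frame with columns `unit_id`, `condition`, `kind`.
#' @export
make_design <- function(n_A, n_B, kind = c("bulk_sample", "cell")) {
  kind <- match.arg(kind)
  if (n_A < 1L || n_B < 1L) stop("both conditions need at least one unit")
  data.frame(
    unit_id = c(sprintf("A%d", seq_len(n_A)), sprintf("B%d", seq_len(n_B))),
    condition = rep(c("A", "B"), c(n_A, n_B)),
    kind = kind, stringsAsFactors = FALSE)
}

# per-transcript read-sampling weights for one unit in condition `cond`,
# with an optional per-transcript gamma perturbation vector gfac
.tx_weights <- function(txome, truth, cond, gfac = NULL) {
  tx <- txome$transcripts
  L <- truth$read_length
  th <- unlist(truth$theta[[cond]], use.names = FALSE)
  th_names <- unlist(lapply(truth$theta[[cond]], names), use.names = FALSE)
  th <- stats::setNames(th, th_names)[tx$transcript_id]
  mu <- truth$mu[[cond]][tx$gene_id]
  if (is.null(gfac)) gfac <- rep(1, nrow(tx))
  efflen <- pmax(tx$length - L + 1L, 1L)
  bad <- th > 0 & tx$length < L
  if (any(bad)) {
    stop(sprintf("read length %d exceeds transcript '%s' (%d nt) which has positive sampling probability",
                 L, tx$transcript_id[which(bad)[1]], tx$length[which(bad)[1]]))
  }
  w <- mu * gfac * th * efflen
  stats::setNames(w, tx$transcript_id)
}

#' Simulate bulk RNA-seq reads
#'
#' Per sample, reads are drawn by (i) sampling a transcript with probability
#' proportional to mu_g * theta_c(t) * (len(t) - L + 1), with an independent
#' per-transcript gamma-multiplicative replicate perturbation (shape 1/phi,
#' mean 1, so marginal transcript counts are negative-binomial with
#' dispersion phi; phi = 0 is pure multinomial), (ii) a uniform start
#' position, and (iii) i.i.d.
#' substitution errors at the configured rate. Every read's origin is
#' recorded in the per-sample truth table.
#'
#' @param txome a `toy_transcriptome`.
#' @param truth a [sim_truth()] object.
#' @param design a [make_design()] table with `kind == "bulk_sample"`.
#' @param n_reads_per_sample reads per sample (>= 1).
#' @param seed integer seed; fixed `(inputs, seed)` reproduce the simulation
#'   (and FASTQ files) byte-for-byte.
#' @param fastq_dir optional directory; when given, per-sample FASTQ
#'   (Phred+33, constant quality "I") and a TSV truth table are written.
#' @return object of class `bulk_sim`: list with `design`, `reads` (named
#'   list of character vectors per sample), `truth` (named list of per-sample
#'   data.frames: `read_id`, `transcript_id`, `start`), and `truth_counts`
#'   (transcripts x samples matrix of true origin counts).
#' @export
simulate_bulk_reads <- function(txome, truth, design, n_reads_per_sample,
                                seed = 1L, fastq_dir = NULL) {
  stopifnot(n_reads_per_sample >= 1L)
  set.seed(seed)
  tx <- txome$transcripts
  L <- truth$read_length
  seqs <- as.character(txome$tx_seq[tx$transcript_id])
  reads <- list()
  truth_tab <- list()
  counts_mat <- matrix(0L, nrow(tx), nrow(design),
                       dimnames = list(tx$transcript_id, design$unit_id))
  gene_ids <- unique(tx$gene_id)
  for (i in seq_len(nrow(design))) {
    s <- design$unit_id[i]
    cond <- design$condition[i]
    # independent gamma draw per transcript: the marginal transcript counts
    # are negative-binomial with dispersion phi (standard NB-equivalent
    # generator, matching the overdispersion assumption of the bulk test)
    gfac <- if (truth$phi > 0) {
      rgamma(nrow(tx), shape = 1 / truth$phi, rate = 1 / truth$phi)
    } else NULL
    w <- .tx_weights(txome, truth, cond, gfac)
    cnt <- as.integer(rmultinom(1L, n_reads_per_sample, w))
    sim <- .sim_reads_cpp(seqs, cnt, L, truth$error_rate)
    ids <- sprintf("%s_r%06d", s, seq_along(sim$read))
    reads[[s]] <- stats::setNames(as.character(sim$read), ids)
    truth_tab[[s]] <- data.frame(
      read_id = ids, transcript_id = tx$transcript_id[sim$origin],
      start = sim$start, stringsAsFactors = FALSE)
    counts_mat[, s] <- cnt
  }
  out <- list(design = design, reads = reads, truth = truth_tab,
              truth_counts = counts_mat, read_length = L)
  class(out) <- "bulk_sim"
  if (!is.null(fastq_dir)) write_bulk_fastq(out, fastq_dir)
  out
}

#' @rdname simulate_bulk_reads
#' @param sim a `bulk_sim` object.
#' @param dir output directory.
#' @export
write_bulk_fastq <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$reads)) {
    .write_fastq(sim$reads[[s]], file.path(dir, paste0(s, ".fastq")))
    write.table(sim$truth[[s]], file.path(dir, paste0(s, "_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

.write_fastq <- function(reads, path) {
  # Phred+33 constant quality 'I' (Q40)
  qual <- strrep("I", nchar(reads))
  con <- file(path, "wb") # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

.encode_base4 <- function(ix, width) {
  # deterministic DNA encoding of non-negative integers, fixed width
  bases <- c("A", "C", "G", "T")
  out <- character(length(ix))
  for (j in seq_len(width)) {
    out <- paste0(bases[(ix %% 4L) + 1L], out)
    ix <- ix %/% 4L
  }
  out
}

#' Simulate barcoded single-cell reads with UMIs
#'
#' Each read carries a cell barcode and a UMI prepended to the cDNA fragment.
#' Per cell, gene-level UMI totals are Poisson with mean proportional to the
#' gene's mu in that condition; when the truth conserves totals
#' (`conserve_total`), switching genes draw their per-cell totals from the
#' same distribution in both conditions and only the isoform proportions
#' differ. Barcodes are condition-disjoint by construction (cells are numbered
#' across conditions and the number is base-4 encoded). UMIs are drawn
#' without replacement within each cell. PCR duplicates are emitted at rate
#' `dup_rate`: each molecule yields 1 + Geometric(1 - dup_rate) reads.
#'
#' @param txome a `toy_transcriptome`.
#' @param truth a [sim_truth()] object.
#' @param n_cells_per_condition integer, or named length-2 vector `c(A=,B=)`.
#' @param umis_per_cell expected total molecules per cell (across all genes).
#' @param seed integer seed.
#' @param dup_rate PCR duplication rate in `[0, 1)`.
#' @param bc_len,umi_len barcode and UMI lengths (nt); the sequencing chemistry
#'   is configurable rather than fixed.
#' @param fastq_path optional FASTQ output file (barcode+UMI+cDNA reads).
#' @return object of class `sc_sim`: list with `design` (cells), `reads`
#'   (data.frame: `read_id`, `barcode`, `umi`, `cdna`), `truth` (one row per
#'   molecule: cell, condition, transcript, start), `bc_len`, `umi_len`,
#'   `read_length`.
#' @export
simulate_sc_reads <- function(txome, truth, n_cells_per_condition,
                              umis_per_cell, seed = 1L, dup_rate = 0,
                              bc_len = 12L, umi_len = 10L, fastq_path = NULL) {
  if (length(n_cells_per_condition) == 1L)
    n_cells_per_condition <- c(A = n_cells_per_condition, B = n_cells_per_condition)
  nA <- as.integer(n_cells_per_condition[["A"]])
  nB <- as.integer(n_cells_per_condition[["B"]])
  if (nA < 1L || nB < 1L)
    stop("each condition needs at least one cell (n_cells_per_condition)")
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must be in [0, 1)")
  set.seed(seed)
  tx <- txome$transcripts
  L <- truth$read_length
  seqs_len <- stats::setNames(tx$length, tx$transcript_id)
  if (any(seqs_len < L))
    stop(sprintf("read length %d exceeds transcript '%s'",
                 L, names(which(seqs_len < L))[1]))
  seqs <- stats::setNames(as.character(txome$tx_seq[tx$transcript_id]),
                          tx$transcript_id)
  design <- make_design(nA, nB, kind = "cell")
  barcodes <- .encode_base4(seq_len(nA + nB), bc_len)
  if (anyDuplicated(barcodes))
    stop("barcode collision across conditions") # cannot happen by construction
  design$unit_id <- barcodes
  gene_ids <- unique(tx$gene_id)
  mol <- list()
  for (i in seq_len(nA + nB)) {
    cond <- design$condition[i]
    mu <- truth$mu[[cond]][gene_ids]
    lam <- umis_per_cell * mu / sum(mu)
    ng <- rpois(length(gene_ids), lam)
    if (sum(ng) == 0L) next
    tx_of_mol <- unlist(lapply(which(ng > 0L), function(gi) {
      th <- truth$theta[[cond]][[gene_ids[gi]]]
      sample(names(th), ng[gi], replace = TRUE, prob = th)
    }), use.names = FALSE)
    n_mol <- length(tx_of_mol)
    umi_ix <- sample.int(4L^umi_len, n_mol) - 1L # unique within the cell
    mol[[length(mol) + 1L]] <- data.frame(
      barcode = barcodes[i], condition = cond, transcript_id = tx_of_mol,
      umi = .encode_base4(umi_ix, umi_len),
      start = floor(runif(n_mol) * (seqs_len[tx_of_mol] - L + 1L)),
      stringsAsFactors = FALSE)
  }
  mol <- do.call(rbind, mol)
  rownames(mol) <- NULL
  # PCR duplication: geometric number of extra copies per molecule
  copies <- if (dup_rate > 0) 1L + stats::rgeom(nrow(mol), 1 - dup_rate) else
    rep(1L, nrow(mol))
  rd <- mol[rep(seq_len(nrow(mol)), copies), , drop = FALSE]
  rownames(rd) <- NULL
  cdna <- substring(seqs[rd$transcript_id], rd$start + 1L, rd$start + L)
  # substitution errors, independently per read copy
  if (truth$error_rate > 0) {
    nerr <- rbinom(length(cdna), L, truth$error_rate)
    for (j in which(nerr > 0L)) {
      pos <- sample.int(L, nerr[j])
      ch <- strsplit(cdna[j], "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      cdna[j] <- paste(ch, collapse = "")
    }
  }
  reads <- data.frame(
    read_id = sprintf("sc_r%07d", seq_along(cdna)),
    barcode = rd$barcode, umi = rd$umi, cdna = unname(cdna),
    stringsAsFactors = FALSE)
  out <- list(design = design, reads = reads, truth = mol,
              bc_len = bc_len, umi_len = umi_len, read_length = L,
              dup_rate = dup_rate)
  class(out) <- "sc_sim"
  if (!is.null(fastq_path)) write_sc_fastq(out, fastq_path)
  out
}

#' @rdname simulate_sc_reads
#' @param sim an `sc_sim` object.
#' @param path FASTQ output file.
#' @export
write_sc_fastq <- function(sim, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  full <- paste0(sim$reads$barcode, sim$reads$umi, sim$reads$cdna)
  .write_fastq(stats::setNames(full, sim$reads$read_id), path)
  truth_path <- sub("\\.fastq$", "_truth.tsv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
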