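# Pipeline orchestration: stages simulate -> index -> quant -> diff-bulk /
# events / diff-sc, driven by a single structured config with reproducible
# seeds, per-stage logging and artifact checksums.

#' Default pipeline configuration
#'
#' A nested list describing one full run: simulation block (transcriptome
#' geometry, proportions, noise, sample/cell numbers), alignment block (k,
#' thresholds) and statistics block (bootstrap counts, FDR level,
#' single-cell selection threshold). Values mirror the package defaults at a
#' small demonstration scale.
#'
#' @param workdir working directory for all artifacts.
#' @param seed integer master seed; stage seeds derive from it.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(workdir = "tccsplice_run", seed = 1L) {
  cfg <- list(
    paths = list(workdir = workdir),
    seed = as.integer(seed),
    simulate = list(
      n_background_genes = 10L,
      poison_fraction = c(A = 0.2, B = 0.6),
      switch_genes = character(0),
      phi = 0.1,
      error_rate = 0.005,
      read_length = 90L,
      n_samples_per_condition = 4L,
      n_reads_per_sample = 50000L,
      n_cells_per_condition = 120L,
      umis_per_cell = 60L,
      dup_rate = 0.1,
      bc_len = 12L,
      umi_len = 10L
    ),
    align = list(
      k = 21L,
      min_cell_total = 20L,
      min_detect_frac = 0.01,
      min_mean = 0.01
    ),
    stats = list(
      bootstrap_bulk = 30L,
      bootstrap_sc = 1000L,
      fdr_level = 0.05,
      sc_min_mean = 0.05,
      sc_min_cells = 20L
    )
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (blk in names(base)) {
    if (is.list(base[[blk]]) && !is.null(cfg[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else if (!is.null(cfg[[blk]])) base[[blk]] <- cfg[[blk]]
  }
  if (!is.null(base$simulate$poison_fraction))
    base$simulate$poison_fraction <-
      stats::setNames(as.numeric(base$simulate$poison_fraction), c("A", "B"))
  base
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.validate_run_config <- function(config) {
  need <- c("paths", "seed", "simulate", "align", "stats")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing required blocks: ", paste(miss, collapse = ", "))
  if (length(config$simulate$poison_fraction) != 2L)
    stop("simulate$poison_fraction must give exactly two condition values (single two-group contrast per run)")
  invisible(TRUE)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.artifact_checksums <- function(paths) {
  ok <- file.exists(paths)
  sums <- rep(NA_character_, length(paths))
  sums[ok] <- unname(tools::md5sum(paths[ok]))
  data.frame(path = paths, md5 = sums, stringsAsFactors = FALSE)
}

.require_artifact <- function(path, producer) {
  missing <- path[!file.exists(path)]
  if (length(missing))
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 missing[1], producer))
  invisible(TRUE)
}

.header_comment <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  sprintf("# tccsplice %s; seed=%d; config_md5=%s",
          as.character(utils::packageVersion("tccsplice")), config$seed,
          unname(tools::md5sum(tmp)))
}

.write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(config), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

.read_stage_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run pipeline stages
#'
#' Executes one subcommand of the pipeline: `simulate` (toy reference +
#' bulk/single-cell reads with truth tables), `index` (k-mer index build and
#' stats), `quant` (TCC matrices and EM abundances with bootstraps),
#' `diff-bulk` (transcript Wald tests, Lancaster and count gene
#' aggregations), `events` (splicing-event enumeration and group LRT),
#' `diff-sc` (single-cell switching tests and EC bootstrap CIs), or `all`
#' (the full chain). Every stage logs its inputs/outputs with checksums to
#' stderr; result tables carry a header comment recording version, seed and
#' config hash. A missing upstream artifact raises an error naming the stage
#' that produces it.
#'
#' @param stage one of `simulate`, `index`, `quant`, `diff-bulk`, `events`,
#'   `diff-sc`, `all`.
#' @param config a `run_config` list (see [default_run_config()]).
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, a character vector of artifact paths written by the
#'   stage(s).
#' @export
run_pipeline <- function(stage = c("all", "simulate", "index", "quant",
                                   "diff-bulk", "events", "diff-sc"),
                         config = default_run_config(), seed = NULL) {
  stage <- match.arg(stage)
  .validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  wd <- config$paths$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    paths <- c(run_pipeline("simulate", config),
               run_pipeline("index", config),
               run_pipeline("quant", config),
               run_pipeline("diff-bulk", config),
               run_pipeline("events", config),
               run_pipeline("diff-sc", config))
    return(invisible(paths))
  }
  switch(stage,
         simulate = .stage_simulate(config),
         index = .stage_index(config),
         quant = .stage_quant(config),
         `diff-bulk` = .stage_diff_bulk(config),
         events = .stage_events(config),
         `diff-sc` = .stage_diff_sc(config))
}

.cfg_txome <- function(config) {
  sim <- config$simulate
  make_toy_transcriptome(
    toy_config(n_background_genes = sim$n_background_genes,
               read_length = sim$read_length, k = config$align$k),
    seed = config$seed)
}

.cfg_truth <- function(config, txome) {
  sim <- config$simulate
  sim_truth(txome, seed = config$seed,
            poison_fraction = sim$poison_fraction,
            switch_genes = sim$switch_genes,
            phi = sim$phi, read_length = sim$read_length,
            error_rate = sim$error_rate)
}

.stage_simulate <- function(config) {
  wd <- config$paths$workdir
  sim <- config$simulate
  txome <- .cfg_txome(config)
  ref <- write_transcriptome(txome, file.path(wd, "ref"))
  truth <- .cfg_truth(config, txome)
  design <- make_design(sim$n_samples_per_condition,
                        sim$n_samples_per_condition)
  bulk <- simulate_bulk_reads(txome, truth, design, sim$n_reads_per_sample,
                              seed = config$seed + 1L,
                              fastq_dir = file.path(wd, "bulk"))
  .write_stage_table(design, file.path(wd, "bulk", "design.tsv"), config)
  sc <- simulate_sc_reads(txome, truth, sim$n_cells_per_condition,
                          sim$umis_per_cell, seed = config$seed + 2L,
                          dup_rate = sim$dup_rate, bc_len = sim$bc_len,
                          umi_len = sim$umi_len,
                          fastq_path = file.path(wd, "sc", "reads.fastq"))
  .write_stage_table(sc$design, file.path(wd, "sc", "design.tsv"), config)
  paths <- c(ref, file.path(wd, "bulk", "design.tsv"),
             file.path(wd, "sc", "design.tsv"),
             file.path(wd, "sc", "reads.fastq"))
  cs <- .artifact_checksums(paths)
  for (i in seq_len(nrow(cs)))
    .stage_log("simulate", "wrote %s (md5 %s)", cs$path[i], cs$md5[i])
  invisible(paths)
}

.load_txome_from_ref <- function(config) {
  wd <- config$paths$workdir
  .require_artifact(file.path(wd, "ref", "transcripts.fa"), "simulate")
  # the reference is regenerated deterministically from (config, seed); the
  # on-disk FASTA is authoritative and checked against it
  txome <- .cfg_txome(config)
  disk <- Biostrings::readDNAStringSet(file.path(wd, "ref", "transcripts.fa"))
  if (!identical(sort(names(disk)), sort(txome$transcripts$transcript_id)))
    stop("reference on disk does not match the configuration; rerun 'simulate'")
  txome
}

.stage_index <- function(config) {
  wd <- config$paths$workdir
  txome <- .load_txome_from_ref(config)
  idx <- build_index(txome, k = config$align$k)
  st <- index_stats(idx)
  df <- data.frame(k = st$k, n_transcripts = st$n_transcripts,
                   n_kmers = st$n_kmers,
                   n_kmer_occurrences = st$n_kmer_occurrences)
  p <- file.path(wd, "index_stats.tsv")
  .write_stage_table(df, p, config)
  .stage_log("index", "k=%d over %d transcripts (%s distinct k-mers)",
             st$k, st$n_transcripts, format(st$n_kmers, big.mark = ","))
  invisible(p)
}

.stage_quant <- function(config) {
  wd <- config$paths$workdir
  sim <- config$simulate
  .require_artifact(file.path(wd, "index_stats.tsv"), "index")
  txome <- .load_txome_from_ref(config)
  idx <- build_index(txome, k = config$align$k)
  design <- .read_stage_table(file.path(wd, "bulk", "design.tsv"))
  fq <- file.path(wd, "bulk", paste0(design$unit_id, ".fastq"))
  .require_artifact(fq, "simulate")
  reads <- lapply(fq, function(f) {
    x <- Biostrings::readDNAStringSet(f, format = "fastq")
    stats::setNames(as.character(x), names(x))
  })
  names(reads) <- design$unit_id
  tcc_bulk <- count_tccs(idx, reads, mode = "bulk")
  write_tcc(tcc_bulk, file.path(wd, "quant", "bulk_tcc"))
  ab <- quantify_units(tcc_bulk, idx, read_length = sim$read_length,
                       B = config$stats$bootstrap_bulk,
                       seed = config$seed + 3L)
  write_abundance(ab, file.path(wd, "quant", "bulk"))
  # single cell: split barcode/UMI/cDNA from the read structure
  scfq <- file.path(wd, "sc", "reads.fastq")
  .require_artifact(scfq, "simulate")
  x <- Biostrings::readDNAStringSet(scfq, format = "fastq")
  full <- as.character(x)
  sc_reads <- data.frame(
    read_id = names(x),
    barcode = substr(full, 1L, sim$bc_len),
    umi = substr(full, sim$bc_len + 1L, sim$bc_len + sim$umi_len),
    cdna = substring(full, sim$bc_len + sim$umi_len + 1L),
    stringsAsFactors = FALSE)
  tcc_sc <- count_tccs(idx, sc_reads, mode = "single_cell")
  tcc_sc <- filter_sc(tcc_sc, min_cell_total = config$align$min_cell_total,
                      min_detect_frac = config$align$min_detect_frac,
                      min_mean = config$align$min_mean)
  write_tcc(tcc_sc, file.path(wd, "quant", "sc_tcc"))
  paths <- c(file.path(wd, "quant", "bulk_tcc.mtx"),
             file.path(wd, "quant", "bulk.abundance.tsv"),
             file.path(wd, "quant", "sc_tcc.mtx"))
  cs <- .artifact_checksums(paths)
  for (i in seq_len(nrow(cs)))
    .stage_log("quant", "wrote %s (md5 %s)", cs$path[i], cs$md5[i])
  invisible(paths)
}

.rebuild_bulk_abundance <- function(config, txome, idx) {
  wd <- config$paths$workdir
  sim <- config$simulate
  .require_artifact(file.path(wd, "quant", "bulk.abundance.tsv"), "quant")
  design <- .read_stage_table(file.path(wd, "bulk", "design.tsv"))
  reads <- lapply(file.path(wd, "bulk", paste0(design$unit_id, ".fastq")),
                  function(f) {
                    x <- Biostrings::readDNAStringSet(f, format = "fastq")
                    stats::setNames(as.character(x), names(x))
                  })
  names(reads) <- design$unit_id
  tcc <- count_tccs(idx, reads, mode = "bulk")
  list(tcc = tcc,
       ab = quantify_units(tcc, idx, read_length = sim$read_length,
                           B = config$stats$bootstrap_bulk,
                           seed = config$seed + 3L),
       design = design)
}

.stage_diff_bulk <- function(config) {
  wd <- config$paths$workdir
  txome <- .load_txome_from_ref(config)
  idx <- build_index(txome, k = config$align$k)
  q <- .rebuild_bulk_abundance(config, txome, idx)
  res <- diff_bulk(q$ab, q$design)
  p1 <- file.path(wd, "results", "bulk_transcripts.tsv")
  p2 <- file.path(wd, "results", "bulk_genes_lancaster.tsv")
  p3 <- file.path(wd, "results", "bulk_genes_count.tsv")
  dir.create(file.path(wd, "results"), showWarnings = FALSE)
  .write_stage_table(res$transcripts, p1, config)
  .write_stage_table(res$genes_lancaster, p2, config)
  .write_stage_table(res$genes_count, p3, config)
  .stage_log("diff-bulk", "%d genes at q < %g (Lancaster aggregation)",
             sum(res$genes_lancaster$qval < config$stats$fdr_level,
                 na.rm = TRUE), config$stats$fdr_level)
  invisible(c(p1, p2, p3))
}

.stage_events <- function(config) {
  wd <- config$paths$workdir
  txome <- .load_txome_from_ref(config)
  idx <- build_index(txome, k = config$align$k)
  q <- .rebuild_bulk_abundance(config, txome, idx)
  evs <- enumerate_events(txome, idx, read_length = config$simulate$read_length)
  res <- test_splice_events(q$tcc, evs, q$design, idx)
  dir.create(file.path(wd, "results"), showWarnings = FALSE)
  p1 <- file.path(wd, "results", "events.tsv")
  p2 <- file.path(wd, "results", "event_tests.tsv")
  .write_stage_table(as.data.frame(evs), p1, config)
  .write_stage_table(res, p2, config)
  .stage_log("events", "%d events enumerated, %d significant at FDR < %g",
             nrow(evs), sum(res$qval < config$stats$fdr_level, na.rm = TRUE),
             config$stats$fdr_level)
  invisible(c(p1, p2))
}

.stage_diff_sc <- function(config) {
  wd <- config$paths$workdir
  sim <- config$simulate
  .require_artifact(file.path(wd, "quant", "sc_tcc.mtx"), "quant")
  txome <- .load_txome_from_ref(config)
  idx <- build_index(txome, k = config$align$k)
  # recount from FASTQ to restore the EC registry of this run
  scfq <- file.path(wd, "sc", "reads.fastq")
  x <- Biostrings::readDNAStringSet(scfq, format = "fastq")
  full <- as.character(x)
  sc_reads <- data.frame(
    read_id = names(x),
    barcode = substr(full, 1L, sim$bc_len),
    umi = substr(full, sim$bc_len + 1L, sim$bc_len + sim$umi_len),
    cdna = substring(full, sim$bc_len + sim$umi_len + 1L),
    stringsAsFactors = FALSE)
  tcc <- count_tccs(idx, sc_reads, mode = "single_cell")
  tcc <- filter_sc(tcc, min_cell_total = config$align$min_cell_total,
                   min_detect_frac = config$align$min_detect_frac,
                   min_mean = config$align$min_mean)
  design <- .read_stage_table(file.path(wd, "sc", "design.tsv"))
  res <- test_isoform_switching(tcc, design,
                                min_mean = config$stats$sc_min_mean,
                                min_cells = config$stats$sc_min_cells)
  dir.create(file.path(wd, "results"), showWarnings = FALSE)
  p1 <- file.path(wd, "results", "sc_switch_tests.tsv")
  .write_stage_table(res, p1, config)
  sl <- suppressMessages(select_gene_tccs(tcc, "SRSF5L", design,
                                          min_mean = config$stats$sc_min_mean))
  paths <- p1
  if (!is.null(sl)) {
    ci <- ec_bootstrap_ci(sl, B = config$stats$bootstrap_sc,
                          seed = config$seed + 4L)
    p2 <- file.path(wd, "results", "sc_ec_ci.tsv")
    .write_stage_table(ci, p2, config)
    paths <- c(p1, p2)
  }
  .stage_log("diff-sc", "tested %d genes", sum(!is.na(res$pval)))
  invisible(paths)
}
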