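#' Build a k-mer index over a transcriptome
#'
#' Indexes every k-mer of every transcript (forward strand, no canonical
#' collapsing) and maps it to the sorted set of transcripts containing it.
#' A transcript of length n contributes exactly n - k + 1 k-mer occurrences.
#' The index also carries the run's equivalence-class registry: EC ids are
#' assigned in order of first observation and are stable for the lifetime of
#' the index.
#'
#' @param x a `toy_transcriptome`, or a named [Biostrings::DNAStringSet] (or
#'   named character vector) of transcript sequences.
#' @param k k-mer length in nt; must satisfy `8 <= k <=` shortest transcript.
#' @param tx2gene optional data.frame (`transcript_id`, `gene_id`) when `x` is
#'   a raw sequence set; defaults to one gene per transcript.
#' @return object of class `kmer_index`.
#' @export
build_index <- function(x, k = 21L, tx2gene = NULL) {
  if (inherits(x, "toy_transcriptome")) {
    seqs <- as.character(x$tx_seq)
    tx2gene <- x$transcripts[, c("transcript_id", "gene_id")]
    seqs <- seqs[tx2gene$transcript_id]
  } else {
    nm <- names(x)
    seqs <- stats::setNames(as.character(x), nm)
    if (is.null(names(seqs))) stop("transcript sequences must be named")
    if (is.null(tx2gene)) {
      tx2gene <- data.frame(transcript_id = names(seqs),
                            gene_id = names(seqs), stringsAsFactors = FALSE)
    }
  }
  k <- as.integer(k)
  if (k < 8L) stop("k must be at least 8")
  lens <- nchar(seqs)
  if (k > min(lens)) {
    short <- names(seqs)[which.min(lens)]
    stop(sprintf("k = %d exceeds the length (%d nt) of the shortest transcript '%s'",
                 k, min(lens), short))
  }
  ptr <- .build_index_cpp(unname(seqs), names(seqs),
                          tx2gene$gene_id[match(names(seqs),
                                                tx2gene$transcript_id)], k)
  df <- as.data.frame(.index_tx_cpp(ptr), stringsAsFactors = FALSE)
  out <- list(ptr = ptr, k = k, transcripts = df,
              seqs = stats::setNames(unname(seqs), names(seqs)))
  class(out) <- "kmer_index"
  out
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- .index_stats_cpp(x$ptr)
  cat(sprintf("kmer_index: k=%d, %d transcripts, %.0f distinct k-mers, %d ECs observed\n",
              st$k, st$n_transcripts, st$n_kmers, st$n_ecs))
  invisible(x)
}

#' Index statistics
#'
#' @param index a `kmer_index`.
#' @return list with `k`, `n_transcripts`, `n_kmers` (distinct),
#'   `n_kmer_occurrences` (total indexed occurrences), `n_ecs`.
#' @export
index_stats <- function(index) .index_stats_cpp(index$ptr)

#' Pseudoalign a single read
#'
#' Returns the equivalence class of the read: the intersection of the
#' transcript sets of all of its k-mers that are present in the index (absent
#' k-mers are skipped). If no k-mer is present, or the intersection is empty,
#' the read is unassigned and `NULL` is returned.
#'
#' @param index a `kmer_index`.
#' @param read a single read sequence (length >= k).
#' @return character vector of compatible transcript ids (sorted in index
#'   order), or `NULL` for an unassigned read.
#' @export
pseudoalign_read <- function(index, read) {
  if (nchar(read) < index$k)
    stop(sprintf("read is shorter than k = %d", index$k))
  ec <- .align_reads_cpp(index$ptr, read)
  if (ec == 0L) return(NULL)
  index$transcripts$transcript_id[ec_transcript_sets(index)[[ec]]]
}

#' Pseudoalign a batch of reads to EC ids
#'
#' @param index a `kmer_index`.
#' @param reads character vector of reads.
#' @return integer vector of EC ids (registry of the index); `NA` for
#'   unassigned reads.
#' @export
pseudoalign <- function(index, reads) {
  ec <- .align_reads_cpp(index$ptr, reads)
  ec[ec == 0L] <- NA_integer_
  ec
}

# list of integer transcript-index vectors, one per registered EC
ec_transcript_sets <- function(index) .ec_sets_cpp(index$ptr)

#' Equivalence-class registry of an index
#'
#' @param index a `kmer_index`.
#' @return data.frame: `ec_id`, `transcripts` (comma-separated ids), `genes`
#'   (comma-separated), `n_tx`, `n_genes`.
#' @export
ec_registry <- function(index) {
  sets <- ec_transcript_sets(index)
  tx <- index$transcripts
  if (length(sets) == 0L)
    return(data.frame(ec_id = integer(0), transcripts = character(0),
                      genes = character(0), n_tx = integer(0),
                      n_genes = integer(0)))
  data.frame(
    ec_id = seq_along(sets),
    transcripts = vapply(sets, function(s)
      paste(tx$transcript_id[s], collapse = ","), character(1)),
    genes = vapply(sets, function(s)
      paste(unique(tx$gene_id[s]), collapse = ","), character(1)),
    n_tx = lengths(sets),
    n_genes = vapply(sets, function(s) length(unique(tx$gene_id[s])),
                     integer(1)),
    stringsAsFactors = FALSE)
}

#' Count transcript compatibility counts (TCCs)
#'
#' Bulk mode counts every assigned read per sample. Single-cell mode first
#' discards reads whose equivalence class spans more than one gene
#' (multi-gene multi-mappers), then collapses duplicate (cell, UMI) molecules
#' to a single count; when the copies of a (cell, UMI) pair disagree on the
#' EC, the EC of the lexicographically first read identifier is kept (and the
#' conflict is logged). Unassigned reads are tallied and reported.
#'
#' @param index a `kmer_index`.
#' @param reads bulk mode: a named list of character vectors (one per
#'   sample), or a `bulk_sim` object. Single-cell mode: a data.frame with
#'   columns `read_id`, `barcode`, `umi`, `cdna`, or an `sc_sim` object.
#' @param mode `"bulk"` or `"single_cell"`; inferred from simulation objects.
#' @return object of class `tcc_matrix`: list with `counts` (sparse
#'   units x ECs matrix, column names are EC ids), `ec_info` (the
#'   [ec_registry()] rows present in the matrix), `mode`, `n_unassigned`,
#'   and in single-cell mode `n_multigene` and `n_umi_conflicts`.
#' @export
count_tccs <- function(index, reads, mode = c("bulk", "single_cell")) {
  if (inherits(reads, "bulk_sim")) { mode <- "bulk"; reads <- reads$reads }
  else if (inherits(reads, "sc_sim")) { mode <- "single_cell"; reads <- reads$reads }
  else mode <- match.arg(mode)
  if (mode == "bulk") {
    if (!is.list(reads) || is.null(names(reads)))
      stop("bulk mode expects a named list of read vectors (one per sample)")
    units <- names(reads)
    trip <- list()
    n_un <- 0L
    for (s in units) {
      ec <- .align_reads_cpp(index$ptr, reads[[s]])
      n_un <- n_un + sum(ec == 0L)
      tab <- table(ec[ec != 0L])
      trip[[s]] <- data.frame(unit = s,
                              ec_id = as.integer(names(tab)),
                              n = as.integer(tab), stringsAsFactors = FALSE)
    }
    trip <- do.call(rbind, trip)
    out <- .tcc_from_triplets(index, trip, units, "bulk")
    out$n_unassigned <- n_un
    message(sprintf("count_tccs: %d reads unassigned", n_un))
    return(out)
  }
  # single_cell
  if (!is.data.frame(reads) ||
      !all(c("read_id", "barcode", "umi", "cdna") %in% names(reads)))
    stop("single_cell mode requires reads with barcodes and UMIs (columns read_id, barcode, umi, cdna)")
  ec <- .align_reads_cpp(index$ptr, reads$cdna)
  n_un <- sum(ec == 0L)
  keep <- ec != 0L
  df <- data.frame(read_id = reads$read_id[keep], barcode = reads$barcode[keep],
                   umi = reads$umi[keep], ec_id = ec[keep],
                   stringsAsFactors = FALSE)
  reg <- ec_registry(index)
  multi <- reg$ec_id[reg$n_genes > 1L]
  n_multi <- sum(df$ec_id %in% multi)
  df <- df[!(df$ec_id %in% multi), , drop = FALSE]
  # UMI deduplication: keep the lexicographically first read id per (cell, UMI)
  df <- df[order(df$barcode, df$umi, df$read_id), , drop = FALSE]
  key <- paste(df$barcode, df$umi, sep = "\r")
  uniq_pair <- !duplicated(paste(key, df$ec_id, sep = "\r"))
  n_conflict <- sum(table(key[uniq_pair]) > 1L)
  df <- df[!duplicated(key), , drop = FALSE]
  units <- sort(unique(reads$barcode))
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = list(unit = df$barcode, ec_id = df$ec_id), FUN = sum)
  out <- .tcc_from_triplets(index, agg, units, "single_cell")
  out$n_unassigned <- n_un
  out$n_multigene <- n_multi
  out$n_umi_conflicts <- n_conflict
  message(sprintf("count_tccs: %d unassigned, %d multi-gene reads dropped, %d UMI conflicts resolved",
                  n_un, n_multi, n_conflict))
  out
}

.tcc_from_triplets <- function(index, trip, units, mode) {
  ecs <- sort(unique(trip$ec_id))
  m <- Matrix::sparseMatrix(
    i = match(trip$unit, units), j = match(trip$ec_id, ecs), x = trip$n,
    dims = c(length(units), length(ecs)),
    dimnames = list(units, as.character(ecs)))
  reg <- ec_registry(index)
  out <- list(counts = m, ec_info = reg[match(ecs, reg$ec_id), , drop = FALSE],
              mode = mode)
  rownames(out$ec_info) <- NULL
  class(out) <- "tcc_matrix"
  out
}

#' @export
print.tcc_matrix <- function(x, ...) {
  cat(sprintf("tcc_matrix (%s): %d units x %d ECs, %0.f counts\n", x$mode,
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Quality filters for single-cell TCC matrices
#'
#' Removes, in this order: (1) cells whose total deduplicated UMI count is
#' below `min_cell_total`; (2) equivalence classes that are BOTH detected in
#' fewer than `min_detect_frac` of the remaining cells AND have a mean count
#' below `min_mean` (an EC is kept if it passes either criterion; the removal
#' set is "rare or low-mean" classes as a conjunction of failures).
#'
#' @param mat a single-cell `tcc_matrix`.
#' @param min_cell_total minimum total UMIs per cell (default 100 at toy
#'   scale; the corresponding threshold of a full-scale run is a free choice).
#' @param min_detect_frac detection-fraction threshold (default 0.01).
#' @param min_mean mean-count threshold (default 0.01).
#' @return the filtered `tcc_matrix`.
#' @export
filter_sc <- function(mat, min_cell_total = 100, min_detect_frac = 0.01,
                      min_mean = 0.01) {
  stopifnot(inherits(mat, "tcc_matrix"))
  if (mat$mode != "single_cell") stop("filter_sc requires a single-cell matrix")
  m <- mat$counts
  keep_cells <- Matrix::rowSums(m) >= min_cell_total
  if (!any(keep_cells)) stop("all cells removed by the total-UMI filter")
  m <- m[keep_cells, , drop = FALSE]
  detect <- Matrix::colMeans(m > 0)
  mn <- Matrix::colMeans(m)
  keep_ec <- !(detect < min_detect_frac & mn < min_mean)
  if (!any(keep_ec)) stop("all equivalence classes removed by the EC filter")
  mat$counts <- m[, keep_ec, drop = FALSE]
  mat$ec_info <- mat$ec_info[keep_ec, , drop = FALSE]
  mat$filtered <- TRUE
  mat
}

#' Write a TCC matrix as MatrixMarket plus sidecar TSVs
#'
#' @param mat a `tcc_matrix`.
#' @param prefix path prefix; writes `<prefix>.mtx` (units x ECs),
#'   `<prefix>.units.tsv` and `<prefix>.ec.tsv`.
#' @return invisibly, the paths written.
#' @export
write_tcc <- function(mat, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p_mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(mat$counts, p_mtx)
  p_units <- paste0(prefix, ".units.tsv")
  write.table(data.frame(unit_id = rownames(mat$counts)), p_units,
              sep = "\t", quote = FALSE, row.names = FALSE)
  p_ec <- paste0(prefix, ".ec.tsv")
  write.table(mat$ec_info, p_ec, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_mtx, p_units, p_ec))
}
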