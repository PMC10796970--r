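#' Configuration for the toy genome and transcriptome
#'
#' Assembles the configuration list consumed by [make_toy_transcriptome()].
#' The default geometry of the SR-family ("SRSF5-like") gene is seven exons of
#' 120 nt separated by 90 nt introns, so that with the default read length
#' (90 nt) every read lies inside one exon or spans exactly one
#' junction/boundary, which keeps the equivalence-class structure of the gene
#' analyzable by hand.
#'
#' @param n_background_genes number of background genes in addition to the
#'   SRSF5-like gene. Background genes carry 1-4 isoforms and, as a set, are
#'   guaranteed to contain at least one skipped-exon (SE) and one
#'   retained-intron (RI) event when two or more multi-exon background genes
#'   are requested.
#' @param bg_isoform_range integer range for the number of isoforms per
#'   background gene.
#' @param bg_exon_count_range integer range for the number of exons of a
#'   background gene's base isoform.
#' @param bg_exon_len_range,bg_intron_len_range nucleotide ranges for exon and
#'   intron lengths of background genes.
#' @param intergenic_gap nucleotides of intergenic sequence between genes.
#' @param include_srsf5_like include the nine-isoform SR-family gene with the
#'   poison cassette in intron 5.
#' @param srsf5_n_exons,srsf5_exon_len,srsf5_intron_len geometry of the
#'   SRSF5-like gene.
#' @param read_length simulated read length L in nt.
#' @param k pseudoalignment k-mer length in nt; must not exceed the shortest
#'   transcript.
#' @return a named list of class `toy_config`.
#' @export
toy_config <- function(n_background_genes = 19L,
                       bg_isoform_range = c(1L, 4L),
                       bg_exon_count_range = c(4L, 8L),
                       bg_exon_len_range = c(80L, 200L),
                       bg_intron_len_range = c(60L, 200L),
                       intergenic_gap = 500L,
                       include_srsf5_like = TRUE,
                       srsf5_n_exons = 7L,
                       srsf5_exon_len = 120L,
                       srsf5_intron_len = 90L,
                       read_length = 90L,
                       k = 21L) {
  cfg <- list(
    n_background_genes = as.integer(n_background_genes),
    bg_isoform_range = as.integer(bg_isoform_range),
    bg_exon_count_range = as.integer(bg_exon_count_range),
    bg_exon_len_range = as.integer(bg_exon_len_range),
    bg_intron_len_range = as.integer(bg_intron_len_range),
    intergenic_gap = as.integer(intergenic_gap),
    include_srsf5_like = isTRUE(include_srsf5_like),
    srsf5_n_exons = as.integer(srsf5_n_exons),
    srsf5_exon_len = as.integer(srsf5_exon_len),
    srsf5_intron_len = as.integer(srsf5_intron_len),
    read_length = as.integer(read_length),
    k = as.integer(k)
  )
  class(cfg) <- "toy_config"
  cfg
}

# exon chains are 2-column matrices (start, end), 0-based half-open,
# coordinates relative to the gene start until final genome layout.

.srsf5_like_gene <- function(cfg) {
  ne <- cfg$srsf5_n_exons
  el <- cfg$srsf5_exon_len
  il <- cfg$srsf5_intron_len
  stopifnot(ne >= 7L)
  starts <- (seq_len(ne) - 1L) * (el + il)
  ex <- cbind(start = starts, end = starts + el)
  # poison cassette: intron 5, between exons 5 and 6
  poison <- c(ex[5L, "end"], ex[6L, "start"])
  chain <- function(idx, merge56 = FALSE, a5 = c(0L, 0L), a3 = c(0L, 0L)) {
    m <- ex[idx, , drop = FALSE]
    if (a5[2] > 0L) { # extend the 3' end of exon a5[1] (alternative donor)
      j <- which(idx == a5[1])
      m[j, "end"] <- m[j, "end"] + a5[2]
    }
    if (a3[2] > 0L) { # shift the 5' start of exon a3[1] (alternative acceptor)
      j <- which(idx == a3[1])
      m[j, "start"] <- m[j, "start"] + a3[2]
    }
    if (merge56) {
      j5 <- which(idx == 5L)
      j6 <- which(idx == 6L)
      m[j5, "end"] <- m[j6, "end"]
      m <- m[-j6, , drop = FALSE]
    }
    m
  }
  # Nine isoforms; the three poison_retained ones keep intron 5 (merged exon
  # 5-intron5-6), echoing the 207/211/212 numbering convention of
  # Ensembl-style isoform suffixes. The two non-canonical retained isoforms
  # carry private splice-site variants (not copies of the productive skip
  # events): this keeps the mixture identifiable from reads that span at
  # most one junction, so EM abundances are well defined.
  iso <- list(
    `201` = list(chain(1:7), "productive"),
    `202` = list(chain(c(1, 3:7)), "productive"),              # SE: skip exon 2
    `203` = list(chain(c(1:2, 4:7)), "productive"),            # SE: skip exon 3
    `205` = list(chain(1:7, a5 = c(4L, 30L)), "productive"),   # A5SS on exon 4
    `206` = list(chain(c(1:3, 5:7)), "productive"),            # SE: skip exon 4
    `209` = list(chain(1:7, a3 = c(6L, 30L)), "productive"),   # A3SS on exon 6
    `207` = list(chain(1:7, merge56 = TRUE), "poison_retained"),
    `211` = list(chain(1:7, merge56 = TRUE, a5 = c(2L, 45L)), "poison_retained"),
    `212` = list(chain(1:7, merge56 = TRUE, a3 = c(3L, 45L)), "poison_retained")
  )
  list(transcripts = iso, poison_interval = poison)
}

.background_gene <- function(cfg, force_event = NULL) {
  n_ex <- if (cfg$bg_exon_count_range[1] == cfg$bg_exon_count_range[2]) {
    cfg$bg_exon_count_range[1]
  } else sample(cfg$bg_exon_count_range[1]:cfg$bg_exon_count_range[2], 1L)
  exl <- sample(cfg$bg_exon_len_range[1]:cfg$bg_exon_len_range[2], n_ex,
                replace = TRUE)
  inl <- if (n_ex > 1L) {
    sample(cfg$bg_intron_len_range[1]:cfg$bg_intron_len_range[2], n_ex - 1L,
           replace = TRUE)
  } else integer(0)
  # single-exon genes must still accommodate a full read
  if (n_ex == 1L) exl <- max(exl, 2L * cfg$read_length)
  starts <- cumsum(c(0L, head(exl + c(inl, 0L), -1L)))
  base <- cbind(start = starts, end = starts + exl)
  n_iso <- if (cfg$bg_isoform_range[1] == cfg$bg_isoform_range[2]) {
    cfg$bg_isoform_range[1]
  } else sample(cfg$bg_isoform_range[1]:cfg$bg_isoform_range[2], 1L)
  if (!is.null(force_event)) n_iso <- max(n_iso, 2L)
  chains <- list(base)
  variant <- function(type) {
    m <- base
    switch(type,
      SE = {
        if (n_ex < 3L) return(NULL)
        j <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
        m[-j, , drop = FALSE]
      },
      RI = {
        if (n_ex < 2L) return(NULL)
        j <- if (n_ex == 2L) 1L else sample(seq_len(n_ex - 1L), 1L)
        m[j, "end"] <- m[j + 1L, "end"]
        m[-(j + 1L), , drop = FALSE]
      },
      A5SS = {
        if (n_ex < 2L) return(NULL)
        j <- if (n_ex == 2L) 1L else sample(seq_len(n_ex - 1L), 1L)
        gap <- m[j + 1L, "start"] - m[j, "end"]
        d <- min(30L, gap - 25L)
        if (d < 8L) return(NULL)
        m[j, "end"] <- m[j, "end"] + d
        m
      },
      A3SS = {
        if (n_ex < 2L) return(NULL)
        j <- if (n_ex == 2L) 2L else sample(2:n_ex, 1L)
        w <- m[j, "end"] - m[j, "start"]
        d <- min(30L, w - 40L)
        if (d < 8L) return(NULL)
        m[j, "start"] <- m[j, "start"] + d
        m
      },
      NULL
    )
  }
  types <- c("SE", "RI", "A5SS", "A3SS")
  if (n_iso > 1L) {
    want <- if (!is.null(force_event)) force_event else sample(types, 1L)
    for (i in seq_len(n_iso - 1L)) {
      for (attempt in 1:8) {
        ty <- if (i == 1L && !is.null(force_event)) force_event
              else sample(types, 1L)
        v <- variant(ty)
        ok <- !is.null(v) &&
          !any(vapply(chains, function(ch) identical(ch, v), logical(1))) &&
          sum(v[, "end"] - v[, "start"]) >= max(cfg$read_length, cfg$k)
        if (ok) { chains[[length(chains) + 1L]] <- v; break }
      }
    }
  }
  chains
}

#' Generate the toy genome and transcriptome
#'
#' Builds a deterministic multi-gene toy genome on a single forward-strand
#' chromosome and its transcript models. The default configuration contains an
#' SR-family splicing-factor gene ("SRSF5L") with exactly nine isoforms, three
#' of which retain the poison cassette in intron 5 (`biotype =
#' "poison_retained"`); the remaining six are productive and none of their
#' exon chains intersects the poison interval.
#'
#' @param config a [toy_config()] list.
#' @param seed integer seed; the same `(config, seed)` pair reproduces the
#'   transcriptome (and any files written by [write_transcriptome()])
#'   bit-for-bit.
#' @return an object of class `toy_transcriptome`: a list with elements
#'   `genome` (named [Biostrings::DNAStringSet] of chromosomes),
#'   `transcripts` (data.frame: `transcript_id`, `gene_id`, `biotype`,
#'   `length`, `n_exons`), `exons` (data.frame of 0-based half-open intervals:
#'   `transcript_id`, `gene_id`, `chrom`, `start`, `end`), `tx_seq` (named
#'   `DNAStringSet` of transcript sequences), `poison` (data.frame of poison
#'   intervals per gene), `config`, and `seed`.
#' @export
make_toy_transcriptome <- function(config = toy_config(), seed = 1L) {
  stopifnot(inherits(config, "toy_config") || is.list(config))
  set.seed(seed)
  genes <- list()
  if (config$include_srsf5_like) {
    s <- .srsf5_like_gene(config)
    genes[["SRSF5L"]] <- s
  }
  nb <- config$n_background_genes
  for (i in seq_len(nb)) {
    force_event <- if (i == 1L && nb >= 2L) "SE" else if (i == 2L) "RI" else NULL
    chains <- .background_gene(config, force_event = force_event)
    gid <- sprintf("BG%03d", i)
    iso <- lapply(seq_along(chains), function(j) list(chains[[j]], "productive"))
    names(iso) <- sprintf("%03d", 200L + seq_along(chains))
    genes[[gid]] <- list(transcripts = iso, poison_interval = NULL)
  }
  if (length(genes) == 0L) stop("configuration yields no genes")

  # lay genes on one chromosome separated by intergenic gaps
  gap <- config$intergenic_gap
  chrom <- "chrT"
  offset <- gap
  exon_rows <- list()
  tx_rows <- list()
  poison_rows <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    span <- max(vapply(g$transcripts, function(tr) max(tr[[1]][, "end"]),
                       numeric(1)))
    for (tname in names(g$transcripts)) {
      tr <- g$transcripts[[tname]]
      txid <- paste0(gid, "-", tname)
      m <- tr[[1]]
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = txid, gene_id = gid, chrom = chrom,
        start = m[, "start"] + offset, end = m[, "end"] + offset,
        stringsAsFactors = FALSE)
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = txid, gene_id = gid, biotype = tr[[2]],
        length = sum(m[, "end"] - m[, "start"]),
        n_exons = nrow(m), stringsAsFactors = FALSE)
    }
    if (!is.null(g$poison_interval)) {
      poison_rows[[length(poison_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom,
        start = g$poison_interval[1] + offset,
        end = g$poison_interval[2] + offset, stringsAsFactors = FALSE)
    }
    offset <- offset + span + gap
  }
  exons <- do.call(rbind, exon_rows)
  transcripts <- do.call(rbind, tx_rows)
  poison <- if (length(poison_rows)) do.call(rbind, poison_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  rownames(exons) <- rownames(transcripts) <- NULL
  if (anyDuplicated(transcripts$transcript_id))
    stop("internal error: duplicated transcript identifiers")

  glen <- offset
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  genome_seq <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))

  # transcript sequence = concatenation of exon subsequences (forward strand)
  tx_seq_chr <- vapply(split(exons, exons$transcript_id)[transcripts$transcript_id],
    function(df) {
      df <- df[order(df$start), , drop = FALSE]
      paste(substring(genome_seq, df$start + 1L, df$end), collapse = "")
    }, character(1))
  tx_seq <- Biostrings::DNAStringSet(tx_seq_chr)

  shortest <- transcripts$transcript_id[which.min(transcripts$length)]
  if (config$k > min(transcripts$length)) {
    stop(sprintf(
      "configuration error: k = %d exceeds the length (%d nt) of the shortest transcript '%s'",
      config$k, min(transcripts$length), shortest))
  }

  out <- list(genome = genome, transcripts = transcripts, exons = exons,
              tx_seq = tx_seq, poison = poison, config = config, seed = seed,
              k_compatible_min_len = min(transcripts$length))
  class(out) <- "toy_transcriptome"
  out
}

#' @export
print.toy_transcriptome <- function(x, ...) {
  cat(sprintf("toy_transcriptome: %d genes, %d transcripts, genome %d nt (seed %d)\n",
              length(unique(x$transcripts$gene_id)), nrow(x$transcripts),
              sum(Biostrings::width(x$genome)), x$seed))
  if (nrow(x$poison)) {
    cat(sprintf("  poison interval: %s:%d-%d (%s)\n", x$poison$chrom[1],
                x$poison$start[1], x$poison$end[1], x$poison$gene_id[1]))
  }
  invisible(x)
}

#' Transcripts of a gene by biotype
#'
#' @param txome a `toy_transcriptome`.
#' @param gene_id gene identifier (default the SRSF5-like gene).
#' @return character vector of transcript ids.
#' @export
poison_transcripts <- function(txome, gene_id = "SRSF5L") {
  tx <- txome$transcripts
  tx$transcript_id[tx$gene_id == gene_id & tx$biotype == "poison_retained"]
}

#' @rdname poison_transcripts
#' @export
productive_transcripts <- function(txome, gene_id = "SRSF5L") {
  tx <- txome$transcripts
  tx$transcript_id[tx$gene_id == gene_id & tx$biotype == "productive"]
}

#' Write FASTA and GFF3 files for a toy transcriptome
#'
#' Writes `genome.fa` (chromosomes), `transcripts.fa` (spliced transcript
#' sequences) and `annotation.gff3` (gene/mRNA/exon features, 1-based
#' inclusive coordinates as required by GFF3, converted from the 0-based
#' half-open internal representation).
#'
#' @param txome a `toy_transcriptome`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths of the files written.
#' @export
write_transcriptome <- function(txome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa_genome <- file.path(dir, "genome.fa")
  fa_tx <- file.path(dir, "transcripts.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(txome$genome, fa_genome)
  Biostrings::writeXStringSet(txome$tx_seq, fa_tx)
  rtracklayer::export(transcriptome_granges(txome), gff, format = "gff3")
  invisible(c(genome = fa_genome, transcripts = fa_tx, annotation = gff))
}

#' GRanges view of the toy annotation
#'
#' @param txome a `toy_transcriptome`.
#' @return a [GenomicRanges::GRanges] with gene, mRNA and exon features
#'   (1-based inclusive starts, GFF3 convention).
#' @export
transcriptome_granges <- function(txome) {
  ex <- txome$exons
  tx <- txome$transcripts
  tx_span <- do.call(rbind, lapply(split(ex, ex$transcript_id)[tx$transcript_id],
    function(df) data.frame(chrom = df$chrom[1], start = min(df$start),
                            end = max(df$end))))
  gene_ids <- unique(tx$gene_id)
  gene_span <- do.call(rbind, lapply(split(ex, ex$gene_id)[gene_ids],
    function(df) data.frame(chrom = df$chrom[1], start = min(df$start),
                            end = max(df$end))))
  gr_gene <- GenomicRanges::GRanges(
    seqnames = gene_span$chrom,
    ranges = IRanges::IRanges(gene_span$start + 1L, gene_span$end),
    strand = "+", type = "gene", ID = gene_ids)
  gr_tx <- GenomicRanges::GRanges(
    seqnames = tx_span$chrom,
    ranges = IRanges::IRanges(tx_span$start + 1L, tx_span$end),
    strand = "+", type = "mRNA", ID = tx$transcript_id, Parent = tx$gene_id)
  gr_ex <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start + 1L, ex$end),
    strand = "+", type = "exon",
    ID = paste0(ex$transcript_id, ".e",
                stats::ave(seq_len(nrow(ex)), ex$transcript_id,
                           FUN = seq_along)),
    Parent = ex$transcript_id)
  c(gr_gene, gr_tx, gr_ex)
}

# internal invariant checker used by the test suite
validate_transcriptome <- function(txome) {
  ex <- txome$exons
  glen <- stats::setNames(Biostrings::width(txome$genome), names(txome$genome))
  stopifnot(all(ex$start >= 0L), all(ex$end <= glen[ex$chrom]),
            all(ex$end > ex$start))
  for (txid in txome$transcripts$transcript_id) {
    m <- ex[ex$transcript_id == txid, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    if (nrow(m) > 1L) stopifnot(all(m$start[-1L] >= m$end[-nrow(m)]))
    sq <- paste(substring(as.character(txome$genome[[m$chrom[1]]]),
                          m$start + 1L, m$end), collapse = "")
    stopifnot(identical(sq, as.character(txome$tx_seq[[txid]])))
  }
  invisible(TRUE)
}
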