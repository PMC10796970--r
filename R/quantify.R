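#' EM estimation of transcript abundances from one unit's TCCs
#'
#' Runs the standard equivalence-class EM from a uniform initialization:
#' `alpha_t <- sum_e c_e * (alpha_t/l_t) / sum_{t' in e} (alpha_{t'}/l_{t'})`,
#' where `l_t` is the effective length. Iteration stops when the maximum
#' absolute change in the normalized abundances (`alpha / N`, the mixture
#' weights the EM contracts) falls below `tol`, or after `max_iter`
#' iterations. `rho_t` is proportional to
#' `alpha_t / l_t` and sums to one: it estimates the molecule (isoform)
#' proportion, whereas `alpha` is on the read-count scale and sums to the
#' number of assigned reads.
#'
#' @param counts numeric vector of EC counts for one unit.
#' @param ec_tx list (same length as `counts`) of integer transcript indices
#'   per EC, 1-based into `transcript_id`.
#' @param transcript_id character vector of transcript ids.
#' @param eff_length numeric effective lengths `max(1, len - L + 1)`.
#' @param tol convergence tolerance on `max |delta rho|` (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param ec_weights optional list parallel to `ec_tx` giving, per EC, the
#'   number of read start positions of each member transcript that fall in
#'   the EC (position-aware likelihood). `NULL` uses unit weights: the
#'   classic width-free equivalence-class EM.
#' @return an `abundance` data.frame (`transcript_id`, `eff_length`,
#'   `est_counts`, `proportion`) with attributes `n_iter`, `loglik` (the
#'   per-iteration observed-data log-likelihood trace) and `converged`.
#'   All-zero counts yield zero abundances with a warning.
#' @export
em_quantify <- function(counts, ec_tx, transcript_id, eff_length,
                        tol = 1e-8, max_iter = 1000L, ec_weights = NULL) {
  stopifnot(length(counts) == length(ec_tx),
            length(transcript_id) == length(eff_length))
  if (sum(counts) <= 0)
    warning("all-zero TCC vector: returning zero abundances")
  fit <- .em_cpp(as.numeric(counts), ec_tx, length(transcript_id),
                 as.numeric(eff_length), tol, as.integer(max_iter),
                 ec_weights)
  out <- data.frame(transcript_id = transcript_id,
                    eff_length = eff_length,
                    est_counts = fit$alpha,
                    proportion = fit$rho,
                    stringsAsFactors = FALSE)
  attr(out, "n_iter") <- fit$n_iter
  attr(out, "loglik") <- fit$loglik
  attr(out, "converged") <- fit$converged
  class(out) <- c("abundance", "data.frame")
  out
}

#' Multinomial bootstrap of the EM abundances
#'
#' Each replicate resamples the unit's total read count multinomially over
#' the equivalence classes (probabilities `c_e / N`) and re-runs the EM.
#' Replicate RNG streams are derived deterministically from `(seed, b)`.
#'
#' @inheritParams em_quantify
#' @param B number of bootstrap replicates (>= 0).
#' @param seed integer seed.
#' @return matrix of bootstrapped `est_counts` (transcripts x B); 0 columns
#'   when `B = 0`.
#' @export
bootstrap_abundances <- function(counts, ec_tx, transcript_id, eff_length,
                                 B = 100L, seed = 1L, tol = 1e-8,
                                 max_iter = 1000L, ec_weights = NULL) {
  stopifnot(B >= 0L)
  N <- sum(counts)
  out <- matrix(0, length(transcript_id), B,
                dimnames = list(transcript_id, NULL))
  if (B == 0L) return(out)
  if (N <= 0) stop("bootstrap requires a positive total count")
  for (b in seq_len(B)) {
    set.seed(.derive_seed(seed, b))
    cb <- as.numeric(rmultinom(1L, N, counts / N))
    fit <- .em_cpp(cb, ec_tx, length(transcript_id),
                   as.numeric(eff_length), tol, as.integer(max_iter),
                   ec_weights)
    out[, b] <- fit$alpha
  }
  out
}

# deterministic 32-bit stream seed from (seed, b)
.derive_seed <- function(seed, b) {
  as.integer((as.numeric(seed) * 7919 + b * 104729) %% 2147483647)
}

#' Quantify all units of a TCC matrix
#'
#' Convenience wrapper: runs [em_quantify()] (and optionally
#' [bootstrap_abundances()]) per unit of a `tcc_matrix`.
#'
#' @param tcc a `tcc_matrix`.
#' @param index the `kmer_index` the matrix was counted against.
#' @param read_length read length L used to compute effective lengths
#'   `max(1, len - L + 1)`.
#' @param B bootstrap replicates per unit (0 disables).
#' @param seed integer seed for the bootstrap streams.
#' @param tol,max_iter EM controls.
#' @param position_weights use the position-aware likelihood (default TRUE):
#'   exact per-(EC, transcript) position counts are enumerated from the
#'   index, which removes the estimation bias of the width-free EC EM when
#'   shared classes cover different numbers of positions on different
#'   isoforms.
#' @return object of class `abundance_set`: list with `est_counts` and
#'   `proportions` (transcripts x units matrices), `boots` (named list of
#'   transcripts x B matrices), `transcripts` (data.frame with gene ids),
#'   `eff_length`, `read_length`.
#' @export
quantify_units <- function(tcc, index, read_length, B = 0L, seed = 1L,
                           tol = 1e-8, max_iter = 1000L,
                           position_weights = TRUE) {
  stopifnot(inherits(tcc, "tcc_matrix"), inherits(index, "kmer_index"))
  tx <- index$transcripts
  eff <- pmax(tx$length - read_length + 1, 1)
  ec_w <- NULL
  if (position_weights) {
    all_w <- .ec_widths_cpp(index$ptr, unname(index$seqs), read_length)
    ec_ids <- as.integer(colnames(tcc$counts))
    ec_w <- all_w[ec_ids]
    # ECs only reachable through sequencing errors have no error-free
    # positions; fall back to unit weights for those
    ec_w <- lapply(ec_w, function(w) if (sum(w) <= 0) rep(1, length(w)) else w)
  }
  sets <- ec_transcript_sets(index)
  ec_ids <- as.integer(colnames(tcc$counts))
  ec_tx <- sets[ec_ids]
  units <- rownames(tcc$counts)
  est <- prop <- matrix(0, nrow(tx), length(units),
                        dimnames = list(tx$transcript_id, units))
  boots <- vector("list", length(units))
  names(boots) <- units
  for (u in units) {
    cnt <- as.numeric(tcc$counts[u, ])
    ab <- em_quantify(cnt, ec_tx, tx$transcript_id, eff, tol, max_iter,
                      ec_weights = ec_w)
    est[, u] <- ab$est_counts
    prop[, u] <- ab$proportion
    if (B > 0L) {
      boots[[u]] <- bootstrap_abundances(cnt, ec_tx, tx$transcript_id, eff,
                                         B = B, seed = .derive_seed(seed, match(u, units)),
                                         tol = tol, max_iter = max_iter,
                                         ec_weights = ec_w)
    } else boots[[u]] <- matrix(0, nrow(tx), 0,
                                dimnames = list(tx$transcript_id, NULL))
  }
  out <- list(est_counts = est, proportions = prop, boots = boots,
              transcripts = tx, eff_length = stats::setNames(eff, tx$transcript_id),
              read_length = read_length)
  class(out) <- "abundance_set"
  out
}

#' Write abundance tables as TSV
#'
#' @param ab an `abundance_set`.
#' @param prefix path prefix; writes `<prefix>.abundance.tsv` (long format)
#'   and `<prefix>.bootstrap.tsv` (replicate-indexed) when bootstraps exist.
#' @return invisibly, paths written.
#' @export
write_abundance <- function(ab, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  units <- colnames(ab$est_counts)
  long <- do.call(rbind, lapply(units, function(u) data.frame(
    unit_id = u, transcript_id = rownames(ab$est_counts),
    length = ab$transcripts$length,
    eff_length = ab$eff_length,
    est_counts = ab$est_counts[, u],
    proportion = ab$proportions[, u], stringsAsFactors = FALSE)))
  p1 <- paste0(prefix, ".abundance.tsv")
  write.table(long, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (ncol(ab$boots[[1]]) > 0L) {
    bl <- do.call(rbind, lapply(units, function(u) {
      m <- ab$boots[[u]]
      data.frame(unit_id = u, replicate = rep(seq_len(ncol(m)), each = nrow(m)),
                 transcript_id = rownames(m), est_counts = as.vector(m),
                 stringsAsFactors = FALSE)
    }))
    p2 <- paste0(prefix, ".bootstrap.tsv")
    write.table(bl, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
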