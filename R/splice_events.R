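# Alternative-splicing event enumeration from exon chains, EC-based event
# counting, length-normalized inclusion levels (psi) and a binomial LRT.

.chain_of <- function(exons, txid) {
  m <- exons[exons$transcript_id == txid, c("start", "end"), drop = FALSE]
  as.matrix(m[order(m$start), , drop = FALSE])
}

.junctions <- function(ch) {
  if (nrow(ch) < 2L) return(matrix(numeric(0), 0, 2))
  cbind(d = ch[-nrow(ch), "end"], a = ch[-1L, "start"])
}

.has_junction <- function(jn, d, a) any(jn[, 1] == d & jn[, 2] == a)
.has_exon <- function(ch, s, e) any(ch[, "start"] == s & ch[, "end"] == e)
.covers <- function(ch, s, e) any(ch[, "start"] <= s & ch[, "end"] >= e)

#' Enumerate alternative splicing events from the annotation
#'
#' Pairwise comparison of exon chains within each multi-isoform gene yields
#' de-duplicated events of the five canonical types: skipped exon (SE),
#' retained intron (RI), alternative 5'/3' splice sites (A5SS/A3SS) and
#' mutually exclusive exons (MXE). For each event, every isoform of the gene
#' is classified into the inclusion set (carries the variable region), the
#' skipping set (carries the direct junction), or neither. Effective lengths
#' `l_I`, `l_S` are computed, when an index is supplied, by exhaustive
#' enumeration of read start positions whose equivalence class resolves
#' uniquely to one form: each form's effective length is the mean over its
#' isoforms of the per-isoform informative position count (so `I / l_I` is
#' proportional to the form's molecule abundance under the uniform-start
#' read model). Events with no uniquely-resolving position for either form
#' are dropped (logged).
#'
#' @param txome a `toy_transcriptome`.
#' @param index optional `kmer_index` over the same transcriptome, required
#'   for effective lengths.
#' @param read_length read length used for the effective-length enumeration.
#' @return data.frame of class `splice_events`: `event_id`, `type`,
#'   `gene_id`, `chrom`, `var_start`, `var_end` (0-based half-open; for RI
#'   the retained intron), `var2_start`, `var2_end` (second exon, MXE only),
#'   `inclusion`, `skipping` (comma-separated transcript ids), `l_I`, `l_S`.
#' @export
enumerate_events <- function(txome, index = NULL,
                             read_length = txome$config$read_length) {
  tx <- txome$transcripts
  ev <- list()
  for (g in unique(tx$gene_id)) {
    ids <- tx$transcript_id[tx$gene_id == g]
    if (length(ids) < 2L) next
    chains <- lapply(ids, .chain_of, exons = txome$exons)
    names(chains) <- ids
    juncs <- lapply(chains, .junctions)
    chrom <- txome$exons$chrom[txome$exons$gene_id == g][1]
    add <- function(type, vs, ve, incl, skip, v2s = NA, v2e = NA) {
      if (length(incl) == 0L || length(skip) == 0L) return()
      ev[[length(ev) + 1L]] <<- data.frame(
        type = type, gene_id = g, chrom = chrom,
        var_start = vs, var_end = ve, var2_start = v2s, var2_end = v2e,
        inclusion = paste(sort(incl), collapse = ","),
        skipping = paste(sort(skip), collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (xi in seq_along(ids)) for (yi in seq_along(ids)) {
      if (xi == yi) next
      X <- chains[[xi]]; Y <- chains[[yi]]
      jY <- juncs[[yi]]
      # SE: internal exon of X absent from Y, flanking junction present in Y
      if (nrow(X) >= 3L) {
        for (j in 2:(nrow(X) - 1L)) {
          s <- X[j, "start"]; e <- X[j, "end"]
          up <- X[j - 1L, "end"]; dn <- X[j + 1L, "start"]
          if (!.has_exon(Y, s, e) && .has_junction(jY, up, dn)) {
            incl <- ids[vapply(chains, .has_exon, logical(1), s = s, e = e)]
            skip <- ids[vapply(juncs, .has_junction, logical(1), d = up, a = dn)]
            add("SE", s, e, incl, setdiff(skip, incl))
          }
        }
      }
      # RI: one exon of X spans two exons of Y plus the intervening intron
      if (nrow(Y) >= 2L) {
        for (j in seq_len(nrow(Y) - 1L)) {
          e1 <- Y[j, , drop = FALSE]; e2 <- Y[j + 1L, , drop = FALSE]
          hit <- X[, "start"] == e1[1, "start"] & X[, "end"] == e2[1, "end"]
          if (any(hit)) {
            vs <- e1[1, "end"]; ve <- e2[1, "start"]
            incl <- ids[vapply(chains, .covers, logical(1), s = vs, e = ve)]
            skip <- ids[vapply(juncs, .has_junction, logical(1), d = vs, a = ve)]
            add("RI", vs, ve, incl, setdiff(skip, incl))
          }
        }
      }
      # A5SS: exons sharing a start with different ends and a common acceptor
      for (j in seq_len(nrow(X) - 1L)) {
        a0 <- X[j + 1L, "start"]
        cand <- which(Y[, "start"] == X[j, "start"] & Y[, "end"] != X[j, "end"])
        for (cj in cand) {
          if (cj >= nrow(Y)) next
          if (Y[cj + 1L, "start"] != a0) next
          lo <- min(X[j, "end"], Y[cj, "end"])
          hi <- max(X[j, "end"], Y[cj, "end"])
          incl <- ids[vapply(juncs, .has_junction, logical(1), d = hi, a = a0)]
          skip <- ids[vapply(juncs, .has_junction, logical(1), d = lo, a = a0)]
          add("A5SS", lo, hi, incl, skip)
        }
      }
      # A3SS: exons sharing an end with different starts and a common donor
      for (j in 2:max(nrow(X), 2L)) {
        if (j > nrow(X)) next
        d0 <- X[j - 1L, "end"]
        cand <- which(Y[, "end"] == X[j, "end"] & Y[, "start"] != X[j, "start"])
        for (cj in cand) {
          if (cj < 2L) next
          if (Y[cj - 1L, "end"] != d0) next
          lo <- min(X[j, "start"], Y[cj, "start"])
          hi <- max(X[j, "start"], Y[cj, "start"])
          incl <- ids[vapply(juncs, .has_junction, logical(1), d = d0, a = lo)]
          skip <- ids[vapply(juncs, .has_junction, logical(1), d = d0, a = hi)]
          add("A3SS", lo, hi, incl, skip)
        }
      }
      # MXE: mutually exclusive internal exons with shared flanks
      if (nrow(X) >= 3L && nrow(Y) >= 3L) {
        for (j in 2:(nrow(X) - 1L)) {
          ea <- X[j, , drop = FALSE]
          f1 <- X[j - 1L, "end"]; f2 <- X[j + 1L, "start"]
          for (l in 2:(nrow(Y) - 1L)) {
            eb <- Y[l, , drop = FALSE]
            if (eb[1, "start"] < ea[1, "end"] && ea[1, "start"] < eb[1, "end"]) next
            if (ea[1, "start"] >= eb[1, "start"]) next # orient: ea upstream
            if (Y[l - 1L, "end"] != f1 || Y[l + 1L, "start"] != f2) next
            if (.has_exon(Y, ea[1, "start"], ea[1, "end"])) next
            if (.has_exon(X, eb[1, "start"], eb[1, "end"])) next
            has_a <- vapply(chains, .has_exon, logical(1),
                            s = ea[1, "start"], e = ea[1, "end"])
            has_b <- vapply(chains, .has_exon, logical(1),
                            s = eb[1, "start"], e = eb[1, "end"])
            add("MXE", ea[1, "start"], ea[1, "end"], ids[has_a & !has_b],
                ids[has_b & !has_a], eb[1, "start"], eb[1, "end"])
          }
        }
      }
    }
  }
  if (length(ev) == 0L) {
    out <- data.frame(event_id = character(0), type = character(0),
                      gene_id = character(0), chrom = character(0),
                      var_start = numeric(0), var_end = numeric(0),
                      var2_start = numeric(0), var2_end = numeric(0),
                      inclusion = character(0), skipping = character(0),
                      l_I = numeric(0), l_S = numeric(0))
    class(out) <- c("splice_events", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, ev)
  key <- with(ev, paste(type, gene_id, var_start, var_end, var2_start, var2_end))
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev <- ev[order(ev$gene_id, ev$var_start, ev$type), , drop = FALSE]
  ev$event_id <- sprintf("%s.%s.%d", ev$gene_id, ev$type,
                         stats::ave(seq_len(nrow(ev)),
                                    paste(ev$gene_id, ev$type),
                                    FUN = seq_along))
  rownames(ev) <- NULL
  ev$l_I <- NA_real_
  ev$l_S <- NA_real_
  if (!is.null(index)) {
    efl <- .event_eff_lengths(txome, index, ev, read_length)
    ev$l_I <- efl$l_I
    ev$l_S <- efl$l_S
    drop <- ev$l_I < 1 | ev$l_S < 1
    if (any(drop))
      message(sprintf("enumerate_events: dropping %d events with no uniquely-resolving read positions",
                      sum(drop)))
    ev <- ev[!drop, , drop = FALSE]
  }
  ev <- ev[, c("event_id", "type", "gene_id", "chrom", "var_start", "var_end",
               "var2_start", "var2_end", "inclusion", "skipping", "l_I", "l_S")]
  rownames(ev) <- NULL
  class(ev) <- c("splice_events", "data.frame")
  ev
}

# effective length = mean (over the form's isoforms) number of read start
# positions whose EC resolves uniquely to that form; the per-isoform mean
# makes I / l_I proportional to the form's molecule abundance under a
# uniform-start read model
.event_eff_lengths <- function(txome, index, ev, L) {
  seqs <- as.character(txome$tx_seq)
  txid <- index$transcripts$transcript_id
  count_form <- function(form_ids) {
    per_iso <- vapply(form_ids, function(t) {
      s <- seqs[[t]]
      n <- nchar(s) - L + 1L
      if (n < 1L) return(0)
      rd <- substring(s, seq_len(n), seq_len(n) + L - 1L)
      ecs <- pseudoalign(index, rd)
      sets <- ec_transcript_sets(index) # refresh: alignment registers new ECs
      sum(vapply(ecs, function(e) {
        !is.na(e) && all(txid[sets[[e]]] %in% form_ids)
      }, logical(1)))
    }, numeric(1))
    round(mean(per_iso))
  }
  l_I <- l_S <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    l_I[i] <- count_form(strsplit(ev$inclusion[i], ",")[[1]])
    l_S[i] <- count_form(strsplit(ev$skipping[i], ",")[[1]])
  }
  list(l_I = l_I, l_S = l_S)
}

#' Count event-informative reads from EC assignments
#'
#' A read (or deduplicated molecule) supports inclusion if its equivalence
#' class is a non-empty subset of the event's inclusion isoform set, skipping
#' if a non-empty subset of the skipping set; ECs intersecting both sets or
#' neither are counted as ambiguous.
#'
#' @param tcc a `tcc_matrix`.
#' @param event one row of a [enumerate_events()] table.
#' @param index the `kmer_index` used to build the matrix.
#' @return data.frame per unit: `unit_id`, `I`, `S`, `ambiguous`.
#' @export
count_event_reads <- function(tcc, event, index) {
  stopifnot(inherits(tcc, "tcc_matrix"), nrow(event) == 1L)
  incl <- strsplit(event$inclusion, ",")[[1]]
  skip <- strsplit(event$skipping, ",")[[1]]
  txid <- index$transcripts$transcript_id
  if (!all(c(incl, skip) %in% txid))
    stop("event references transcripts unknown to the index")
  sets <- ec_transcript_sets(index)
  ec_ids <- as.integer(colnames(tcc$counts))
  cls <- vapply(ec_ids, function(e) {
    tset <- txid[sets[[e]]]
    inI <- all(tset %in% incl)
    inS <- all(tset %in% skip)
    if (inI && !inS) "I" else if (inS && !inI) "S" else "ambiguous"
  }, character(1))
  m <- tcc$counts
  data.frame(
    unit_id = rownames(m),
    I = as.numeric(Matrix::rowSums(m[, cls == "I", drop = FALSE])),
    S = as.numeric(Matrix::rowSums(m[, cls == "S", drop = FALSE])),
    ambiguous = as.numeric(Matrix::rowSums(m[, cls == "ambiguous", drop = FALSE])),
    stringsAsFactors = FALSE)
}

#' Length-normalized inclusion level
#'
#' `psi = (I/l_I) / (I/l_I + S/l_S)`. Undefined (`NA`) when `I + S = 0`.
#'
#' @param I,S inclusion and skipping read counts.
#' @param l_I,l_S effective lengths (read start positions) of the two forms.
#' @return psi in `[0, 1]` (vectorized).
#' @export
psi <- function(I, S, l_I, l_S) {
  out <- (I / l_I) / (I / l_I + S / l_S)
  out[I + S == 0] <- NA_real_
  out
}

# read-scale inclusion probability implied by a molecule-scale psi
.theta_of_psi <- function(p, l_I, l_S) p * l_I / (p * l_I + (1 - p) * l_S)
.psi_of_theta <- function(th, l_I, l_S) th * l_S / (th * l_S + (1 - th) * l_I)

#' Group-difference likelihood-ratio test for one splicing event
#'
#' Per-unit inclusion counts are modeled as `I_u ~ Binomial(I_u + S_u,
#' theta)`, where `theta(psi) = psi * l_I / (psi * l_I + (1 - psi) * l_S)` is
#' the read-scale inclusion probability. The null fits one common psi; the
#' alternative one psi per group (maximum likelihood; for the binomial the ML
#' estimate of theta is the pooled inclusion fraction). `LRT = 2 *
#' (loglik_1 - loglik_0)` is referred to chi-square with 1 df. Replicate
#' overdispersion is deliberately not modeled.
#'
#' @param counts data.frame from [count_event_reads()].
#' @param design two-condition design table covering the units.
#' @param l_I,l_S effective lengths of the event.
#' @return one-row data.frame: `psi_A`, `psi_B`, `delta_psi`
#'   (`psi_B - psi_A`), `lrt`, `df`, `pval`; all `NA` when a group has no
#'   informative reads.
#' @export
event_group_lrt <- function(counts, design, l_I, l_S) {
  d <- design[match(counts$unit_id, design$unit_id), , drop = FALSE]
  lev <- sort(unique(d$condition))
  stopifnot(length(lev) == 2L)
  n <- counts$I + counts$S
  ga <- d$condition == lev[1] & n > 0
  gb <- d$condition == lev[2] & n > 0
  if (!any(ga) || !any(gb)) {
    return(data.frame(psi_A = NA_real_, psi_B = NA_real_,
                      delta_psi = NA_real_, lrt = NA_real_, df = 1L,
                      pval = NA_real_))
  }
  ll <- function(idx, th) {
    th <- min(max(th, 1e-12), 1 - 1e-12)
    sum(stats::dbinom(counts$I[idx], n[idx], th, log = TRUE))
  }
  use <- ga | gb
  th0 <- sum(counts$I[use]) / sum(n[use])
  thA <- sum(counts$I[ga]) / sum(n[ga])
  thB <- sum(counts$I[gb]) / sum(n[gb])
  lrt <- max(0, 2 * (ll(ga, thA) + ll(gb, thB) - ll(use, th0)))
  data.frame(psi_A = .psi_of_theta(thA, l_I, l_S),
             psi_B = .psi_of_theta(thB, l_I, l_S),
             delta_psi = .psi_of_theta(thB, l_I, l_S) -
               .psi_of_theta(thA, l_I, l_S),
             lrt = lrt, df = 1L,
             pval = pchisq(lrt, df = 1L, lower.tail = FALSE))
}

#' Test all enumerated events for group differences
#'
#' @param tcc a `tcc_matrix` of the units to compare.
#' @param events a [enumerate_events()] table with effective lengths.
#' @param design two-condition design table.
#' @param index the `kmer_index` used for counting.
#' @return data.frame per event with counts summaries, psi per group,
#'   `delta_psi`, `lrt`, `pval` and BH `qval` (over tested events).
#' @export
test_splice_events <- function(tcc, events, design, index) {
  res <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    cnt <- count_event_reads(tcc, events[i, , drop = FALSE], index)
    r <- event_group_lrt(cnt, design, events$l_I[i], events$l_S[i])
    cbind(data.frame(event_id = events$event_id[i], type = events$type[i],
                     gene_id = events$gene_id[i],
                     I_total = sum(cnt$I), S_total = sum(cnt$S),
                     stringsAsFactors = FALSE), r)
  }))
  res$qval <- NA_real_
  tested <- !is.na(res$pval)
  res$qval[tested] <- bh_adjust(res$pval[tested])
  res
}
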