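.check_design2 <- function(design, units) {
  design <- design[match(units, design$unit_id), , drop = FALSE]
  if (anyNA(design$condition))
    stop("design does not label every quantified unit")
  lev <- sort(unique(design$condition))
  if (length(lev) != 2L) stop("exactly two condition labels are required")
  nA <- sum(design$condition == lev[1])
  nB <- sum(design$condition == lev[2])
  if (nA < 2L || nB < 2L)
    stop("each condition needs at least two samples for the Wald test")
  list(design = design, lev = lev, nA = nA, nB = nB)
}

# Wald machinery shared by the transcript- and gene-level tests.
# y: features x units matrix of est_counts; boot_vars: features x units matrix
# of bootstrap variances of log(counts + offset).
.wald_core <- function(y_counts, boot_vars, design, log_offset = 0.5,
                       bio_floor = 1e-6, shrink = TRUE) {
  d <- .check_design2(design, colnames(y_counts))
  y <- log(y_counts + log_offset)
  a <- d$design$condition == d$lev[1]
  b <- d$design$condition == d$lev[2]
  mA <- rowMeans(y[, a, drop = FALSE])
  mB <- rowMeans(y[, b, drop = FALSE])
  beta <- mB - mA
  ssA <- rowSums((y[, a, drop = FALSE] - mA)^2)
  ssB <- rowSums((y[, b, drop = FALSE] - mB)^2)
  s2_tot <- (ssA + ssB) / (d$nA + d$nB - 2L)
  s2_inf <- rowMeans(boot_vars)
  # one-sided variance moderation: with a handful of replicates the pooled
  # variance estimate has only nA+nB-2 degrees of freedom, and pushing
  # beta/se through a normal tail is anticonservative exactly where the
  # variance fluctuates low. The df-corrected mean-dependent prior trend of
  # the total variance acts as a floor: per-feature variances are raised to
  # the trend, never lowered below their raw value.
  if (shrink && length(beta) >= 10L) {
    sq <- tryCatch(
      limma::squeezeVar(pmax(s2_tot, 1e-8), df = d$nA + d$nB - 2L,
                        covariate = rowMeans(y), robust = TRUE),
      error = function(e) NULL)
    if (!is.null(sq)) s2_tot <- pmax(s2_tot, sq$var.prior)
  }
  s2_bio <- pmax(s2_tot - s2_inf, bio_floor)
  se <- sqrt((s2_bio + s2_inf) * (1 / d$nA + 1 / d$nB))
  z <- beta / se
  data.frame(mean_obs = rowMeans(y_counts),
             beta = beta, se = se, stat = z,
             pval = 2 * pnorm(-abs(z)),
             sigma2_inf = s2_inf, sigma2_bio = s2_bio,
             sigma2_tot = s2_tot, stringsAsFactors = FALSE)
}

.boot_logvar <- function(boots, log_offset = 0.5) {
  # features x units matrix of Var_b log(boot + offset)
  nf <- nrow(boots[[1]])
  v <- vapply(boots, function(m) {
    lm <- log(m + log_offset)
    rowSums((lm - rowMeans(lm))^2) / (ncol(m) - 1L)
  }, numeric(nf))
  matrix(v, nrow = nf, dimnames = list(rownames(boots[[1]]), names(boots)))
}

#' Transcript-level Wald test with inferential variance decomposition
#'
#' For each transcript, observations are `y_s = ln(est_counts_s + 0.5)`. The
#' inferential variance `sigma2_inf` is the mean (over samples) of the
#' bootstrap variance of `ln(alpha^(b) + 0.5)`; the biological variance is
#' `max(sigma2_tot - sigma2_inf, 1e-6)` where `sigma2_tot` is the pooled
#' within-group variance of `y`. The effect `beta` is the difference of group
#' means on the log scale, `se = sqrt((sigma2_bio + sigma2_inf) *
#' (1/n_A + 1/n_B))`, and the p-value is the two-sided standard-normal tail
#' of `z = beta / se`.
#'
#' @param ab an `abundance_set` from [quantify_units()] with `B >= 2`
#'   bootstrap replicates per sample.
#' @param design a two-condition design table with at least two samples per
#'   condition.
#' @param log_offset half-count stabilizer added before taking logs.
#' @param shrink apply empirical-Bayes variance moderation (default TRUE):
#'   the biological variance component is squeezed toward a mean-dependent
#'   prior ([limma::squeezeVar()]), which stabilizes the heavy lower tail of
#'   few-replicate variance estimates and keeps the normal-tail Wald
#'   p-values calibrated. `shrink = FALSE` gives the plain per-feature
#'   estimator exactly as written above.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `mean_obs`, `beta`, `se`, `stat`, `pval`, variance
#'   components, and `mean_est_counts` (the Lancaster weight basis).
#' @export
transcript_wald_test <- function(ab, design, log_offset = 0.5, shrink = TRUE) {
  stopifnot(inherits(ab, "abundance_set"))
  if (ncol(ab$boots[[1]]) < 2L)
    stop("transcript_wald_test requires at least 2 bootstrap replicates per sample")
  bv <- .boot_logvar(ab$boots, log_offset)
  res <- .wald_core(ab$est_counts, bv, design, log_offset, shrink = shrink)
  data.frame(transcript_id = rownames(ab$est_counts),
             gene_id = ab$transcripts$gene_id,
             mean_est_counts = rowMeans(ab$est_counts),
             res, row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-level Wald test on aggregated counts
#'
#' Sums estimated transcript counts (and their bootstrap replicates) within
#' each gene per sample, then applies the same Wald machinery as
#' [transcript_wald_test()]. This detects overall up/down regulation of a
#' gene but is blind to isoform switching at conserved totals.
#'
#' @inheritParams transcript_wald_test
#' @return data.frame per gene: `gene_id`, `beta`, `se`, `stat`, `pval`,
#'   `qval` (BH).
#' @export
gene_count_test <- function(ab, design, log_offset = 0.5, shrink = TRUE) {
  stopifnot(inherits(ab, "abundance_set"))
  g <- ab$transcripts$gene_id
  gsum <- rowsum(ab$est_counts, g)
  gboots <- lapply(ab$boots, function(m) rowsum(m, g))
  bv <- .boot_logvar(gboots, log_offset)
  res <- .wald_core(gsum, bv, design, log_offset, shrink = shrink)
  out <- data.frame(gene_id = rownames(gsum), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$qval <- bh_adjust(out$pval)
  out
}

#' Lancaster p-value aggregation
#'
#' Weighted generalization of Fisher's combined-probability test: each
#' p-value contributes `Qchisq(w_i, 1 - p_i)`, the upper chi-square quantile
#' with `w_i` degrees of freedom, and the sum is referred to a chi-square
#' distribution with `sum(w_i)` degrees of freedom. With all weights equal to
#' 2 this reduces exactly to Fisher's method.
#'
#' @param pvals numeric vector of p-values (clamped into
#'   `[1e-15, 1 - 1e-15]`).
#' @param weights positive weights, same length as `pvals`.
#' @return the aggregated p-value, or `NA` for empty input.
#' @export
lancaster_aggregate <- function(pvals, weights) {
  stopifnot(length(pvals) == length(weights))
  if (length(pvals) == 0L) return(NA_real_)
  if (any(weights <= 0)) stop("Lancaster weights must be positive")
  p <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  T <- sum(qchisq(p, df = weights, lower.tail = FALSE))
  pchisq(T, df = sum(weights), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]);
#' rejects `NaN` input.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-values are not allowed")
  p.adjust(pvals, method = "BH")
}

#' Gene-level aggregation of transcript tests via the Lancaster method
#'
#' Aggregates transcript-level Wald p-values to genes with weights equal to
#' the mean estimated counts of each transcript across all samples;
#' transcripts with mean count below `min_weight` are excluded from
#' aggregation. Genes with no transcript passing the floor are reported
#' untested (`NA` p).
#'
#' @param tx_res output of [transcript_wald_test()].
#' @param min_weight inclusion floor on the mean estimated counts (default 1).
#' @return data.frame per gene: `gene_id`, `n_tx_used`, `total_weight`,
#'   `pval`, `qval` (BH over tested genes).
#' @export
lancaster_gene_test <- function(tx_res, min_weight = 1) {
  keep <- tx_res$mean_est_counts >= min_weight
  used <- tx_res[keep, , drop = FALSE]
  genes <- unique(tx_res$gene_id)
  res <- do.call(rbind, lapply(genes, function(g) {
    sub <- used[used$gene_id == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(gene_id = g, n_tx_used = 0L, total_weight = 0,
                        pval = NA_real_, stringsAsFactors = FALSE))
    data.frame(gene_id = g, n_tx_used = nrow(sub),
               total_weight = sum(sub$mean_est_counts),
               pval = lancaster_aggregate(sub$pval, sub$mean_est_counts),
               stringsAsFactors = FALSE)
  }))
  res$qval <- NA_real_
  tested <- !is.na(res$pval)
  res$qval[tested] <- bh_adjust(res$pval[tested])
  res
}

#' Bulk differential pipeline
#'
#' Runs the transcript-level Wald tests and both gene-level aggregations
#' (Lancaster p-value aggregation for splicing/switching sensitivity; count
#' aggregation for overall expression changes), with BH FDR control.
#'
#' @inheritParams transcript_wald_test
#' @param min_weight Lancaster inclusion floor on mean estimated counts.
#' @return list with `transcripts`, `genes_lancaster`, `genes_count`.
#' @export
diff_bulk <- function(ab, design, log_offset = 0.5, min_weight = 1,
                      shrink = TRUE) {
  tx <- transcript_wald_test(ab, design, log_offset, shrink = shrink)
  tx$qval <- bh_adjust(tx$pval)
  list(transcripts = tx,
       genes_lancaster = lancaster_gene_test(tx, min_weight),
       genes_count = gene_count_test(ab, design, log_offset, shrink = shrink))
}
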