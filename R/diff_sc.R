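# Single-cell isoform-switching inference on TCC matrices: gene-wise EC
# selection, logistic-regression LRT between conditions, gene-level contrast,
# and percentile bootstrap CIs for per-EC means.

#' Select a gene's TCC columns for testing
#'
#' Retains equivalence classes whose transcript set lies entirely within the
#' gene and whose mean count exceeds `min_mean` in BOTH conditions.
#'
#' @param mat a filtered single-cell `tcc_matrix` (see [filter_sc()]).
#' @param gene_id gene to slice.
#' @param design two-condition design covering the cells of the matrix.
#' @param min_mean per-condition mean-count threshold (default 0.05).
#' @return object of class `gene_tcc_slice`: list with `gene_id`, `counts`
#'   (dense cells x E matrix), `y` (condition factor), `ec_ids`,
#'   `ec_transcripts`; or `NULL` (with a message) when no EC is retained —
#'   the gene is untestable.
#' @export
select_gene_tccs <- function(mat, gene_id, design, min_mean = 0.05) {
  stopifnot(inherits(mat, "tcc_matrix"))
  if (mat$mode != "single_cell") stop("select_gene_tccs expects a single-cell matrix")
  d <- design[match(rownames(mat$counts), design$unit_id), , drop = FALSE]
  if (anyNA(d$condition)) stop("design does not label every cell")
  lev <- sort(unique(d$condition))
  if (length(lev) != 2L) stop("exactly two conditions are required")
  in_gene <- mat$ec_info$genes == gene_id
  if (!any(in_gene)) {
    message(sprintf("select_gene_tccs: no ECs map to gene '%s'; untestable", gene_id))
    return(NULL)
  }
  m <- as.matrix(mat$counts[, in_gene, drop = FALSE])
  mA <- colMeans(m[d$condition == lev[1], , drop = FALSE])
  mB <- colMeans(m[d$condition == lev[2], , drop = FALSE])
  keep <- mA > min_mean & mB > min_mean
  if (!any(keep)) {
    message(sprintf("select_gene_tccs: no ECs of '%s' pass min_mean = %g in both conditions; untestable",
                    gene_id, min_mean))
    return(NULL)
  }
  out <- list(gene_id = gene_id,
              counts = m[, keep, drop = FALSE],
              y = factor(d$condition, levels = lev),
              ec_ids = mat$ec_info$ec_id[in_gene][keep],
              ec_transcripts = mat$ec_info$transcripts[in_gene][keep])
  class(out) <- "gene_tcc_slice"
  out
}

# ridge-stabilized logistic fit by IRLS with step halving; intercept
# unpenalized. Returns unpenalized deviance at the fitted coefficients.
.logistic_ridge <- function(X, y01, lambda = 1e-8, max_iter = 200L,
                            tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  dev_of <- function(b) {
    eta <- pmin(pmax(drop(Xd %*% b), -30), 30)
    mu <- plogis(eta)
    -2 * sum(y01 * log(mu) + (1 - y01) * log1p(-mu))
  }
  pdev_of <- function(b) dev_of(b) + drop(t(b) %*% pen %*% b)
  pdev <- pdev_of(beta)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    bn <- tryCatch(drop(solve(H, crossprod(Xd, w * z))), error = function(e) NULL)
    if (is.null(bn)) break
    step <- 1
    pd_new <- pdev_of(bn)
    while (!is.finite(pd_new) || pd_new > pdev + 1e-12) {
      step <- step / 2
      if (step < 1e-8) break
      bn <- beta + step * (bn - beta)
      pd_new <- pdev_of(bn)
    }
    conv <- abs(pdev - pd_new) < tol * (abs(pdev) + 1)
    beta <- bn
    pdev <- pd_new
    if (conv) break
  }
  eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
  mu <- plogis(eta)
  separated <- max(abs(ifelse(y01 == 1, 1 - mu, mu))) < 1e-6 ||
    max(abs(beta[-1])) > 25
  list(beta = beta, deviance = dev_of(beta), fitted = mu,
       separated = separated, n_iter = it)
}

#' Logistic-regression isoform-switching test on a gene's TCCs
#'
#' Fits `condition ~ intercept + log(1 + c_ce)` over the gene's retained
#' equivalence classes by maximizing the Bernoulli log-likelihood with a tiny
#' ridge stabilizer, and compares against the intercept-only model by a
#' likelihood-ratio test on `chi-square(E)` where `E` is the number of EC
#' features. Complete separation is flagged (`separated = TRUE`); the LRT is
#' naturally capped at the null deviance and the p-value is still reported
#' from the chi-square tail at that capped statistic.
#'
#' @param slice a [select_gene_tccs()] slice.
#' @param min_cells minimum cells per condition (default 20).
#' @param lambda ridge stabilizer (default 1e-8), numerical conditioning only.
#' @param depth_normalize optionally scale each cell's counts to a common
#'   depth of 10,000 before the `log1p` transform (default FALSE: at equal
#'   simulated depths no scaling is applied).
#' @param cell_totals per-cell totals used when `depth_normalize = TRUE`.
#' @return object of class `switch_test`: list with `gene_id`, `lrt`, `df`,
#'   `pval`, `separated`, `direction` (sign of the per-EC group-mean
#'   difference, second condition minus first), `ec_ids`, and the null/full
#'   deviances.
#' @export
tcc_logistic_test <- function(slice, min_cells = 20L, lambda = 1e-8,
                              depth_normalize = FALSE, cell_totals = NULL) {
  stopifnot(inherits(slice, "gene_tcc_slice"))
  tab <- table(slice$y)
  if (any(tab < min_cells))
    stop(sprintf("fewer than %d cells in a condition", min_cells))
  X <- slice$counts
  if (depth_normalize) {
    if (is.null(cell_totals)) stop("cell_totals required for depth normalization")
    X <- X / cell_totals * 1e4
  }
  X <- log1p(X)
  y01 <- as.integer(slice$y == levels(slice$y)[2])
  fit <- .logistic_ridge(X, y01, lambda = lambda)
  p0 <- mean(y01)
  D0 <- -2 * sum(y01 * log(p0) + (1 - y01) * log(1 - p0))
  lrt <- max(0, D0 - fit$deviance)
  E <- ncol(X)
  mdiff <- colMeans(slice$counts[y01 == 1, , drop = FALSE]) -
    colMeans(slice$counts[y01 == 0, , drop = FALSE])
  out <- list(gene_id = slice$gene_id, lrt = lrt, df = E,
              pval = pchisq(lrt, df = E, lower.tail = FALSE),
              separated = fit$separated,
              direction = sign(mdiff),
              ec_ids = slice$ec_ids,
              null_deviance = D0, deviance = fit$deviance,
              coef = fit$beta)
  class(out) <- "switch_test"
  out
}

#' @export
print.switch_test <- function(x, ...) {
  cat(sprintf("switch_test %s: LRT = %.2f on %d df, p = %.3g%s\n", x$gene_id,
              x$lrt, x$df, x$pval,
              if (x$separated) " (separation flagged)" else ""))
  invisible(x)
}

#' Gene-level contrast on total counts
#'
#' Identical logistic machinery with the single feature `log(1 + per-cell
#' gene total)`; LRT on 1 df. Under pure isoform switching with conserved
#' totals this contrast is null while [tcc_logistic_test()] is not.
#'
#' @inheritParams tcc_logistic_test
#' @return list with `pval`, `lrt`, `df = 1`, `separated`.
#' @export
gene_total_test <- function(slice, min_cells = 20L, lambda = 1e-8) {
  stopifnot(inherits(slice, "gene_tcc_slice"))
  tab <- table(slice$y)
  if (any(tab < min_cells))
    stop(sprintf("fewer than %d cells in a condition", min_cells))
  X <- matrix(log1p(rowSums(slice$counts)), ncol = 1,
              dimnames = list(NULL, "total"))
  y01 <- as.integer(slice$y == levels(slice$y)[2])
  fit <- .logistic_ridge(X, y01, lambda = lambda)
  p0 <- mean(y01)
  D0 <- -2 * sum(y01 * log(p0) + (1 - y01) * log(1 - p0))
  lrt <- max(0, D0 - fit$deviance)
  list(pval = pchisq(lrt, df = 1L, lower.tail = FALSE), lrt = lrt, df = 1L,
       separated = fit$separated)
}

#' Switching test across genes with Bonferroni correction
#'
#' Runs [tcc_logistic_test()] and [gene_total_test()] for each requested gene
#' and applies Bonferroni correction over the number of genes actually tested
#' in the run.
#'
#' @param mat a filtered single-cell `tcc_matrix`.
#' @param design two-condition design.
#' @param genes character vector of genes (default: all single-gene EC genes
#'   in the matrix).
#' @param min_mean EC selection threshold (see [select_gene_tccs()]).
#' @param min_cells minimum cells per condition.
#' @return data.frame per gene: `gene_id`, `n_ecs`, `lrt`, `df`, `pval`,
#'   `p_bonf` (`min(1, m * p)`), `separated`, `gene_total_pval`; untestable
#'   genes carry `NA`.
#' @export
test_isoform_switching <- function(mat, design, genes = NULL, min_mean = 0.05,
                                   min_cells = 20L) {
  if (is.null(genes))
    genes <- sort(unique(mat$ec_info$genes[mat$ec_info$n_genes == 1L]))
  rows <- lapply(genes, function(g) {
    sl <- suppressMessages(select_gene_tccs(mat, g, design, min_mean))
    if (is.null(sl))
      return(data.frame(gene_id = g, n_ecs = 0L, lrt = NA_real_, df = NA_integer_,
                        pval = NA_real_, separated = NA,
                        gene_total_pval = NA_real_, stringsAsFactors = FALSE))
    st <- tcc_logistic_test(sl, min_cells = min_cells)
    gt <- gene_total_test(sl, min_cells = min_cells)
    data.frame(gene_id = g, n_ecs = st$df, lrt = st$lrt, df = st$df,
               pval = st$pval, separated = st$separated,
               gene_total_pval = gt$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$pval))
  out$p_bonf <- pmin(1, out$pval * m)
  out[, c("gene_id", "n_ecs", "lrt", "df", "pval", "p_bonf", "separated",
          "gene_total_pval")]
}

#' Percentile bootstrap confidence intervals for per-EC mean TCCs
#'
#' Resamples cells with replacement within each condition and recomputes the
#' per-EC mean; the CI is the 2.5th/97.5th percentile of the bootstrap
#' distribution (at the default 95% level). Deterministic for a fixed seed.
#' A condition with a single cell yields a degenerate CI equal to the point
#' value and is flagged.
#'
#' @param slice a [select_gene_tccs()] slice.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data.frame: `ec_id`, `condition`, `mean`, `lower`, `upper`, `B`,
#'   `degenerate`.
#' @export
ec_bootstrap_ci <- function(slice, B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(slice, "gene_tcc_slice"), B >= 1L)
  set.seed(seed)
  alpha <- (1 - level) / 2
  out <- list()
  for (cond in levels(slice$y)) {
    m <- slice$counts[slice$y == cond, , drop = FALSE]
    n <- nrow(m)
    pt <- colMeans(m)
    if (n == 1L) {
      out[[cond]] <- data.frame(ec_id = slice$ec_ids, condition = cond,
                                mean = pt, lower = pt, upper = pt, B = B,
                                degenerate = TRUE, stringsAsFactors = FALSE)
      next
    }
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    bm <- matrix(0, B, ncol(m))
    for (b in seq_len(B)) bm[b, ] <- colMeans(m[idx[, b], , drop = FALSE])
    qs <- apply(bm, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
    out[[cond]] <- data.frame(ec_id = slice$ec_ids, condition = cond,
                              mean = pt, lower = qs[1, ], upper = qs[2, ],
                              B = B, degenerate = FALSE,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
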