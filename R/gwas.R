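#' @title Kinship- and structure-corrected association scan
#' @description Single-marker generalized-least-squares scan on the pooled
#'   stratified panel. The polygenic and residual variances are estimated
#'   once under the null (EMMAX/P3D scheme) by REML with the Astle-Balding
#'   kinship and the leading principal components as fixed covariates; every
#'   marker is then tested by GLS with the fixed covariance V = sg2 K +
#'   se2 I. Multiple testing by Bonferroni and Benjamini-Hochberg FDR;
#'   significant markers are grouped into loci by single-linkage clustering
#'   of allelic-correlation R-squared above 0.8.
#' @name gwas
NULL

#' Astle-Balding kinship matrix
#'
#' K = (1/M) sum_m (x_m - 2 p_m)(x_m - 2 p_m)' / (2 p_m (1 - p_m)) over M
#' markers with alternate-allele frequencies p_m.
#'
#' @param G A complete [geno_matrix()] or dosage matrix with every marker
#'   polymorphic.
#' @return Symmetric positive semi-definite lines x lines matrix.
#' @export
kinship <- function(G) {
  X <- prep_X(G)
  p <- colMeans(X) / 2
  vars <- colMeans(X^2) - colMeans(X)^2
  if (any(p <= 0 | p >= 1) || any(vars <= 0)) {
    stop("monomorphic marker(s) present: filter before computing kinship")
  }
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(W) / ncol(X)
  (K + t(K)) / 2
}

#' Principal-component covariates for population structure
#'
#' First `n_components` principal-component scores of the centered genotype
#' matrix. Signs are fixed (largest-magnitude loading positive) so results
#' are deterministic.
#'
#' @param G A complete [geno_matrix()] or dosage matrix.
#' @param n_components Number of components (default 10), truncated with a
#'   warning when exceeding the matrix rank.
#' @return Lines x components score matrix.
#' @export
pc_covariates <- function(G, n_components = 10) {
  X <- prep_X(G)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  r <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (n_components > r) {
    warning("requested ", n_components, " components but rank is ", r,
            "; truncating")
    n_components <- r
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(X)
  scores
}

# Null-model REML for y = C b + g + e, g ~ N(0, sg2 K), via eigen of K.
null_reml <- function(y, K, C) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Ct <- crossprod(eg$vectors, C)
  q <- ncol(C)
  parts <- function(lam) {
    w <- 1 / (d + lam)
    A <- crossprod(Ct, Ct * w)
    beta <- solve(A, crossprod(Ct, yt * w))
    r <- yt - Ct %*% beta
    sg2 <- sum(r^2 * w) / (n - q)
    ll <- -0.5 * ((n - q) * log(sg2) - sum(log(w)) +
                    determinant(A, logarithm = TRUE)$modulus + (n - q))
    list(ll = as.numeric(ll), sg2 = sg2, beta = beta)
  }
  opt <- stats::optimize(function(l) parts(exp(l))$ll,
                         interval = log(c(1e-5, 1e5)), maximum = TRUE)
  lam <- exp(opt$maximum)
  p <- parts(lam)
  list(sg2 = p$sg2, se2 = lam * p$sg2, lambda = lam,
       U = eg$vectors, d = d)
}

#' Genome-wide association scan
#'
#' @param G A complete [geno_matrix()].
#' @param y Phenotypes (typically line BLUPs), named by line or ordered as
#'   the genotype rows.
#' @param K Kinship matrix from [kinship()]; set `NULL` (with
#'   `covariates = NULL`) for a naive uncorrected scan.
#' @param covariates Covariate matrix (e.g. [pc_covariates()]); an intercept
#'   is always added.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param fdr_q Benjamini-Hochberg FDR level.
#' @param ld_threshold Allelic R-squared above which significant markers are
#'   merged into one locus.
#' @return Object of class `gwas_result`: per-marker table (`effect`, `se`,
#'   `p`, `score` = -log10 p, `evar_pct`), thresholds, significant sets, LD
#'   matrix and locus clusters among FDR-significant markers.
#' @export
gwas_scan <- function(G, y, K = NULL, covariates = NULL, alpha = 0.05,
                      fdr_q = 0.05, ld_threshold = 0.8) {
  X <- prep_X(G)
  if (!is.null(names(y))) y <- y[rownames(X)]
  stopifnot(length(y) == nrow(X), !anyNA(y))
  n <- nrow(X)
  C <- cbind(intercept = rep(1, n), covariates)
  if (is.null(K)) {
    # naive scan: V = se2 I; equivalent to rotating with the identity
    U <- diag(n); d <- rep(0, n)
    se2 <- stats::var(y)
    ys <- y / sqrt(se2)
    Cs <- C / sqrt(se2)
    Xs <- X / sqrt(se2)
    vcomp <- list(sg2 = 0, se2 = se2)
  } else {
    vcomp <- null_reml(y, K, C)
    w <- 1 / sqrt(vcomp$sg2 * (vcomp$d + vcomp$lambda))
    if (any(!is.finite(w))) {
      warning("singular covariance; adding ridge jitter 1e-8")
      w <- 1 / sqrt(vcomp$sg2 * (vcomp$d + vcomp$lambda) + 1e-8)
    }
    ys <- crossprod(vcomp$U, y) * w
    Cs <- crossprod(vcomp$U, C) * w
    Xs <- crossprod(vcomp$U, X) * w
  }
  # residualize on the covariates (GLS with known V: unit-variance errors)
  qrC <- qr(Cs)
  yr <- qr.resid(qrC, ys)
  Xr <- qr.resid(qrC, Xs)
  xtx <- colSums(Xr^2)
  xty <- as.numeric(crossprod(Xr, yr))
  yty <- sum(yr^2)
  effect <- xty / xtx
  se <- 1 / sqrt(xtx)
  z <- effect / se
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  evar <- 100 * (xty^2) / (xtx * yty)
  M <- ncol(X)
  res <- data.frame(
    marker = colnames(X),
    chrom = if (inherits(G, "geno_matrix")) G$map$chrom else NA,
    pos = if (inherits(G, "geno_matrix")) G$map$pos else NA,
    effect = effect, se = se, p = p, score = -log10(p), evar_pct = evar,
    stringsAsFactors = FALSE
  )
  bonf <- bonferroni_threshold(alpha, M)
  res$sig_bonferroni <- res$p <= bonf
  fdr <- fdr_select(res$p, fdr_q)
  res$sig_fdr <- seq_len(M) %in% fdr$selected
  sig <- res$marker[res$sig_fdr]
  ld <- if (length(sig) >= 2) ld_r2(G, sig, threshold = ld_threshold) else NULL
  structure(list(
    table = res, n = n, m = M,
    vcomp = vcomp[c("sg2", "se2")],
    bonferroni = bonf, fdr_threshold = fdr$threshold,
    significant = list(bonferroni = res$marker[res$sig_bonferroni],
                       fdr = sig),
    ld = ld
  ), class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %d markers, %d lines; sg2 = %.4g, se2 = %.4g\n",
              x$m, x$n, x$vcomp$sg2, x$vcomp$se2))
  cat(sprintf("  Bonferroni (%g): %d significant; FDR: %d significant%s\n",
              x$bonferroni, length(x$significant$bonferroni),
              length(x$significant$fdr),
              if (is.na(x$fdr_threshold)) " (threshold undefined)" else ""))
  invisible(x)
}

#' Bonferroni per-test level
#'
#' @param alpha Family-wise error level.
#' @param M Number of tests.
#' @return `alpha / M`.
#' @export
bonferroni_threshold <- function(alpha, M) {
  stopifnot(M >= 1, alpha > 0, alpha < 1)
  alpha / M
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending and finds the largest rank k with
#' p_(k) <= k q / M; all ranks up to k are selected. When no rank passes the
#' threshold is flagged undefined (`NA`) and the selection is empty.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return List with `selected` (indices into `pvalues`) and `threshold`
#'   (the p-value cutoff, `NA` when undefined).
#' @export
fdr_select <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  M <- length(pvalues)
  o <- order(pvalues)
  ps <- pvalues[o]
  pass <- which(ps <= seq_len(M) * q / M)
  if (length(pass) == 0) {
    return(list(selected = integer(0), threshold = NA_real_))
  }
  k <- max(pass)
  list(selected = sort(o[seq_len(k)]), threshold = ps[k])
}

#' Allelic correlation R-squared and locus clustering
#'
#' Squared Pearson correlation of genotype-dose vectors for each pair of the
#' given markers; pairs above the threshold are merged into loci by single
#' linkage (connected components of the above-threshold graph).
#'
#' @param G A complete [geno_matrix()] or dosage matrix.
#' @param markers Marker ids (column names) to assess.
#' @param threshold R-squared above which two markers share a locus
#'   (default 0.8).
#' @return List with `r2` (matrix) and `locus` (integer cluster id per
#'   marker).
#' @export
ld_r2 <- function(G, markers, threshold = 0.8) {
  X <- prep_X(G)
  stopifnot(all(markers %in% colnames(X)))
  sub <- X[, markers, drop = FALSE]
  if (any(apply(sub, 2, stats::sd) == 0)) stop("constant marker in LD set")
  r2 <- stats::cor(sub)^2
  list(r2 = r2, locus = cluster_loci(r2, threshold))
}

#' Single-linkage locus clusters from an R-squared matrix
#'
#' @param r2 Symmetric R-squared matrix.
#' @param threshold Link threshold (strictly greater than).
#' @return Integer cluster id per marker, named.
#' @export
cluster_loci <- function(r2, threshold = 0.8) {
  m <- nrow(r2)
  id <- seq_len(m)
  find <- function(i) { while (id[i] != i) i <- id[i]; i }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j && r2[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) id[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  out <- match(roots, unique(roots))
  names(out) <- rownames(r2)
  out
}

#' Plot-ready Manhattan and QQ tables
#'
#' Adds a cumulative genome coordinate per marker (strictly increasing along
#' the table), the two -log10 thresholds as horizontal-line values, and an
#' observed-vs-expected quantile table for the QQ plot (expected quantile
#' for rank i of M is -log10(i / (M + 1))).
#'
#' @param result A `gwas_result`.
#' @return List with `manhattan` (marker, chrom, pos, cum_pos, score,
#'   sig flags), `thresholds`, `qq`.
#' @export
manhattan_table <- function(result) {
  stopifnot(inherits(result, "gwas_result"))
  tab <- result$table
  if (any(is.na(tab$chrom))) {
    warning("unplaced markers binned into 'chrU'")
    tab$chrom[is.na(tab$chrom)] <- "chrU"
    tab$pos[is.na(tab$pos)] <- seq_len(sum(is.na(tab$pos)))
  }
  chroms <- unique(tab$chrom)
  span <- vapply(chroms, function(ch) max(tab$pos[tab$chrom == ch]) + 1,
                 numeric(1))
  offset <- c(0, cumsum(span))[seq_along(chroms)]
  names(offset) <- chroms
  ord <- order(match(tab$chrom, chroms), tab$pos, tab$marker)
  tab <- tab[ord, ]
  tab$cum_pos <- offset[tab$chrom] + tab$pos +
    (seq_len(nrow(tab)) - 1) * 1e-9  # strict monotonicity under ties
  M <- nrow(tab)
  qq <- data.frame(
    expected = -log10(seq_len(M) / (M + 1)),
    observed = sort(tab$score, decreasing = TRUE)
  )
  list(
    manhattan = tab[, c("marker", "chrom", "pos", "cum_pos", "score",
                        "sig_bonferroni", "sig_fdr")],
    thresholds = c(bonferroni = -log10(result$bonferroni),
                   fdr = if (is.na(result$fdr_threshold)) NA_real_
                         else -log10(result$fdr_threshold)),
    qq = qq
  )
}
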