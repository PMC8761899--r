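gwas_fixture <- function() {
  fixture("gwas_panel", function() {
    gm <- genome_map(7, 100, 40)
    G <- simulate_study_panel(gm, sizes = c(50, 50, 50), seed = 33)
    Gc <- filter_markers(G, 1, 0.05)$geno
    list(geno = Gc, K = kinship(Gc), pcs = pc_covariates(Gc, 10))
  })
}

test_that("kinship is symmetric, PSD, and duplicates share entries", {
  fx <- gwas_fixture()
  K <- fx$K
  expect_true(isSymmetric(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # duplicated fully inbred lines: K entry equals the diagonal
  G <- fx$geno
  g2 <- G$geno[c(1, 1, 2:20), ]
  rownames(g2) <- sprintf("d%02d", 1:21)
  K2 <- kinship(g2[, apply(g2, 2, function(x) length(unique(x)) > 1)])
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_error(kinship(cbind(a = rep(1, 5), b = c(0, 1, 2, 1, 0))),
               "monomorphic")
})

test_that("unstructured panels give near-zero mean off-diagonal kinship", {
  set.seed(44)
  M <- 500
  X <- matrix(rbinom(60 * M, 2, 0.5), 60, M)
  colnames(X) <- paste0("m", 1:M); rownames(X) <- paste0("l", 1:60)
  K <- kinship(X)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 2 / sqrt(M))
})

test_that("principal components separate the three populations", {
  fx <- gwas_fixture()
  pcs <- fx$pcs
  pop <- fx$geno$lines$population
  # silhouette-style check on the first two PCs
  d <- as.matrix(dist(pcs[, 1:2]))
  sil <- vapply(seq_along(pop), function(i) {
    a <- mean(d[i, pop == pop[i]][-which(which(pop == pop[i]) == i)])
    b <- min(vapply(setdiff(unique(pop), pop[i]),
                    function(q) mean(d[i, pop == q]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # duplicated lines get identical scores; scores are orthogonal
  expect_lt(max(abs(crossprod(pcs) - diag(colSums(pcs^2)))), 1e-6)
})

test_that("GLS scan with identity kinship matches the explicit formula", {
  set.seed(55)
  n <- 40; m <- 12
  X <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("l", 1:n), paste0("k", 1:m)))
  y <- rnorm(n) + X[, 3] * 0.8
  K <- diag(n); dimnames(K) <- list(rownames(X), rownames(X))
  res <- gwas_scan(X, y, K = K)
  V <- res$vcomp$sg2 + res$vcomp$se2
  manual_p <- vapply(1:m, function(j) {
    xr <- X[, j] - mean(X[, j]); yr <- y - mean(y)
    z <- (sum(xr * yr) / sum(xr^2)) / sqrt(V / sum(xr^2))
    2 * pnorm(-abs(z))
  }, numeric(1))
  expect_equal(res$table$p, manual_p, tolerance = 1e-10)
  expect_true(all(res$table$evar_pct >= 0 & res$table$evar_pct <= 100))
})

test_that("kinship+PC correction yields uniform null p-values; naive scan inflates", {
  fx <- gwas_fixture()
  pop_shift <- c(AxI = 0, KxA = 1.5, KxI = 3)[fx$geno$lines$population]
  set.seed(66)
  y <- pop_shift + rnorm(length(pop_shift))
  names(y) <- fx$geno$lines$line
  res <- gwas_scan(fx$geno, y, fx$K, fx$pcs)
  expect_gt(suppressWarnings(ks.test(res$table$p, "punif"))$p.value, 0.01)
  naive <- gwas_scan(fx$geno, y, K = NULL)
  expect_gt(mean(naive$table$p < 0.05), 0.07)
  expect_lt(mean(res$table$p < 0.05), 0.12)
})

test_that("a moderate simulated QTL surfaces in the top LD cluster at design scale", {
  gm <- genome_map(7, 100, 25)
  G <- simulate_study_panel(gm, sizes = c(102, 100, 104), seed = 33)
  Gc <- filter_markers(G, 1, 0.05)$geno
  K <- kinship(Gc)
  pcs <- pc_covariates(Gc, 10)
  found <- 0
  for (s in 1:5) {
    set.seed(70 + s)
    qtl <- sample(ncol(Gc$geno), 1)
    g <- Gc$geno[, qtl]
    y <- g + rnorm(length(g), 0, sqrt(var(g) * (1 / 0.08 - 1)))
    names(y) <- Gc$lines$line
    res <- gwas_scan(Gc, y, K, pcs)
    top10 <- order(res$table$p)[1:10]
    r2 <- cor(Gc$geno[, top10, drop = FALSE], g)^2
    if (max(r2) > 0.5) found <- found + 1
  }
  expect_gte(found, 4)
})

test_that("Bonferroni threshold identities", {
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(-log10(bonferroni_threshold(0.05, 1000)), log10(1000 / 0.05))
})

test_that("BH step-up: hand example, degenerate case, oracle equivalence", {
  # cutoffs are (0.01, 0.02, 0.03, 0.04, 0.05); ranks 1-2 pass, 3-4 miss
  # (0.039 > 0.03 and 0.041 > 0.04), so the step-up selects the first two
  p_hand <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  sel <- fdr_select(p_hand, q = 0.05)
  expect_equal(sel$selected, 1:2)
  expect_equal(sel$threshold, 0.008)
  expect_identical(sel$selected,
                   which(p.adjust(p_hand, "BH") <= 0.05))
  none <- fdr_select(rep(1, 5), 0.05)
  expect_equal(none$selected, integer(0))
  expect_true(is.na(none$threshold))
  brute_bh <- function(p, q) {
    M <- length(p); o <- order(p); ps <- p[o]
    best <- 0
    for (k in seq_len(M)) if (ps[k] <= k * q / M) best <- k
    if (best == 0) integer(0) else sort(o[seq_len(best)])
  }
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    expect_identical(fdr_select(p, 0.05)$selected, brute_bh(p, 0.05))
  }
})

test_that("Bonferroni selections are a subset of BH selections", {
  set.seed(88)
  for (i in 1:20) {
    p <- runif(100)^3
    bonf <- which(p <= bonferroni_threshold(0.05, 100))
    bh <- fdr_select(p, 0.05)$selected
    expect_true(all(bonf %in% bh))
  }
})

test_that("LD R-squared and single-linkage locus clustering", {
  fx <- gwas_fixture()
  ids <- fx$geno$map$marker[c(1, 1, 50)]
  # identical vectors cluster together with R2 = 1
  X <- fx$geno$geno
  dup <- cbind(a = X[, 1], b = X[, 1], c = X[, 50])
  ld <- ld_r2(dup, c("a", "b", "c"))
  expect_equal(ld$r2["a", "b"], 1)
  expect_equal(ld$locus[["a"]], ld$locus[["b"]])
  # chained clustering: links a-b and b-c merge all three
  r2 <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.85, 0.6, 0.85, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(unname(cluster_loci(r2, 0.8)), c(1, 1, 1))
  r2[2, 3] <- r2[3, 2] <- 0.5
  expect_equal(unname(cluster_loci(r2, 0.8)), c(1, 1, 2))
  # independent markers: mean R2 near 1/(n-1)
  set.seed(99)
  n <- 80
  Z <- matrix(rbinom(n * 40, 2, 0.5), n, 40,
              dimnames = list(paste0("l", 1:n), paste0("m", 1:40)))
  ld2 <- ld_r2(Z, colnames(Z))
  expect_lt(abs(mean(ld2$r2[upper.tri(ld2$r2)]) - 1 / (n - 1)), 0.01)
  expect_error(ld_r2(cbind(const = rep(1, 5), z = c(0, 1, 2, 0, 1)),
                     c("const", "z")), "constant")
})

test_that("Manhattan and QQ tables are plot-ready", {
  fx <- gwas_fixture()
  set.seed(101)
  y <- rnorm(nrow(fx$geno$geno))
  names(y) <- fx$geno$lines$line
  res <- gwas_scan(fx$geno, y, fx$K, fx$pcs)
  mt <- manhattan_table(res)
  expect_true(all(diff(mt$manhattan$cum_pos) > 0))
  expect_equal(nrow(mt$qq), res$m)
  expect_equal(mt$qq$expected[1], -log10(1 / (res$m + 1)))
  expect_equal(mt$thresholds[["bonferroni"]], -log10(0.05 / res$m))
  # score definition
  expect_equal(res$table$score, -log10(res$table$p))
})
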