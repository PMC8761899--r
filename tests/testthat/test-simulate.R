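test_that("parental divergence hits requested fractions", {
  gm <- genome_map(1, 100, 10000)
  # zero divergence between parents 1 and 2
  P <- simulate_parents(gm, c(0, 0.4, 0.4), seed = 1)
  expect_identical(P[1, ], P[2, ])
  # maximal divergence between parents 1 and 3
  P <- simulate_parents(gm, c(0, 1, 1), seed = 2)
  expect_true(all(P[1, ] != P[3, ]))
  # binomial sampling error at n = 10,000, divergence 0.30
  P <- simulate_parents(gm, c(0.30, 0.45, 0.45), seed = 3)
  d <- parent_divergence(P)
  expect_lt(abs(d[["d12"]] - 0.30), 0.015)
  expect_lt(abs(d[["d13"]] - 0.45), 0.015)
  # empty map rejected
  expect_error(simulate_parents(gm[0, ], c(0, 0, 0)), "no markers")
  # triangle-violating divergences rejected
  expect_error(simulate_parents(gm, c(0.9, 0.9, 0.9)), "pattern")
})

test_that("residual heterozygosity decays as 0.5^g", {
  gm <- genome_map(1, 100, 1)
  p1 <- 0L; p2 <- 1L
  for (g in c(1, 3, 6)) {
    G <- simulate_ril_population(p1, p2, 10000, g, gm, seed = 10 + g)
    het <- mean(G$geno == 1)
    expect_lt(abs(het - 0.5^g), 0.004 + 0.01 * (g == 1))
  }
})

test_that("allele frequency at a segregating marker is one half", {
  gm <- genome_map(1, 100, 1)
  G <- simulate_ril_population(0L, 1L, 10000, 6, gm, seed = 21)
  expect_lt(abs(mean(G$geno) / 2 - 0.5), 0.02)
})

test_that("map-function limits: complete linkage and independence", {
  # two markers 0 cM apart never recombine
  gm0 <- data.frame(marker = c("a", "b"), chrom = "chr1", pos = c(50, 50))
  class(gm0) <- c("genome_map", "data.frame")
  G <- simulate_ril_population(c(0L, 0L), c(1L, 1L), 500, 6, gm0, seed = 31)
  expect_true(all(G$geno[, 1] == G$geno[, 2]))
  # markers on different chromosomes are inherited independently
  gm2 <- genome_map(2, 100, 1)
  G2 <- simulate_ril_population(c(0L, 0L), c(1L, 1L), 4000, 6, gm2, seed = 32)
  hom <- G2$geno[G2$geno[, 1] %in% c(0, 2) & G2$geno[, 2] %in% c(0, 2), ]
  recomb <- mean(hom[, 1] != hom[, 2])
  expect_lt(abs(recomb - 0.5), 0.03)
})

test_that("identical parents give a monomorphic population with a warning", {
  gm <- small_map(1, 5)
  expect_warning(simulate_ril_population(rep(0L, 5), rep(0L, 5), 10, 6, gm),
                 "monomorphic")
})

test_that("connected populations carry only their own parents' alleles", {
  gm <- small_map(2, 30)
  panel <- simulate_study_panel(gm, sizes = c(20, 20, 20), seed = 41)
  P <- attr(panel, "parents")
  axi <- panel$geno[panel$lines$population == "AxI", ]
  # AxI descends from parents 1 and 2: wherever they agree, AxI is fixed
  same <- which(P[1, ] == P[2, ])
  for (j in same) {
    expect_true(all(axi[, j] == 2 * P[1, j]))
  }
})

test_that("genetic values hit variance targets exactly and respect GEI", {
  st <- study_fixture()
  tv <- st$sim$values
  arch <- st$arch
  expect_equal(var(tv$values$protein$main), arch$traits$protein$sg2,
               tolerance = 1e-9)
  expect_equal(var(tv$values$yield$main), arch$traits$yield$sg2,
               tolerance = 1e-9)
  # interaction mean square of GEI deviations matches sge2 exactly
  D <- tv$values$protein$gv - tv$values$protein$main
  dc <- sweep(D - rowMeans(D), 2, colMeans(D) - mean(D))
  ims <- sum(dc^2) / ((nrow(D) - 1) * (ncol(D) - 1))
  expect_equal(ims, arch$traits$protein$sge2, tolerance = 1e-9)
})

test_that("zero GEI makes line values identical across environments", {
  gm <- small_map(2, 15)
  G <- simulate_study_panel(gm, sizes = c(10, 10, 10), seed = 51)
  arch <- trait_architecture(
    traits = list(
      yield = list(mean = 5, env_effects = c(a = 0, b = 0), sg2 = 1,
                   sge2 = 0, se2 = 0.5, block_sd = 0),
      protein = list(mean = 24, env_effects = c(a = 0, b = 0), sg2 = 0.7,
                     sge2 = 0, se2 = 0.5, block_sd = 0)
    ), n_qtl = 10, rg_traits = 0
  )
  tv <- assign_trait_values(G, arch, seed = 52)
  expect_equal(tv$values$yield$gv[, 1], tv$values$yield$gv[, 2])
})

test_that("perfect effect correlation gives perfectly correlated traits", {
  gm <- small_map(2, 15)
  G <- simulate_study_panel(gm, sizes = c(10, 10, 10), seed = 61)
  arch <- trait_architecture(
    traits = list(
      yield = list(mean = 5, env_effects = c(a = 0, b = 0), sg2 = 1,
                   sge2 = 0, se2 = 0.5, block_sd = 0),
      protein = list(mean = 24, env_effects = c(a = 0, b = 0), sg2 = 0.7,
                     sge2 = 0, se2 = 0.5, block_sd = 0)
    ), n_qtl = 10, rg_traits = 1
  )
  tv <- assign_trait_values(G, arch, seed = 62)
  expect_equal(cor(tv$values$yield$main, tv$values$protein$main), 1,
               tolerance = 1e-9)
})

test_that("requesting more causal loci than polymorphic markers errors", {
  gm <- small_map(1, 5)
  G <- simulate_study_panel(gm, sizes = c(5, 5, 5), seed = 71)
  expect_error(assign_trait_values(G, study_architecture(n_qtl = 100)),
               "polymorphic")
})

test_that("trial plots decompose as mean + environment + genetic value", {
  gm <- small_map(2, 15)
  G <- simulate_study_panel(gm, sizes = c(8, 8, 8), seed = 81)
  arch <- trait_architecture(
    traits = list(
      yield = list(mean = 5, env_effects = c(a = 1, b = -1), sg2 = 1,
                   sge2 = 0, se2 = 0, block_sd = 0),
      protein = list(mean = 24, env_effects = c(a = 0, b = 0), sg2 = 0.7,
                     sge2 = 0, se2 = 0, block_sd = 0)
    ), n_qtl = 10, rg_traits = 0
  )
  tv <- assign_trait_values(G, arch, seed = 82)
  pl <- simulate_trial(tv, arch, n_blocks = 2, seed = 83,
                       derive_protein_yield = FALSE)
  y <- pl[pl$trait == "yield", ]
  expected <- 5 + c(a = 1, b = -1)[y$environment] +
    tv$values$yield$gv[cbind(match(y$line, rownames(tv$values$yield$gv)),
                             match(y$environment, c("a", "b")))]
  expect_equal(y$value, unname(expected))
})

test_that("protein yield is exactly yield times protein over 100, per plot", {
  st <- study_fixture()
  pl <- st$sim$plots
  key <- function(d) paste(d$line, d$environment, d$block)
  y <- pl[pl$trait == "yield", ]
  p <- pl[pl$trait == "protein", ]
  py <- pl[pl$trait == "protein_yield", ]
  p <- p[match(key(y), key(p)), ]
  py <- py[match(key(y), key(py)), ]
  expect_equal(py$value, y$value * p$value / 100, tolerance = 1e-12)
})

test_that("study-default trial emits 306 x 3 x 3 plot records per trait", {
  st <- study_fixture()
  pl <- st$sim$plots
  expect_equal(sum(pl$trait == "protein"), 306 * 3 * 3)
  expect_equal(sum(pl$trait == "yield"), 2754)
  expect_false(any(duplicated(pl[, c("line", "environment", "block", "trait")])))
})

test_that("missingness overlay respects rates, determinism and identity", {
  gm <- genome_map(1, 100, 2)
  G <- simulate_ril_population(c(0L, 0L), c(1L, 1L), 10000, 6, gm, seed = 91)
  expect_false(anyNA(add_missingness(G, 0, 0, seed = 92)$geno))
  Gm <- add_missingness(G, c(0.5, 0.1), 0, seed = 93)
  rate <- colMeans(is.na(Gm$geno))
  expect_lt(abs(rate[1] - 0.5), 0.013)
  expect_lt(abs(rate[2] - 0.1), 0.013)
  # observed entries unchanged
  obs <- !is.na(Gm$geno)
  expect_identical(Gm$geno[obs], G$geno[obs])
  # same seed, same mask
  Gm2 <- add_missingness(G, c(0.5, 0.1), 0, seed = 93)
  expect_identical(Gm$geno, Gm2$geno)
  expect_error(add_missingness(G, 1, 0), "no data left")
})
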