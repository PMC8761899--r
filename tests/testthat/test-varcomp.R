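test_that("single-environment ANOVA matches a hand computation on 6 plots", {
  pl <- hand_plots()
  # grand mean 12; line means 10, 12, 14; block means 12.333, 11.667
  # SS_G = 2 * ((10-12)^2 + 0 + (14-12)^2) = 16, df 2, MS_G = 8
  # SS_B = 3 * ((1/3)^2 + (1/3)^2) = 2/3, df 1, MS_B = 2/3
  # SS_T = 1+9+1+1+9+1 = 22; SS_e = 22 - 16 - 2/3 = 16/3; df 2, MS_e = 8/3
  vc <- anova_single_env(pl, "t", "E1")
  expect_equal(vc$m, 12)
  expect_equal(vc$components[["se2"]], 8 / 3)
  expect_equal(vc$components[["sg2"]], (8 - 8 / 3) / 2)
  expect_equal(vc$components[["sb2"]], 0)  # (2/3 - 8/3)/3 truncated
  expect_true("sb2" %in% vc$truncated)
  expect_equal(vc$tests$F[1], 8 / (8 / 3))
})

test_that("all-equal plot values give zero components", {
  pl <- hand_plots()
  pl$value <- 7
  vc <- anova_single_env(pl, "t", "E1")
  expect_equal(vc$components[["sg2"]], 0)
  expect_equal(vc$components[["se2"]], 0)
})

test_that("unbalanced single-environment data are rejected with advice", {
  pl <- hand_plots()[-1, ]
  expect_error(anova_single_env(pl, "t", "E1"), "REML")
})

test_that("EMS estimates agree with REML on balanced interior data", {
  pl <- balanced_plots(L = 40, e = 3, n = 3, sg2 = 1.2, sge2 = 0.6,
                       se2 = 0.8, seed = 5)
  ems <- anova_multi_env(pl, "t")
  reml <- anova_multi_env(pl, "t", method = "reml")
  for (cmp in c("sg2", "sge2", "se2")) {
    expect_gt(ems$components[[cmp]], 0)
    expect_equal(ems$components[[cmp]], reml$components[[cmp]],
                 tolerance = 1e-4)
  }
})

test_that("multi-environment EMS matches explicit quadratic forms on a tiny design", {
  # 4 lines x 2 envs x 2 blocks with hand-checkable expectations
  pl <- balanced_plots(L = 4, e = 2, n = 2, sg2 = 2, sge2 = 1, se2 = 0.5,
                       seed = 11)
  vc <- anova_multi_env(pl, "t")
  y <- pl$value
  m <- mean(y)
  gbar <- tapply(y, pl$line, mean)
  cell <- tapply(y, list(pl$line, pl$environment), mean)
  ebar <- tapply(y, pl$environment, mean)
  ms_g <- 4 * sum((gbar - m)^2) / 3
  ms_ge <- 2 * sum((sweep(sweep(cell, 1, gbar), 2, ebar) + m)^2) / 3
  bebar <- tapply(y, list(pl$environment, pl$block), mean)
  ss_be <- 4 * sum(sweep(bebar, 1, ebar)^2)
  ss_e <- sum((y - m)^2) - 4 * sum((gbar - m)^2) - 8 * sum((ebar - m)^2) -
    2 * sum((sweep(sweep(cell, 1, gbar), 2, ebar) + m)^2) - ss_be
  ms_e <- ss_e / 6
  expect_equal(vc$components[["se2"]], ms_e)
  expect_equal(vc$components[["sge2"]], max(0, (ms_ge - ms_e) / 2))
  expect_equal(vc$components[["sg2"]], max(0, (ms_g - ms_ge) / 4))
})

test_that("identical rankings with equal spacing across environments give zero GEI", {
  base <- expand.grid(line = sprintf("l%d", 1:5), environment = c("E1", "E2"),
                      block = 1:2, stringsAsFactors = FALSE)
  base$population <- "p"; base$trait <- "t"
  base$value <- as.integer(sub("l", "", base$line)) +
    ifelse(base$environment == "E2", 3, 0)
  vc <- anova_multi_env(base, "t")
  expect_equal(vc$components[["sge2"]], 0)
  expect_equal(vc$components[["se2"]], 0)
})

test_that("nested population model recovers between- and within-population variance", {
  st <- study_fixture()
  vc <- anova_multi_env(st$sim$plots, "protein", include_population = TRUE)
  expect_identical(vc$method, "reml")
  expect_setequal(names(vc$components),
                  c("sr2", "sgr2", "sre2", "sgre2", "sb2", "se2"))
  # within-population genetic variance dominates among-population variance
  expect_gt(vc$components[["sgr2"]], vc$components[["sr2"]])
})

test_that("residual sum of squares is never negative on random balanced data", {
  for (s in 1:5) {
    pl <- balanced_plots(L = 8, e = 3, n = 2, seed = 100 + s)
    vc <- anova_multi_env(pl, "t")
    expect_gte(vc$components[["se2"]], 0)
    expect_true(all(vc$components[c("sg2", "sge2", "sb2")] >= 0))
  }
})

test_that("genetic coefficient of variation follows its definition", {
  expect_equal(cv_g(4, 20), 10)
  expect_equal(cv_g(0, 5), 0)
  expect_equal(cv_g(0.724, 24.27), 3.506, tolerance = 5e-4)
  expect_error(cv_g(1, 0), "positive")
})

test_that("heritability formulas and limits", {
  expect_equal(heritability(1, 0, 3)$H2, 1)
  expect_equal(heritability(1, 1, 3)$H2, 0.75)
  expect_equal(heritability(1, 1, 1e9)$H2, 1, tolerance = 1e-8)
  expect_equal(heritability(1, 1, 3, sge2 = 1, e = 2)$H2, 0.6)
  # with zero GEI the multi-env formula reduces to single-env with e*n reps
  expect_equal(heritability(2, 1.5, 3, sge2 = 0, e = 2)$H2,
               heritability(2, 1.5, 6)$H2)
  # GEI can only reduce heritability
  expect_lte(heritability(1, 1, 3, sge2 = 0.5, e = 3)$H2,
             heritability(1, 1, 3, sge2 = 0, e = 3)$H2)
  expect_error(heritability(0, 0, 3), "undefined")
})

test_that("BLUP shrinkage of line means", {
  expect_equal(blup_line_means(c(8, 10, 12), 0.5), c(9, 10, 11))
  expect_equal(blup_line_means(c(8, 10, 12), 1), c(8, 10, 12))
  expect_equal(blup_line_means(c(8, 10, 12), 0), c(10, 10, 10))
  means <- rnorm(50)
  H2 <- 0.7
  expect_equal(var(blup_line_means(means, H2)), H2^2 * var(means))
  # ranking preserved
  expect_equal(order(blup_line_means(means, 0.3)), order(means))
})

test_that("Pearson correlation: hand example, exact cases, guards", {
  expect_equal(phenotypic_correlation(1:5, c(2, 1, 4, 3, 5)), 0.8)
  x <- rnorm(20)
  expect_equal(phenotypic_correlation(x, 2 * x + 3), 1)
  expect_error(phenotypic_correlation(x, rep(1, 20)), "zero variance")
})

test_that("cross-environment genetic correlation divides out heritability", {
  st <- study_fixture()
  ge <- genetic_correlation_env_pair(st$sim$plots, "protein",
                                     "Lodi1314", "Lodi1415")
  expect_equal(ge$rg, ge$r / (ge$H1 * ge$H2))
  expect_true(ge$rg_clamped >= -1 && ge$rg_clamped <= 1)
  # under compound symmetry the expectation is sg2/(sg2 + sge2) ~ 0.706
  expect_lt(abs(ge$rg - 0.724 / (0.724 + 0.302)), 0.2)
})

test_that("between-trait genetic correlation is exact for degenerate traits", {
  pl <- balanced_plots(L = 30, e = 1, n = 3, sg2 = 1, sge2 = 0, se2 = 0.4,
                       seed = 31)
  same <- pl; same$trait <- "t2"
  both <- rbind(pl, same)
  expect_equal(genetic_correlation_traits(both, "t", "t2", "E1")$rg, 1)
  neg <- pl; neg$trait <- "t2"; neg$value <- -neg$value
  expect_equal(genetic_correlation_traits(rbind(pl, neg), "t", "t2", "E1")$rg,
               -1)
  lin <- pl; lin$trait <- "t2"; lin$value <- 2 * lin$value + 3
  expect_equal(genetic_correlation_traits(rbind(pl, lin), "t", "t2", "E1")$rg,
               1)
})

test_that("trait genetic correlation recovers the generating value on average", {
  arch <- study_architecture(n_qtl = 40)
  gm <- genome_map(7, 100, 15)
  est <- vapply(1:20, function(s) {
    G <- simulate_study_panel(gm, seed = 1000 + s)
    tv <- assign_trait_values(G, arch, seed = 2000 + s)
    pl <- simulate_trial(tv, arch, 3, seed = 3000 + s)
    mean(vapply(c("Lodi1314", "Lodi1415", "Perugia1314"), function(env)
      genetic_correlation_traits(pl, "yield", "protein", env)$rg,
      numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(est) - arch$rg_traits), 0.06)
  st <- study_fixture()
  se <- genetic_correlation_traits(st$sim$plots, "yield", "protein",
                                   "Lodi1314")$se
  expect_true(is.finite(se) && se > 0 && se < 0.5)
})

test_that("environment-wise BLUPs assemble into a complete matrix", {
  st <- study_fixture()
  bl <- env_blups(st$sim$plots, "protein")
  expect_equal(dim(bl), c(306, 3))
  expect_false(anyNA(bl))
  h2 <- attr(bl, "H2")
  expect_true(all(h2 > 0.5 & h2 < 1))
})
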