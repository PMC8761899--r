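#' @title Variance components and heritability from plot-level phenotypes
#' @description Balanced randomized-complete-block designs are analysed by
#'   exact expected-mean-squares (EMS) equations; the nested model with the
#'   RIL-population factor (unbalanced whenever population sizes differ) and
#'   any unbalanced data are analysed by REML through lme4. Negative
#'   method-of-moments estimates are truncated at zero and flagged.
#' @name varcomp
NULL

check_plots <- function(plots, trait) {
  stopifnot(inherits(plots, "data.frame"))
  stopifnot(all(c("line", "environment", "block", "trait", "value") %in%
                  names(plots)))
  out <- plots[plots$trait == trait, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records for trait '", trait, "'")
  out
}

is_balanced <- function(df) {
  tab <- table(df$line, df$environment, df$block)
  all(tab == 1)
}

new_varcomp <- function(components, m, e, n, tests = NULL, method = "ems") {
  flagged <- names(components)[components < 0]
  components[components < 0] <- 0
  structure(list(components = components, m = m, e = e, n = n,
                 truncated = flagged, tests = tests, method = method),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp (%s): grand mean %.4g, e = %d, n = %d\n",
              x$method, x$m, x$e, x$n))
  print(round(x$components, 5))
  if (length(x$truncated)) {
    cat("truncated at 0:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-environment ANOVA (genotype + block, both random)
#'
#' Balanced two-way model y_ir = m + G_i + B_r + e_ir. EMS estimators:
#' se2 = MS_e, sb2 = (MS_B - MS_e)/L, sg2 = (MS_G - MS_e)/n. Returns the
#' genotype F test against the residual.
#'
#' @param plots A `plot_phenotypes` data frame.
#' @param trait Trait name.
#' @param environment Environment to analyse.
#' @param population Optional: restrict to one RIL population.
#' @return A `varcomp` object with components `sg2`, `sb2`, `se2`.
#' @export
anova_single_env <- function(plots, trait, environment, population = NULL) {
  df <- check_plots(plots, trait)
  df <- df[df$environment == environment, , drop = FALSE]
  if (!is.null(population)) df <- df[df$population == population, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for environment '", environment, "'")
  L <- length(unique(df$line))
  n <- length(unique(df$block))
  if (L < 2 || n < 2) stop("need >= 2 lines and >= 2 blocks")
  if (!all(table(df$line, df$block) == 1)) {
    stop("unbalanced data: use the REML option (anova_multi_env(method = 'reml')) ",
         "or complete the design")
  }
  y <- df$value
  gbar <- tapply(y, df$line, mean)
  bbar <- tapply(y, df$block, mean)
  m <- mean(y)
  ss_g <- n * sum((gbar - m)^2)
  ss_b <- L * sum((bbar - m)^2)
  ss_t <- sum((y - m)^2)
  ss_e <- ss_t - ss_g - ss_b
  df_g <- L - 1; df_b <- n - 1; df_e <- (L - 1) * (n - 1)
  ms_g <- ss_g / df_g; ms_b <- ss_b / df_b; ms_e <- ss_e / df_e
  tests <- data.frame(
    term = c("genotype", "block"),
    F = c(ms_g / ms_e, ms_b / ms_e),
    df1 = c(df_g, df_b), df2 = df_e,
    p = c(stats::pf(ms_g / ms_e, df_g, df_e, lower.tail = FALSE),
          stats::pf(ms_b / ms_e, df_b, df_e, lower.tail = FALSE))
  )
  new_varcomp(
    c(sg2 = (ms_g - ms_e) / n, sb2 = (ms_b - ms_e) / L, se2 = ms_e),
    m = m, e = 1L, n = n, tests = tests
  )
}

#' Multi-environment ANOVA with genotype-by-environment interaction
#'
#' Without the population factor (default): fixed environments, random
#' genotype, block-within-environment and GEI; balanced EMS estimators
#' sg2 = (MS_G - MS_GE)/(n e), sge2 = (MS_GE - MS_e)/n, se2 = MS_e, plus the
#' ratio sg2/sge2 and F tests (G over GE; GE and B(E) over error). With
#' `include_population = TRUE`, or whenever the design is unbalanced, the
#' model y = m + R_k + G_i(R_k) + E_j + B_r(E_j) + R_k E_j + G_i(R_k) E_j + e
#' is fitted by REML (environment fixed, all else random).
#'
#' @param plots A `plot_phenotypes` data frame.
#' @param trait Trait name.
#' @param include_population Fit the nested RIL-population model.
#' @param method `"ems"` (balanced designs) or `"reml"`.
#' @return A `varcomp` object. Without the population factor the components
#'   are `sg2`, `sge2`, `sb2`, `se2` plus `ratio_g_ge`; with it, `sr2`,
#'   `sgr2`, `sre2`, `sgre2`, `sb2`, `se2`.
#' @export
anova_multi_env <- function(plots, trait, include_population = FALSE,
                            method = c("ems", "reml")) {
  method <- match.arg(method)
  df <- check_plots(plots, trait)
  envs <- unique(df$environment)
  if (length(envs) < 2) stop("single environment: use anova_single_env()")
  if (include_population || method == "reml" || !is_balanced(df)) {
    return(anova_multi_env_reml(df, include_population))
  }
  L <- length(unique(df$line))
  e <- length(envs)
  n <- length(unique(df$block))
  y <- df$value
  m <- mean(y)
  gbar <- tapply(y, df$line, mean)
  ebar <- tapply(y, df$environment, mean)
  gebar <- tapply(y, list(df$line, df$environment), mean)
  bebar <- tapply(y, list(df$environment, df$block), mean)
  ss_g <- n * e * sum((gbar - m)^2)
  ss_env <- n * L * sum((ebar - m)^2)
  ss_ge <- n * sum((sweep(sweep(gebar, 1, gbar), 2, ebar) + m)^2)
  ss_be <- L * sum(sweep(bebar, 1, ebar)^2)
  ss_t <- sum((y - m)^2)
  ss_e <- ss_t - ss_g - ss_env - ss_ge - ss_be
  df_g <- L - 1
  df_ge <- (L - 1) * (e - 1)
  df_be <- e * (n - 1)
  df_e <- (L - 1) * (n - 1) * e
  ms_g <- ss_g / df_g; ms_ge <- ss_ge / df_ge
  ms_be <- ss_be / df_be; ms_e <- ss_e / df_e
  comps <- c(
    sg2 = (ms_g - ms_ge) / (n * e),
    sge2 = (ms_ge - ms_e) / n,
    sb2 = (ms_be - ms_e) / L,
    se2 = ms_e
  )
  tests <- data.frame(
    term = c("genotype", "gxe", "block(env)"),
    F = c(ms_g / ms_ge, ms_ge / ms_e, ms_be / ms_e),
    df1 = c(df_g, df_ge, df_be),
    df2 = c(df_ge, df_e, df_e),
    p = c(stats::pf(ms_g / ms_ge, df_g, df_ge, lower.tail = FALSE),
          stats::pf(ms_ge / ms_e, df_ge, df_e, lower.tail = FALSE),
          stats::pf(ms_be / ms_e, df_be, df_e, lower.tail = FALSE))
  )
  out <- new_varcomp(comps, m = m, e = e, n = n, tests = tests)
  out$components <- c(out$components,
                      ratio_g_ge = unname(
                        if (out$components["sge2"] > 0)
                          out$components["sg2"] / out$components["sge2"]
                        else NA_real_))
  out
}

anova_multi_env_reml <- function(df, include_population) {
  df$line <- factor(df$line)
  df$environment <- factor(df$environment)
  df$block <- factor(df$block)
  e <- nlevels(df$environment)
  n <- nlevels(df$block)
  if (include_population) {
    df$population <- factor(df$population)
    fit <- lme4::lmer(
      value ~ environment + (1 | population) + (1 | population:line) +
        (1 | environment:block) + (1 | population:environment) +
        (1 | population:line:environment),
      data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else 0
    }
    comps <- c(
      sr2 = pick("population"),
      sgr2 = pick("population:line"),
      sre2 = pick("population:environment"),
      sgre2 = pick("population:line:environment"),
      sb2 = pick("environment:block"),
      se2 = pick("Residual")
    )
  } else {
    fit <- lme4::lmer(
      value ~ environment + (1 | line) + (1 | environment:block) +
        (1 | line:environment),
      data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else 0
    }
    comps <- c(
      sg2 = pick("line"),
      sge2 = pick("line:environment"),
      sb2 = pick("environment:block"),
      se2 = pick("Residual")
    )
    comps <- c(comps, ratio_g_ge = unname(
      if (comps["sge2"] > 0) comps["sg2"] / comps["sge2"] else NA_real_))
  }
  new_varcomp(comps, m = mean(df$value), e = e, n = n, tests = NULL,
              method = "reml")
}

#' Genetic coefficient of variation
#'
#' CV_g = 100 sqrt(sg2) / m, in percent.
#'
#' @param sg2 Genotypic variance component (>= 0).
#' @param m Trait mean (> 0).
#' @return Percent CV_g.
#' @export
cv_g <- function(sg2, m) {
  if (m <= 0) stop("mean must be positive")
  stopifnot(sg2 >= 0)
  100 * sqrt(sg2) / m
}

#' Broad-sense heritability, genotype-mean basis
#'
#' Single environment: H2 = sg2 / (sg2 + se2/n). Multi-environment:
#' H2 = sg2 / (sg2 + sge2/e + se2/(e n)).
#'
#' @param sg2,sge2,se2 Variance components (>= 0).
#' @param e Number of environments.
#' @param n Replicates per environment.
#' @return List of class `heritability` with `H2`, `H`, `e`, `n`.
#' @export
heritability <- function(sg2, se2, n, sge2 = 0, e = 1) {
  stopifnot(sg2 >= 0, se2 >= 0, sge2 >= 0, n >= 1, e >= 1)
  denom <- sg2 + sge2 / e + se2 / (e * n)
  if (denom == 0) stop("undefined heritability: all components zero")
  H2 <- sg2 / denom
  structure(list(H2 = H2, H = sqrt(H2), e = e, n = n,
                 scope = if (e > 1) "multi-environment" else "single-environment"),
            class = "heritability")
}

#' Shrink line means toward the grand mean by heritability
#'
#' BLUP_i = grand mean + H2 (ybar_i - grand mean): the genotype-mean BLUP for
#' a balanced single trial. Preserves ranking; the variance of the BLUPs is
#' H2^2 times the variance of the means.
#'
#' @param means Named numeric vector of line means.
#' @param H2 Broad-sense heritability in \[0, 1\] (or a `heritability`
#'   object).
#' @param center Optional shrinkage target; defaults to `mean(means)`.
#' @return Numeric vector of shrunken line values.
#' @export
blup_line_means <- function(means, H2, center = NULL) {
  if (inherits(H2, "heritability")) H2 <- H2$H2
  stopifnot(H2 >= 0, H2 <= 1)
  if (is.null(center)) center <- mean(means)
  center + H2 * (means - center)
}

#' Per-environment line BLUPs for a trait
#'
#' For each environment: line means over blocks, the single-environment
#' ANOVA heritability, and H2-shrunken BLUPs. These serve as phenotypic data
#' for genomic selection and GWAS.
#'
#' @param plots A `plot_phenotypes` data frame.
#' @param trait Trait name.
#' @return A lines x environments matrix of BLUPs with the per-environment
#'   `H2` attached as attribute `H2`.
#' @export
env_blups <- function(plots, trait) {
  df <- check_plots(plots, trait)
  envs <- sort(unique(df$environment))
  lines <- sort(unique(df$line))
  out <- matrix(NA_real_, length(lines), length(envs),
                dimnames = list(lines, envs))
  h2 <- numeric(length(envs))
  names(h2) <- envs
  for (j in seq_along(envs)) {
    vc <- anova_single_env(plots, trait, envs[j])
    H2 <- heritability(vc$components["sg2"], vc$components["se2"], vc$n)$H2
    sub <- df[df$environment == envs[j], ]
    mns <- tapply(sub$value, sub$line, mean)
    out[names(mns), j] <- blup_line_means(mns, H2)
    h2[j] <- H2
  }
  attr(out, "H2") <- h2
  out
}

#' Pearson phenotypic correlation
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return The correlation coefficient.
#' @export
phenotypic_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Genetic correlation of line values between two environments
#'
#' r_g = r / (H1 H2): the Pearson correlation of line means across the two
#' environments divided by the square roots of the per-environment
#' genotype-mean-basis heritabilities. Values beyond +/-1 (possible with
#' noisy H) are reported raw alongside a clamped value.
#'
#' @param plots A `plot_phenotypes` data frame.
#' @param trait Trait name.
#' @param env1,env2 Environment names.
#' @return List of class `correlation_estimate` with `r`, `rg`, `rg_clamped`,
#'   `H1`, `H2`, `clamped` flag.
#' @export
genetic_correlation_env_pair <- function(plots, trait, env1, env2) {
  df <- check_plots(plots, trait)
  vc1 <- anova_single_env(plots, trait, env1)
  vc2 <- anova_single_env(plots, trait, env2)
  H1 <- heritability(vc1$components["sg2"], vc1$components["se2"], vc1$n)$H
  H2 <- heritability(vc2$components["sg2"], vc2$components["se2"], vc2$n)$H
  if (H1 == 0 || H2 == 0) stop("undefined genetic correlation: H is zero")
  s1 <- df[df$environment == env1, ]
  s2 <- df[df$environment == env2, ]
  m1 <- tapply(s1$value, s1$line, mean)
  m2 <- tapply(s2$value, s2$line, mean)
  common <- intersect(names(m1), names(m2))
  r <- phenotypic_correlation(m1[common], m2[common])
  rg <- r / (H1 * H2)
  structure(list(r = r, rg = rg, rg_clamped = max(-1, min(1, rg)),
                 clamped = abs(rg) > 1, H1 = H1, H2 = H2,
                 context = c(env1, env2)),
            class = "correlation_estimate")
}

#' Genetic correlation between two traits within one environment
#'
#' Genotypic covariance from the mean cross-products of the balanced two-way
#' (genotype, block) MANOVA: Cov_G = (MCP_G - MCP_e)/n, and
#' r_g = Cov_G / sqrt(sg2_X sg2_Y). An approximate first-order delta-method
#' standard error is returned, treating the genotypic (co)variance estimates
#' as independent with Var(MS) ~ 2 MS^2/df analogues.
#'
#' @param plots A `plot_phenotypes` data frame holding both traits on
#'   identical plots.
#' @param traitX,traitY Trait names.
#' @param environment Environment to analyse.
#' @return A `correlation_estimate` with `rg`, `se`, `cov_g` and the two
#'   genotypic variances.
#' @export
genetic_correlation_traits <- function(plots, traitX, traitY, environment) {
  dx <- check_plots(plots, traitX)
  dy <- check_plots(plots, traitY)
  dx <- dx[dx$environment == environment, ]
  dy <- dy[dy$environment == environment, ]
  key <- function(d) paste(d$line, d$block)
  dy <- dy[match(key(dx), key(dy)), ]
  if (anyNA(dy$value)) stop("traits not measured on identical plots")
  L <- length(unique(dx$line))
  n <- length(unique(dx$block))
  if (!all(table(dx$line, dx$block) == 1)) stop("unbalanced data")
  x <- dx$value; y <- dy$value
  gx <- tapply(x, dx$line, mean); gy <- tapply(y, dx$line, mean)
  bx <- tapply(x, dx$block, mean); by <- tapply(y, dx$block, mean)
  mx <- mean(x); my <- mean(y)
  df_g <- L - 1; df_e <- (L - 1) * (n - 1)
  mcp_g <- n * sum((gx - mx) * (gy - my)) / df_g
  rx <- x - gx[as.character(dx$line)] - bx[as.character(dx$block)] + mx
  ry <- y - gy[as.character(dx$line)] - by[as.character(dx$block)] + my
  mcp_e <- sum(rx * ry) / df_e
  cov_g <- (mcp_g - mcp_e) / n
  vcx <- anova_single_env(plots, traitX, environment)
  vcy <- anova_single_env(plots, traitY, environment)
  vgx <- vcx$components["sg2"]; vgy <- vcy$components["sg2"]
  if (vgx <= 0 || vgy <= 0) {
    stop("undefined genetic correlation: non-positive genotypic variance")
  }
  rg <- cov_g / sqrt(vgx * vgy)
  msx <- vcx$components["se2"]; msy <- vcy$components["se2"]
  var_cov <- ((mcp_g^2 + (n * vgx + msx) * (n * vgy + msy)) / df_g +
                (mcp_e^2 + msx * msy) / df_e) / n^2
  var_vgx <- 2 * ((n * vgx + msx)^2 / df_g + msx^2 / df_e) / n^2
  var_vgy <- 2 * ((n * vgy + msy)^2 / df_g + msy^2 / df_e) / n^2
  se <- abs(rg) * sqrt(
    var_cov / cov_g^2 + var_vgx / (4 * vgx^2) + var_vgy / (4 * vgy^2)
  )
  structure(list(rg = unname(rg), rg_clamped = unname(max(-1, min(1, rg))),
                 clamped = abs(rg) > 1, se = unname(se),
                 cov_g = cov_g, vg_x = unname(vgx), vg_y = unname(vgy),
                 context = c(traitX, traitY, environment)),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat("correlation_estimate:", paste(x$context, collapse = " / "), "\n")
  if (!is.null(x$r)) cat(sprintf("  r (phenotypic) = %.4f\n", x$r))
  cat(sprintf("  r_g = %.4f%s\n", x$rg,
              if (isTRUE(x$clamped)) sprintf(" (clamped: %.4f)", x$rg_clamped) else ""))
  if (!is.null(x$se)) cat(sprintf("  approx SE = %.4f\n", x$se))
  invisible(x)
}
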