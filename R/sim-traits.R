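#' Trait architecture for the phenotype simulator
#'
#' Parameterizes two primary traits (grain yield, t/ha, and grain protein
#' content, % dry matter) plus their genetic correlation. Protein yield is
#' never parameterized: it is derived per plot as yield x protein/100.
#'
#' Variance targets are on the scale the multi-environment ANOVA estimates:
#' `sg2` is the genotypic variance of line values, `sge2` the
#' genotype-by-environment interaction variance (compound symmetry), `se2`
#' the plot error variance.
#'
#' @param traits Named list; each element a list with fields `mean`,
#'   `env_effects` (length-e deviations from the mean), `sg2`, `sge2`, `se2`,
#'   `block_sd` (SD of random block-within-environment effects).
#' @param n_qtl Number of causal loci shared by the two traits.
#' @param rg_traits Target genetic correlation between the two traits,
#'   induced through correlated additive effects at the shared loci.
#' @return Object of class `trait_architecture`.
#' @export
trait_architecture <- function(traits, n_qtl = 60, rg_traits = 0.15) {
  stopifnot(length(traits) == 2, !is.null(names(traits)))
  stopifnot(abs(rg_traits) <= 1, n_qtl >= 1)
  for (tr in traits) {
    stopifnot(all(c("mean", "env_effects", "sg2", "sge2", "se2") %in% names(tr)))
    stopifnot(tr$sg2 >= 0, tr$sge2 >= 0, tr$se2 >= 0)
  }
  structure(list(traits = traits, n_qtl = n_qtl, rg_traits = rg_traits),
            class = "trait_architecture")
}

#' Default architecture emulating the study's pea panel
#'
#' Genotypic and GEI variances follow the published multi-environment
#' estimates for grain yield (0.575, 1.435) and protein content
#' (0.724, 0.302). Error variances are derived by inverting the
#' genotype-mean-basis heritability H2 = sg2/(sg2 + sge2/e + se2/(e n)) at
#' the published H2 values (0.52 for yield, 0.82 for protein) with e = 3
#' environments and n = 3 replicates, giving se2 of about 0.472 and 0.524.
#' Environment means follow the printed trial means; the trait genetic
#' correlation target (0.15) sits mid-range of the published per-environment
#' estimates (0.12-0.18).
#'
#' @param n_qtl Number of shared causal loci.
#' @param rg_traits Genetic correlation target between yield and protein.
#' @return A [trait_architecture()].
#' @export
study_architecture <- function(n_qtl = 60, rg_traits = 0.15) {
  se2_from_h2 <- function(sg2, sge2, h2, e = 3, n = 3) {
    e * n * (sg2 / h2 - sg2 - sge2 / e)
  }
  yld <- list(
    mean = 4.60,
    env_effects = c(Lodi1314 = 1.71, Lodi1415 = -0.01, Perugia1314 = -1.70),
    sg2 = 0.575, sge2 = 1.435,
    se2 = se2_from_h2(0.575, 1.435, 0.52),
    block_sd = 0.15
  )
  prot <- list(
    mean = 24.27,
    env_effects = c(Lodi1314 = 1.05, Lodi1415 = -1.05, Perugia1314 = 0.00),
    sg2 = 0.724, sge2 = 0.302,
    se2 = se2_from_h2(0.724, 0.302, 0.82),
    block_sd = 0.10
  )
  trait_architecture(list(yield = yld, protein = prot),
                     n_qtl = n_qtl, rg_traits = rg_traits)
}

#' GEI variance implied by a target cross-environment genetic correlation
#'
#' Under the compound-symmetry GEI used by the simulator, the genetic
#' correlation of line values between any two environments is
#' sg2 / (sg2 + sge2); this inverts that relation.
#'
#' @param sg2 Genotypic variance.
#' @param rg Target genetic correlation in (0, 1\].
#' @return The `sge2` achieving the target.
#' @export
sge2_for_rg <- function(sg2, rg) {
  stopifnot(rg > 0, rg <= 1, sg2 > 0)
  sg2 * (1 - rg) / rg
}

# Scale a vector to an exact sample variance (n-1 denominator), mean zero.
scale_to_var <- function(x, target) {
  x <- x - mean(x)
  v <- stats::var(x)
  if (target == 0) return(x * 0)
  if (v < 1e-300) stop("cannot rescale a constant vector to positive variance")
  x * sqrt(target / v)
}

#' Assign genetic values per line and environment
#'
#' Causal loci are sampled among polymorphic markers and shared by the two
#' traits; additive effects are drawn from a bivariate normal with the target
#' between-trait correlation. Per trait, line main values are rescaled so the
#' realized (n-1 denominator) variance equals `sg2` exactly; GEI deviations
#' are drawn iid normal per line x environment (the unrestricted
#' compound-symmetry structure a REML/EMS analysis estimates) and rescaled so
#' that their double-centered interaction mean square equals `sge2` exactly.
#'
#' @param G A complete (no missing) [geno_matrix()].
#' @param arch A [trait_architecture()].
#' @param environments Character vector of environment names.
#' @param seed Optional integer seed.
#' @return Object of class `trait_values`: per trait a lines x environments
#'   matrix of centered genetic values (main + GEI), plus the line main
#'   values and the causal-locus table.
#' @export
assign_trait_values <- function(G, arch, environments = NULL, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"), inherits(arch, "trait_architecture"))
  if (anyNA(G$geno)) stop("genotype matrix must be complete (pre-missingness)")
  if (is.null(environments)) {
    environments <- names(arch$traits[[1]]$env_effects)
    if (is.null(environments)) {
      environments <- paste0("env", seq_along(arch$traits[[1]]$env_effects))
    }
  }
  n_env <- length(environments)
  poly <- which(apply(G$geno, 2, function(x) length(unique(x)) > 1))
  if (arch$n_qtl > length(poly)) {
    stop("more causal loci requested than polymorphic markers available")
  }
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample(poly, arch$n_qtl))
  # The correlation target is on the per-environment genotypic scale (the
  # scale a within-environment MANOVA estimates). With GEI drawn
  # independently per trait, each trait's per-environment genotypic variance
  # is sg2 + sge2 while the cross-trait covariance comes from the main
  # effects alone, attenuating the realized correlation by
  # sqrt(sg2/(sg2+sge2)) per trait; the effect-level correlation is scaled
  # up to compensate.
  att <- vapply(arch$traits, function(tr) {
    if (tr$sg2 + tr$sge2 == 0) 1 else sqrt(tr$sg2 / (tr$sg2 + tr$sge2))
  }, numeric(1))
  rho <- arch$rg_traits / prod(att)
  if (abs(rho) > 1) {
    warning("trait correlation target unattainable with this GEI level; ",
            "clamping the effect correlation to ", sign(rho))
    rho <- sign(rho)
  }
  z <- matrix(stats::rnorm(2 * arch$n_qtl), ncol = 2)
  eff <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  X <- G$geno[, qtl, drop = FALSE]
  n_lines <- nrow(X)
  values <- list()
  for (t in seq_along(arch$traits)) {
    tr <- arch$traits[[t]]
    g_main <- scale_to_var(as.numeric(X %*% eff[, t]), tr$sg2)
    if (tr$sge2 > 0 && n_env > 1) {
      # unrestricted (iid) GEI, as a compound-symmetry REML/ANOVA expects;
      # scaled so the double-centered interaction mean square hits sge2
      # exactly (the quantity the balanced interaction MS estimates)
      D <- matrix(stats::rnorm(n_lines * n_env), n_lines, n_env)
      dc <- sweep(D - rowMeans(D), 2, colMeans(D) - mean(D))
      ssq <- sum(dc^2) / ((n_lines - 1) * (n_env - 1))
      D <- D * sqrt(tr$sge2 / ssq)
    } else {
      D <- matrix(0, n_lines, n_env)
    }
    gv <- matrix(g_main, n_lines, n_env) + D
    dimnames(gv) <- list(G$lines$line, environments)
    values[[names(arch$traits)[t]]] <- list(gv = gv, main = g_main)
  }
  structure(
    list(values = values, environments = environments,
         qtl = data.frame(marker = G$map$marker[qtl],
                          eff_1 = eff[, 1], eff_2 = eff[, 2]),
         lines = G$lines),
    class = "trait_values"
  )
}

#' Simulate a multi-environment randomized complete block trial
#'
#' Plot values follow y = m + E_j + B_r(E_j) + g_i + d_ij + e_ijr with
#' genotypic main values `g_i` and GEI deviations `d_ij` from
#' [assign_trait_values()], fixed environment effects, random block-within-
#' environment effects, and iid plot error with variance `se2`. Protein yield
#' per plot is computed exactly as yield_plot x protein_plot / 100, never
#' simulated independently.
#'
#' @param tv A `trait_values` object.
#' @param arch The [trait_architecture()] used to generate it.
#' @param n_blocks Replicates per environment (default 3).
#' @param seed Optional integer seed.
#' @param derive_protein_yield Add the derived `protein_yield` trait rows.
#' @return Long-format data frame with columns `line`, `population`,
#'   `environment`, `block`, `trait`, `value` (class `plot_phenotypes`).
#' @export
simulate_trial <- function(tv, arch, n_blocks = 3, seed = NULL,
                           derive_protein_yield = TRUE) {
  stopifnot(inherits(tv, "trait_values"), n_blocks >= 2)
  if (!is.null(seed)) set.seed(seed)
  envs <- tv$environments
  lines <- tv$lines
  n_lines <- nrow(lines)
  base <- expand.grid(
    line_idx = seq_len(n_lines), environment = envs,
    block = seq_len(n_blocks),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  plot_mats <- list()
  for (tn in names(tv$values)) {
    tr <- arch$traits[[tn]]
    gv <- tv$values[[tn]]$gv
    blk <- matrix(stats::rnorm(length(envs) * n_blocks, 0,
                               if (is.null(tr$block_sd)) 0 else tr$block_sd),
                  length(envs), n_blocks,
                  dimnames = list(envs, as.character(seq_len(n_blocks))))
    ee <- tr$env_effects
    if (is.null(names(ee))) names(ee) <- envs
    y <- tr$mean + ee[base$environment] +
      blk[cbind(base$environment, as.character(base$block))] +
      gv[cbind(base$line_idx, match(base$environment, envs))] +
      stats::rnorm(nrow(base), 0, sqrt(tr$se2))
    plot_mats[[tn]] <- as.numeric(y)
  }
  out <- do.call(rbind, lapply(names(plot_mats), function(tn) {
    data.frame(
      line = lines$line[base$line_idx],
      population = lines$population[base$line_idx],
      environment = base$environment,
      block = base$block,
      trait = tn,
      value = plot_mats[[tn]],
      stringsAsFactors = FALSE
    )
  }))
  if (derive_protein_yield &&
      all(c("yield", "protein") %in% names(plot_mats))) {
    py <- data.frame(
      line = lines$line[base$line_idx],
      population = lines$population[base$line_idx],
      environment = base$environment,
      block = base$block,
      trait = "protein_yield",
      value = plot_mats[["yield"]] * plot_mats[["protein"]] / 100,
      stringsAsFactors = FALSE
    )
    out <- rbind(out, py)
  }
  rownames(out) <- NULL
  class(out) <- c("plot_phenotypes", "data.frame")
  out
}

#' One-call simulation of the full study design
#'
#' Convenience wrapper: connected panel genotypes, genetic values, trial
#' phenotypes, and (optionally) missingness overlay.
#'
#' @param map Genetic map.
#' @param sizes Population sizes.
#' @param arch Trait architecture.
#' @param n_blocks Replicates per environment.
#' @param mpm_profile,mps_profile Missingness rates for the genotype overlay
#'   (applied to a copy; the complete matrix is also returned).
#' @param seed Master seed.
#' @return List with `geno` (complete), `geno_missing`, `values`, `plots`,
#'   `arch`.
#' @export
simulate_study <- function(map = genome_map(), sizes = c(102, 100, 104),
                           arch = study_architecture(), n_blocks = 3,
                           mpm_profile = 0, mps_profile = 0, seed = 1) {
  G <- simulate_study_panel(map, sizes = sizes, seed = sub_seed(seed, 10))
  tv <- assign_trait_values(G, arch, seed = sub_seed(seed, 20))
  plots <- simulate_trial(tv, arch, n_blocks = n_blocks,
                          seed = sub_seed(seed, 30))
  Gm <- if (any(mpm_profile > 0) || any(mps_profile > 0)) {
    add_missingness(G, mpm_profile, mps_profile, seed = sub_seed(seed, 40))
  } else {
    G
  }
  list(geno = G, geno_missing = Gm, values = tv, plots = plots, arch = arch)
}
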