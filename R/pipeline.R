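#' @title End-to-end pipeline
#' @description One-call orchestration of the full analysis: simulate the
#'   connected-panel design (or read supplied files), filter and impute
#'   markers, estimate variance components, heritabilities and BLUPs,
#'   cross-validate genomic predictions in both scenarios, run the GWAS, and
#'   evaluate GS-vs-PS gain scenarios. Every stage seed derives from the
#'   single master seed, so a rerun with the same config is bit-identical.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed.
#' @param map Genetic map for simulation.
#' @param sizes RIL population sizes.
#' @param arch Trait architecture.
#' @param n_blocks Replicates per environment.
#' @param mpm_sim,mps_sim Simulated missingness rates (marker / sample).
#' @param mpm,mps,maf_min Filtering thresholds.
#' @param impute_method `"knn"` or `"mode"`.
#' @param model GS model name (see [fit_gs()]).
#' @param cv_k,cv_reps Cross-validation folds and repetitions.
#' @param traits Traits to analyse.
#' @param gwas_traits Traits to scan.
#' @param n_pcs Principal components for the GWAS.
#' @param gain_p_P,gain_c_P,gain_c_G Gain-scenario settings.
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("rilgs_run_"), seed = 1,
                            map = genome_map(markers_per_chrom = 120),
                            sizes = c(102, 100, 104),
                            arch = study_architecture(),
                            n_blocks = 3,
                            mpm_sim = 0.08, mps_sim = 0.05,
                            mpm = 0.2, mps = 0.25, maf_min = 0.05,
                            impute_method = "knn",
                            model = "rrblup", cv_k = 10, cv_reps = 2,
                            traits = c("yield", "protein", "protein_yield"),
                            gwas_traits = c("yield", "protein"),
                            n_pcs = 10,
                            gain_p_P = 0.10, gain_c_P = 220, gain_c_G = 60) {
  if (!model %in% c("rrblup", "bayesA", "bayesC", "bayesLasso")) {
    stop("unknown model '", model, "'")
  }
  stopifnot(cv_k >= 2, cv_reps >= 1, n_blocks >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Stages run in order (simulate, filter, varcomp, blup, cv, gwas, gain);
#' artifacts are written under `config$out_dir` (components.tsv, cv.tsv,
#' gwas.tsv, scenario.json, manifest.json) and returned invisibly as a
#' report bundle.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return List (class `report_bundle`) with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  say("stage simulate: %d lines, %d markers pre-filter",
      sum(config$sizes), nrow(config$map))
  sim <- simulate_study(config$map, config$sizes, config$arch,
                        n_blocks = config$n_blocks,
                        mpm_profile = config$mpm_sim,
                        mps_profile = config$mps_sim, seed = seed)
  vcf_path <- file.path(config$out_dir, "genotypes.vcf")
  write_vcf(sim$geno_missing, vcf_path)
  utils::write.csv(sim$plots, file.path(config$out_dir, "phenotypes.csv"),
                   row.names = FALSE)

  say("stage markers: filtering mpm = %g, mps = %g, maf >= %g",
      config$mpm, config$mps, config$maf_min)
  G <- read_vcf(vcf_path)
  fm <- filter_markers(G, config$mpm, config$maf_min)
  fs <- filter_samples(fm$geno, config$mps)
  Gc <- impute_genotypes(fs$geno, config$impute_method)
  say("  %d markers, %d lines retained", ncol(Gc$geno), nrow(Gc$geno))

  say("stage varcomp")
  components <- list()
  blups <- list()
  for (tr in config$traits) {
    vc <- anova_multi_env(sim$plots, tr)
    vcp <- anova_multi_env(sim$plots, tr, include_population = TRUE)
    components[[tr]] <- list(pooled = vc, with_population = vcp)
    blups[[tr]] <- env_blups(sim$plots, tr)
  }
  comp_tab <- do.call(rbind, lapply(config$traits, function(tr) {
    v <- components[[tr]]$pooled$components
    w <- components[[tr]]$with_population$components
    data.frame(trait = tr, t(v), t(w[setdiff(names(w), names(v))]))
  }))
  utils::write.table(comp_tab, file.path(config$out_dir, "components.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage cv: model %s, %d folds x %d reps", config$model, config$cv_k,
      config$cv_reps)
  cv <- list()
  for (tr in config$traits) {
    bl <- blups[[tr]][rownames(Gc$geno), , drop = FALSE]
    cv[[tr]] <- list(
      intra = intra_population_cv(Gc, bl, config$model, k = config$cv_k,
                                  reps = config$cv_reps,
                                  seed = sub_seed(seed, 50)),
      inter = inter_population_cv(Gc, bl, config$model,
                                  seed = sub_seed(seed, 60))
    )
  }
  cv_tab <- do.call(rbind, lapply(config$traits, function(tr) {
    rbind(
      cbind(trait = tr, cv[[tr]]$intra$cells[
        , c("scenario", "train_envs", "val_env", "population", "r_ab")]),
      cbind(trait = tr, stats::setNames(
        cv[[tr]]$inter$cells[, c("scenario", "train_envs", "val_env",
                                 "train_population", "r_ab")],
        c("scenario", "train_envs", "val_env", "population", "r_ab")))
    )
  }))
  utils::write.table(cv_tab, file.path(config$out_dir, "cv.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage gwas: %d PCs", config$n_pcs)
  K <- kinship(Gc)
  pcs <- pc_covariates(Gc, config$n_pcs)
  gwas <- list()
  for (tr in config$gwas_traits) {
    y <- rowMeans(blups[[tr]][rownames(Gc$geno), , drop = FALSE])
    gwas[[tr]] <- gwas_scan(Gc, y, K, pcs)
  }
  gwas_tab <- do.call(rbind, lapply(names(gwas), function(tr) {
    cbind(trait = tr, gwas[[tr]]$table)
  }))
  utils::write.table(gwas_tab, file.path(config$out_dir, "gwas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage gain")
  tr_gain <- if ("protein_yield" %in% config$traits) "protein_yield"
             else config$traits[1]
  vcg <- components[[tr_gain]]$pooled$components
  H2_sel <- heritability(vcg["sg2"], vcg["se2"], config$n_blocks,
                         sge2 = vcg["sge2"], e = 2)$H2
  scen <- list()
  for (sc in c("intra", "inter")) {
    r_ab <- cv[[tr_gain]][[sc]]$summary$grand
    for (tP in c(1, 2)) {
      scen[[sprintf("%s_tP%d", sc, tP)]] <- gain_scenario(
        r_ab = r_ab, H2 = H2_sel, t_P = tP,
        c_P = config$gain_c_P, c_G = config$gain_c_G, p_P = config$gain_p_P
      )
    }
  }
  jsonlite::write_json(
    lapply(scen, function(s) unclass(s)[!vapply(unclass(s), is.null, TRUE)]),
    file.path(config$out_dir, "scenario.json"),
    auto_unbox = TRUE, digits = NA
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("rilgs")),
    seed = seed,
    stages = c("simulate", "markers", "varcomp", "cv", "gwas", "gain"),
    n_lines = nrow(Gc$geno), n_markers = ncol(Gc$geno),
    traits = config$traits, model = config$model
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(structure(list(
    config = config, sim = sim, geno = Gc,
    filter_reports = list(markers = fm$report, samples = fs$report),
    components = components, blups = blups, cv = cv, gwas = gwas,
    gain = scen
  ), class = "report_bundle"))
}

#' Report tables in the published layouts
#'
#' Formats a report bundle into the layouts of the study's summary tables:
#' variance components per trait, model predictive abilities, the intra- and
#' inter-population predictive-ability table, and the gain-scenario table
#' (whose t_P = 2 column is exactly twice the t_P = 1 column).
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return Named list of data frames (`components`, `cv`, `gain`).
#' @export
paper_tables <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  traits <- names(bundle$components)
  components <- do.call(rbind, lapply(traits, function(tr) {
    v <- bundle$components[[tr]]$pooled$components
    w <- bundle$components[[tr]]$with_population$components
    data.frame(
      trait = tr, sg2 = v[["sg2"]], sge2 = v[["sge2"]],
      ratio = v[["ratio_g_ge"]],
      sr2 = w[["sr2"]], sgr2 = w[["sgr2"]], sre2 = w[["sre2"]],
      sgre2 = w[["sgre2"]]
    )
  }))
  cv <- do.call(rbind, lapply(traits, function(tr) {
    intra <- bundle$cv[[tr]]$intra$summary
    inter <- bundle$cv[[tr]]$inter$summary
    env_means <- stats::setNames(intra$by_env$r_ab, intra$by_env$val_env)
    pop_means <- stats::setNames(inter$by_population$r_ab,
                                 inter$by_population$train_population)
    out <- data.frame(trait = tr, t(env_means), intra_mean = intra$grand,
                      t(pop_means), inter_mean = inter$grand,
                      check.names = FALSE)
    out
  }))
  gain <- do.call(rbind, lapply(grep("tP1$", names(bundle$gain), value = TRUE),
    function(nm) {
      s1 <- bundle$gain[[nm]]
      s2 <- bundle$gain[[sub("tP1", "tP2", nm)]]
      data.frame(
        scenario = sub("_tP1", "", nm), r_Ac = s1$r_Ac, H = s1$H,
        ratio_tP1 = s1$efficiency_ratio, ratio_tP2 = s2$efficiency_ratio
      )
    }))
  list(components = components, cv = cv, gain = gain)
}
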