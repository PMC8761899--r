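#!/usr/bin/env Rscript
# Variance components, heritabilities and genetic correlations from the
# plot phenotypes: pooled multi-environment ANOVA (EMS) and the nested
# RIL-population model (REML), per-environment heritability and BLUPs,
# cross-environment genetic correlations and the yield-protein genetic
# correlation per environment.

library(rilgs)

plots <- read.csv("results/phenotypes.csv")
class(plots) <- c("plot_phenotypes", "data.frame")
traits <- c("yield", "protein", "protein_yield")
envs <- sort(unique(plots$environment))

comp <- do.call(rbind, lapply(traits, function(tr) {
  pooled <- anova_multi_env(plots, tr)
  nested <- anova_multi_env(plots, tr, include_population = TRUE)
  h2 <- heritability(pooled$components[["sg2"]], pooled$components[["se2"]],
                     n = 3, sge2 = pooled$components[["sge2"]], e = 3)$H2
  data.frame(trait = tr, t(pooled$components),
             t(nested$components[c("sr2", "sgr2", "sre2", "sgre2")]),
             H2 = h2)
}))
write.table(comp, "results/variance_components.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("variance components (pooled + nested):")
print(comp, digits = 3)

# genetic correlations across environment pairs and between traits
pairs <- combn(envs, 2)
rg_env <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
  do.call(rbind, lapply(traits, function(tr) {
    ge <- genetic_correlation_env_pair(plots, tr, pairs[1, i], pairs[2, i])
    data.frame(trait = tr, env1 = pairs[1, i], env2 = pairs[2, i],
               r = ge$r, rg = ge$rg_clamped)
  }))
}))
rg_tr <- do.call(rbind, lapply(envs, function(e) {
  gt <- genetic_correlation_traits(plots, "yield", "protein", e)
  data.frame(environment = e, rg = gt$rg, se = gt$se)
}))
write.table(rg_env, "results/genetic_correlations_env.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(rg_tr, "results/genetic_correlations_traits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("yield-protein genetic correlation by environment:")
print(rg_tr, digits = 2)

# per-environment BLUPs feed the genomic prediction and GWAS stages
for (tr in traits) {
  bl <- env_blups(plots, tr)
  write.csv(data.frame(line = rownames(bl), bl, check.names = FALSE),
            sprintf("results/blups_%s.csv", tr), row.names = FALSE)
}
message("wrote per-environment BLUPs for ", paste(traits, collapse = ", "))
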