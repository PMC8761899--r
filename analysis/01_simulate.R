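#!/usr/bin/env Rscript
# Simulate the study design: three connected RIL populations (102/100/104
# F6-derived lines from paired crosses among three parents, the third parent
# more divergent), genotyped at GBS-like density and phenotyped for grain
# yield and protein content in 3 environments x 3 blocks. Writes the
# genotypes (VCF, with structured missingness) and plot phenotypes (CSV).

library(rilgs)

seed <- 2026
set.seed(seed)
dir.create("results", showWarnings = FALSE)

arch <- study_architecture()
sim <- simulate_study(
  map = genome_map(n_chrom = 7, length_cM = 100, markers_per_chrom = 120),
  sizes = c(102, 100, 104),
  arch = arch,
  n_blocks = 3,
  mpm_profile = stats::rbeta(7 * 120, 1.2, 10),  # skewed per-marker rates
  mps_profile = 0.03,
  seed = seed
)

write_vcf(sim$geno_missing, "results/genotypes.vcf")
write.csv(sim$plots, "results/phenotypes.csv", row.names = FALSE)

message(sprintf("panel: %d lines x %d markers, %.1f%% missing calls",
                nrow(sim$geno_missing$geno), ncol(sim$geno_missing$geno),
                100 * mean(is.na(sim$geno_missing$geno))))
message(sprintf("plots: %d records across %d traits",
                nrow(sim$plots), length(unique(sim$plots$trait))))
message("wrote results/genotypes.vcf and results/phenotypes.csv")
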