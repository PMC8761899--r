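#!/usr/bin/env Rscript
# Marker quality control: read the VCF, drop markers with > 20% missing
# calls, monomorphic markers and MAF < 5%, then drop samples with > 25%
# missing calls, and impute the remainder by k-nearest-neighbour vote.

library(rilgs)

G <- read_vcf("results/genotypes.vcf")
message(sprintf("read %d lines x %d markers (%d multiallelic skipped)",
                nrow(G$geno), ncol(G$geno),
                attr(G, "n_multiallelic_skipped")))

fm <- filter_markers(G, mpm = 0.2, maf_min = 0.05)
print(fm$report)
fs <- filter_samples(fm$geno, mps = 0.25)
print(fs$report)

Gc <- impute_genotypes(fs$geno, method = "knn", k = 5)
stopifnot(!anyNA(Gc$geno))

out <- data.frame(line = Gc$lines$line, population = Gc$lines$population,
                  Gc$geno, check.names = FALSE)
write.table(out, "results/genotypes_filtered.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("final matrix: %d lines x %d markers -> %s",
                nrow(Gc$geno), ncol(Gc$geno),
                "results/genotypes_filtered.tsv"))
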