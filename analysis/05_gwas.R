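#!/usr/bin/env Rscript
# Association scans for grain yield and protein content on the pooled
# stratified panel: Astle-Balding kinship + 10 principal components in a
# GLS (P3D) model, Bonferroni and FDR thresholds, LD clustering of any
# significant markers, and plot-ready Manhattan/QQ tables.

library(rilgs)

geno_tab <- read.delim("results/genotypes_filtered.tsv", check.names = FALSE)
geno <- as.matrix(geno_tab[, -(1:2)])
storage.mode(geno) <- "integer"
rownames(geno) <- geno_tab$line
chrom <- sub("^m_(chr[0-9]+)_.*", "\\1", colnames(geno))
Gc <- geno_matrix(geno,
                  data.frame(marker = colnames(geno), chrom = chrom,
                             pos = as.integer(ave(seq_along(chrom), chrom,
                                                  FUN = seq_along))),
                  data.frame(line = geno_tab$line,
                             population = geno_tab$population))

K <- kinship(Gc)
pcs <- pc_covariates(Gc, 10)

for (tr in c("yield", "protein")) {
  b <- read.csv(sprintf("results/blups_%s.csv", tr), check.names = FALSE)
  y <- rowMeans(as.matrix(b[, -1]))
  names(y) <- b$line
  res <- gwas_scan(Gc, y[rownames(Gc$geno)], K, pcs)
  print(res)
  mt <- manhattan_table(res)
  write.table(cbind(trait = tr, mt$manhattan),
              sprintf("results/gwas_%s.tsv", tr), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(mt$qq, sprintf("results/gwas_qq_%s.tsv", tr), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(res$significant$fdr) >= 2) {
    message("FDR-significant markers cluster into ",
            max(res$ld$locus), " locus/loci")
  } else if (is.na(res$fdr_threshold)) {
    top <- head(res$table[order(res$table$p), "marker"], 5)
    message("FDR threshold undefined for ", tr,
            "; top markers by score: ", paste(top, collapse = ", "))
  }
}
message("wrote results/gwas_*.tsv")
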