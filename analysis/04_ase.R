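#!/usr/bin/env Rscript
# Stage 4 — tunicamycin-induced changes in allele-specific expression.
#
# Per cross: Fisher's exact test on pooled maternal/paternal counts in
# control vs TM (informative genes with pooled coverage > 50 and >= 2
# SNPs), BH correction (5% FDR call), direction of the maternal-proportion
# shift, and the intersection with genes upregulated by TM in the maternal
# reference strain.
#
# Requires: analysis/01_simulate.R, analysis/02_induction.R

suppressPackageStartupMessages(library(stressdiv))

samples <- read.delim("results/data/samples.tsv")
snps <- read_snp_records("results/data/snp_allele_counts.tsv", samples)
gac <- aggregate_gene_allele_counts(filter_snps(snps))
ind_b6 <- read.delim("results/induction_B6.tsv", comment.char = "#")
induced <- ind_b6$gene[ind_b6$induced]

summaries <- list()
for (cr in unique(gac$cross)) {
  res <- test_ase_change(gac, cr)
  write.table(res, sprintf("results/ase_change_%s.tsv", cr), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summaries[[cr]] <- summarize_ase(res, induced)
}
summary_tab <- do.call(rbind, summaries)
rownames(summary_tab) <- NULL
write.table(summary_tab, "results/ase_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("stress-induced ASE changes per cross:\n")
print(summary_tab, digits = 3)
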