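#!/usr/bin/env Rscript
# Stage 5 — regulatory differences shared across F1 crosses.
#
# Using the per-cross classifications from stage 3: flags genes with the
# same effect type (cis or trans) in two or more informative crosses,
# tests the magnitude of shared differences for a strain effect
# (chi-squared on pooled allele counts, FDR 5%), and contrasts the sharing
# proportion between control and TM conditions.
#
# Requires: analysis/01_simulate.R, analysis/03_cistrans.R

suppressPackageStartupMessages(library(stressdiv))

samples <- read.delim("results/data/samples.tsv")
snps <- read_snp_records("results/data/snp_allele_counts.tsv", samples)
gac <- aggregate_gene_allele_counts(filter_snps(snps))

files <- list.files("results", pattern = "^cistrans_.*\\.tsv$",
                    full.names = TRUE)
calls <- lapply(files, read.delim, comment.char = "#")
names(calls) <- sub("^cistrans_(.*)\\.tsv$", "\\1", basename(files))

for (type in c("cis", "trans")) {
  by_cond <- lapply(stats::setNames(c("control", "TM"), c("control", "TM")),
                    function(cond) find_shared(
                      lapply(calls, function(d)
                        d[d$condition == cond, , drop = FALSE]), type))
  write.table(rbind(by_cond$control, by_cond$TM),
              sprintf("results/shared_%s.tsv", type), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ct <- condition_sharing_contrast(by_cond$control, by_cond$TM)
  cat(sprintf(
    "%s: shared among >= 2 crosses: control %d/%d (%.0f%%), TM %d/%d (%.0f%%); contrast p = %.2g\n",
    type, ct$table["control", "shared"], sum(ct$table["control", ]),
    100 * ct$prop_shared["control"],
    ct$table["TM", "shared"], sum(ct$table["TM", ]),
    100 * ct$prop_shared["TM"], ct$p.value))
  for (cond in c("control", "TM")) {
    ses <- strain_effect_on_shared(by_cond[[cond]], gac, cond)
    write.table(ses, sprintf("results/shared_%s_strain_effect_%s.tsv",
                             type, cond),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("  %s %s: %d/%d shared genes show a strain effect on magnitude (chi2, FDR 5%%)\n",
                type, cond, sum(ses$strain_effect), nrow(ses)))
  }
}
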