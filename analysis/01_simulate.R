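#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the experimental design: 8 inbred strains (B6 maternal reference)
# x 2 conditions (control, tunicamycin) x 3 replicates of gene-level counts,
# plus per-SNP allele counts for 5 F1 crosses sharing B6 as maternal parent.
# The generative truth (per-gene induction, cis, trans and stress-only
# effects) is written alongside so later stages can be scored by recovery.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(stressdiv))
seed <- suppressWarnings(as.integer(commandArgs(trailingOnly = TRUE)[1]))
if (is.na(seed)) seed <- 1

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cm <- sprintf("seed=%d", seed)
write_counts(sim$parents, "results/data/parent_counts.tsv",
             "results/data/parent_samples.tsv", cm)
write.table(sim$samples, "results/data/samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_snp_records(sim$snps, "results/data/snp_allele_counts.tsv", cm)
write_truth(sim$truth$regulatory, "results/data/truth_regulatory.tsv", cm)
write.table(sim$truth$induction, "results/data/truth_induction.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- sim$truth$regulatory
cat(sprintf("simulated %d genes, %d parental samples, %d SNP records (seed %d)\n",
            cfg$n_genes, ncol(sim$parents$counts), nrow(sim$snps), seed))
cat("generative regulatory architectures (gene x cross x condition rows):\n")
print(table(tr$category))
cat(sprintf("genes induced in >= 1 strain: %d\n",
            length(unique(sim$truth$induction$gene[
              sim$truth$induction$log2fc > 0]))))
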