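#!/usr/bin/env Rscript
# Stage 2 — normalization, condition QC, and induction calling per strain.
#
# TMM-normalizes the parental counts, screens each strain for samples that
# do not cluster with their own condition (PCA + 2-means with a
# leave-one-out margin), calls tunicamycin-induced genes per strain
# (>= 1.5-fold, FDR 1%, NB exact test with common dispersion), partitions
# the induced union into unique/shared/common, tests for strain effects on
# the induction magnitude (ANOVA on log2 fold changes, FDR 1%), and builds
# the Spearman correlation network among the strongest strain-effect genes.
#
# Requires: analysis/01_simulate.R

suppressPackageStartupMessages(library(stressdiv))

parents <- read_counts("results/data/parent_counts.tsv",
                       "results/data/parent_samples.tsv")
parents <- tmm_normalize(parents)
strains <- unique(parents$samples$group)

removed <- unlist(lapply(strains, function(s) qc_condition_outliers(parents, s)))
cat(sprintf("condition QC removed %d sample(s)%s\n", length(removed),
            if (length(removed)) paste0(": ", paste(removed, collapse = ", "))
            else ""))
if (length(removed))
  parents <- tmm_normalize(drop_samples(parents, removed))

induction <- lapply(stats::setNames(strains, strains),
                    function(s) test_induction(parents, s))
for (s in strains)
  write.table(induction[[s]], sprintf("results/induction_%s.tsv", s),
              sep = "\t", quote = FALSE, row.names = FALSE)
cat("induced genes per strain:\n")
print(vapply(induction, function(d) sum(d$induced), integer(1)))

spectrum <- induced_gene_sets(induction)
write.table(spectrum, "results/induction_sharing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("induced in >= 1 strain: %d genes; sharing spectrum:\n",
            nrow(spectrum)))
print(table(spectrum$class))

fc <- fold_change_table(parents)
se <- strain_effect(fc)
write.table(se, "results/strain_effect.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("strain effect on induction magnitude: %d / %d genes (FDR 1%%)\n",
            sum(se$significant), nrow(se)))

ord <- order(se$q)
top <- head(se$gene[ord][se$significant[ord]], 40L)
net <- correlation_network(fc, top)
write.table(net, "results/correlation_network.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("correlation network over top %d strain-effect genes: %d edges (p < 0.05)\n",
            length(top), nrow(net)))
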