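#!/usr/bin/env Rscript
# Stage 3 — cis/trans classification per F1 cross and condition.
#
# Filters SNP allele records (coverage >= 4, quality flags), pools
# replicates, restricts to informative genes (>= 2 SNPs, pooled coverage
# > 20), and runs the two-step hierarchy per cross and condition at
# FDR 0.1%: exact binomial tests of parental divergence and F1 allelic
# imbalance, then Fisher's ratio comparison (the trans test) on step-1
# significant genes. Also labels each effect as condition-persistent or
# condition-specific.
#
# Requires: analysis/01_simulate.R

suppressPackageStartupMessages(library(stressdiv))

parents <- tmm_normalize(read_counts("results/data/parent_counts.tsv",
                                     "results/data/parent_samples.tsv"))
samples <- read.delim("results/data/samples.tsv")
snps <- read_snp_records("results/data/snp_allele_counts.tsv", samples)
gac <- aggregate_gene_allele_counts(filter_snps(snps))

crosses <- unique(gac$cross)
paternal_of <- setNames(sub("^x", "", crosses), crosses)
maternal <- "B6"

for (cr in crosses) {
  calls <- lapply(stats::setNames(c("control", "TM"), c("control", "TM")),
                  function(cond) run_cistrans(parents, gac, cr, maternal,
                                              paternal_of[[cr]], cond))
  write.table(rbind(calls$control, calls$TM),
              sprintf("results/cistrans_%s.tsv", cr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pat <- compare_conditions(calls$control, calls$TM)
  write.table(pat, sprintf("results/condition_patterns_%s.tsv", cr),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (cond in c("control", "TM")) {
    d <- calls[[cond]]
    n_cis <- sum(d$category == "cis"); n_trans <- sum(d$category == "trans")
    cat(sprintf(
      "%s %s: %d informative; cis %d, trans %d (%.0f%% cis); median |cis| %.2f, median |trans| %.2f\n",
      cr, cond, nrow(d), n_cis, n_trans,
      100 * n_cis / max(1, n_cis + n_trans),
      stats::median(d$cis_mag[d$category == "cis"]),
      stats::median(d$trans_mag[d$category == "trans"])))
  }
  cis_pat <- pat[pat$effect_type == "cis" & pat$status != "neither", ]
  cat(sprintf("  cis effects by condition: %s\n",
              paste(names(table(cis_pat$status)), table(cis_pat$status),
                    sep = "=", collapse = ", ")))
}
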