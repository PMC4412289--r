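#!/usr/bin/env Rscript
# Stage 6 — aggregate run report and recovery scoring against the truth.
#
# Collects the per-stage tables into a JSON summary and, because the study
# is synthetic, scores the classifications against the generative truth:
# category recovery of cis/trans/conserved genes and sensitivity of the
# induction calls.
#
# Requires: analysis/01_simulate.R .. 05_shared.R

suppressPackageStartupMessages(library(stressdiv))

truth <- read_truth("results/data/truth_regulatory.tsv")
tind <- read.delim("results/data/truth_induction.tsv")

files <- list.files("results", pattern = "^cistrans_.*\\.tsv$",
                    full.names = TRUE)
calls <- do.call(rbind, lapply(files, read.delim, comment.char = "#"))
m <- merge(calls, truth, by = c("gene", "cross", "condition"),
           suffixes = c("", ".true"))
rec <- sapply(c("cis", "trans", "conserved"), function(cc)
  mean(m$category[m$category.true == cc] == cc))
cat("category recovery (called = true) over informative gene x cross x condition:\n")
print(round(rec, 3))

ind_files <- list.files("results", pattern = "^induction_.*\\.tsv$",
                        full.names = TRUE)
ind_files <- ind_files[!grepl("sharing", ind_files)]
ind <- do.call(rbind, lapply(ind_files, read.delim, comment.char = "#"))
mi <- merge(ind, tind, by = c("gene", "strain"))
sens <- mean(mi$induced[mi$log2fc_total >= log2(3)])
fdr <- sum(mi$induced & mi$log2fc_total <= 0) / max(1, sum(mi$induced))
cat(sprintf("induction: sensitivity %.3f at true fold >= 3; empirical FDR %.4f\n",
            sens, fdr))

spectrum <- read.delim("results/induction_sharing.tsv", comment.char = "#")
se <- read.delim("results/strain_effect.tsv", comment.char = "#")
ase <- read.delim("results/ase_summary.tsv", comment.char = "#")

report <- list(
  package_version = as.character(packageVersion("stressdiv")),
  induction = list(
    n_induced_any = nrow(spectrum),
    sharing = as.list(table(spectrum$class)),
    n_strain_effect = sum(se$significant),
    sensitivity_fold3 = sens,
    empirical_fdr = fdr),
  cistrans = list(
    category_counts = as.list(table(m$category)),
    recovery = as.list(rec)),
  ase = ase)
jsonlite::write_json(report, "results/analysis_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/analysis_report.json\n")
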