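# Stress-induced changes in allele-specific expression (ASE) within an F1
# cross: Fisher's exact test on pooled maternal/paternal counts in control vs
# TM samples, allele-specific fold-change decomposition, and the per-cross
# summary of ASE changes intersected with induction calls.

#' Test TM-induced change in allele-specific expression for one cross
#'
#' For every gene informative for ASE (>= 2 SNPs, pooled coverage > 50 in both
#' conditions), Fisher's exact test on the 2x2 table of maternal/paternal
#' counts in control vs TM samples, BH-corrected across genes within the
#' cross. The maternal proportion is reported per condition.
#'
#' @param gac Aggregated allele counts (replicates pooled) for one cross,
#'   both conditions.
#' @param cross Cross label.
#' @param fdr Significance threshold on q (default 0.05; the correction is
#'   always applied, the cutoff is configurable and recorded downstream).
#' @return Data frame with gene, per-condition proportions, p, q, significant
#'   and the direction of the maternal shift.
#' @export
test_ase_change <- function(gac, cross, fdr = 0.05) {
  sub <- gac[gac$cross == cross, , drop = FALSE]
  genes <- informative_genes(sub, "ase")
  ctrl <- sub[sub$condition == "control", , drop = FALSE]
  tm <- sub[sub$condition == "TM", , drop = FALSE]
  ic <- match(genes, ctrl$gene); it <- match(genes, tm$gene)
  n <- length(genes)
  p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- rbind(c(ctrl$maternal_total[ic[i]], ctrl$paternal_total[ic[i]]),
                 c(tm$maternal_total[it[i]], tm$paternal_total[it[i]]))
    p[i] <- fisher_exact_two_sided(tab)
  }
  prop_c <- ctrl$maternal_total[ic] /
    (ctrl$maternal_total[ic] + ctrl$paternal_total[ic])
  prop_t <- tm$maternal_total[it] /
    (tm$maternal_total[it] + tm$paternal_total[it])
  q <- bh_fdr(p)
  sig <- q <= fdr
  data.frame(
    gene = genes, cross = cross,
    prop_maternal_control = prop_c, prop_maternal_TM = prop_t,
    p = p, q = q, significant = sig,
    maternal_shift = ifelse(!sig, "none",
                            ifelse(prop_t > prop_c, "up", "down")),
    stringsAsFactors = FALSE)
}

#' Decompose a total fold change into allele-specific fold changes
#'
#' Given the maternal proportion in each condition and the total linear fold
#' change of the gene, the allele-specific fold changes are
#' `total_fc * prop_TM / prop_control` (maternal) and
#' `total_fc * (1 - prop_TM) / (1 - prop_control)` (paternal). The control
#' proportions weight the allele folds back to the total:
#' `prop_control * maternal_fold + (1 - prop_control) * paternal_fold =
#' total_fc`.
#'
#' @param prop_control,prop_tm Maternal proportions per condition.
#' @param total_fc Total linear fold change (TM / control).
#' @return Data frame with maternal_fold and paternal_fold (NA where an
#'   allele is absent under control, flagged by `undefined`).
#' @export
allelic_fold_decomposition <- function(prop_control, prop_tm, total_fc) {
  stopifnot(all(prop_control >= 0 & prop_control <= 1, na.rm = TRUE),
            all(prop_tm >= 0 & prop_tm <= 1, na.rm = TRUE))
  mf <- ifelse(prop_control > 0, total_fc * prop_tm / prop_control, NA_real_)
  pf <- ifelse(prop_control < 1,
               total_fc * (1 - prop_tm) / (1 - prop_control), NA_real_)
  data.frame(maternal_fold = mf, paternal_fold = pf,
             undefined = is.na(mf) | is.na(pf))
}

#' Reconstruct the post-stress allelic state from allele-specific folds
#'
#' The inverse of [allelic_fold_decomposition()]: from the control maternal
#' proportion and the two allele-specific linear fold changes, recovers the
#' total fold change and the maternal proportion under TM.
#'
#' @param prop_control Maternal proportion under control.
#' @param maternal_fold,paternal_fold Allele-specific linear fold changes.
#' @return Data frame with total_fold and prop_tm.
#' @export
allelic_response_reconstruction <- function(prop_control, maternal_fold,
                                            paternal_fold) {
  total <- prop_control * maternal_fold + (1 - prop_control) * paternal_fold
  data.frame(total_fold = total,
             prop_tm = prop_control * maternal_fold / total)
}

#' Between-replicate dispersion of allelic proportions
#'
#' Diagnostic for the extra-binomial variability that pooled exact tests do
#' not model: per gene, cross and condition, the standard deviation of the
#' per-replicate maternal proportion across replicates (genes with >= 2
#' replicate observations of coverage >= 10).
#'
#' @param gac_reps Aggregated allele counts with `pool_replicates = FALSE`.
#' @param min_coverage Minimum per-replicate coverage for a proportion to
#'   enter the dispersion estimate (default 10).
#' @return Data frame with gene, cross, condition, n_reps and prop_sd.
#' @export
ase_replicate_dispersion <- function(gac_reps, min_coverage = 10) {
  cov <- gac_reps$maternal_total + gac_reps$paternal_total
  sub <- gac_reps[cov >= min_coverage, , drop = FALSE]
  prop <- sub$maternal_total / (sub$maternal_total + sub$paternal_total)
  key <- paste(sub$gene, sub$cross, sub$condition, sep = "\r")
  sds <- tapply(prop, key, stats::sd)
  ns <- tapply(prop, key, length)
  keep <- ns >= 2
  parts <- do.call(rbind, strsplit(names(sds)[keep], "\r", fixed = TRUE))
  data.frame(gene = parts[, 1L], cross = parts[, 2L], condition = parts[, 3L],
             n_reps = as.integer(ns[keep]), prop_sd = as.numeric(sds[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cross summary of stress-induced ASE
#'
#' Counts and percentages of informative genes with a significant ASE change,
#' the direction tallies of the maternal-proportion shift, and the
#' intersection with TM-upregulated genes.
#'
#' @param results A [test_ase_change()] table for one cross.
#' @param induced_genes Character vector of genes upregulated by TM (from the
#'   induction analysis).
#' @return One-row data frame mirroring the per-cross summary table:
#'   informative count, ASE-change count and percent, up/down tallies,
#'   and the count and percent of ASE-change genes also upregulated by TM.
#' @export
summarize_ase <- function(results, induced_genes = character(0)) {
  sig <- results[results$significant, , drop = FALSE]
  n_sig <- nrow(sig)
  n_up <- sum(sig$maternal_shift == "up")
  n_induced <- sum(sig$gene %in% induced_genes)
  data.frame(
    cross = results$cross[1L],
    n_informative = nrow(results),
    ase_change = n_sig,
    pct_ase_change = 100 * n_sig / max(1L, nrow(results)),
    maternal_up = n_up,
    maternal_down = n_sig - n_up,
    upregulated_by_tm = n_induced,
    pct_upregulated_by_tm = if (n_sig > 0) 100 * n_induced / n_sig else 0,
    stringsAsFactors = FALSE)
}
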