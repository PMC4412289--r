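# Two-step hierarchical inference of cis- and trans-regulatory divergence per
# gene, cross and condition, from pooled parental counts and F1 allelic
# totals, with category assignment and magnitude statistics.
#
# Step 1 tests parental differential expression and F1 allelic imbalance with
# exact binomial tests (BH within each family). Step 2, applied only to genes
# significant in step 1, compares the parental ratio to the F1 allelic ratio
# with Fisher's exact test (BH within the tested subset); a significant ratio
# difference is the trans signal. Conditions are always analyzed separately.

#' Depth-standardize a pair of parental counts
#'
#' Re-expresses two pooled parental counts at a common target depth,
#' preserving the library-size-corrected expression ratio (rounded to
#' integers). This puts the parental row of the 2x2 Fisher table on the same
#' footing as the F1 allelic row and keeps the exact tests conservative when
#' replicate counts are overdispersed relative to pure count sampling.
#'
#' @param a,b Pooled counts for the two strains.
#' @param lib_a,lib_b Effective library sizes of the pooled samples.
#' @param target Common depth (here, the gene's F1 allelic total).
#' @return Integer vector `c(a_std, b_std)` summing to `target`.
#' @export
standardize_parental_pair <- function(a, b, lib_a, lib_b, target) {
  stopifnot(a >= 0, b >= 0, lib_a > 0, lib_b > 0, target >= 0)
  if (a + b == 0) return(c(NA_integer_, NA_integer_))
  ra <- (a / lib_a) / (a / lib_a + b / lib_b)
  a_std <- as.integer(round(target * ra))
  c(a_std, as.integer(target) - a_std)
}

#' Exact binomial test of parental differential expression
#'
#' Tests pooled counts of two parental strains against the null that counts
#' split in proportion to the effective library sizes.
#'
#' @param counts_a,counts_b Pooled gene counts for the two strains.
#' @param lib_a,lib_b Effective library sizes (> 0).
#' @return Two-sided p-value, or NA when both counts are zero (gene skipped).
#' @export
parental_de_test <- function(counts_a, counts_b, lib_a, lib_b) {
  if (counts_a + counts_b == 0) return(NA_real_)
  binom_exact_two_sided(counts_a, counts_a + counts_b,
                        lib_a / (lib_a + lib_b))
}

#' Exact binomial test of F1 allelic imbalance
#'
#' @param maternal,paternal Pooled allelic counts.
#' @return Two-sided p-value against a balanced (0.5) allelic proportion.
#' @export
f1_allelic_test <- function(maternal, paternal) {
  binom_exact_two_sided(maternal, maternal + paternal, 0.5)
}

#' Fisher comparison of parental and F1 expression ratios (the trans test)
#'
#' @param parental Length-2 vector of (depth-standardized) parental counts.
#' @param f1 Length-2 vector of F1 maternal/paternal counts.
#' @return Two-sided p-value; NA for a degenerate table (a zero row total),
#'   which downstream is treated as untestable (ambiguous).
#' @export
ratio_comparison_test <- function(parental, f1) {
  if (anyNA(parental) || anyNA(f1) || sum(parental) == 0 || sum(f1) == 0)
    return(NA_real_)
  fisher_exact_two_sided(rbind(parental, f1))
}

#' Assign regulatory categories from the three tests and ratio signs
#'
#' Categories follow the standard parental/F1 decision table: significance of
#' parental divergence (P), F1 allelic imbalance (F1) and the ratio
#' comparison (trans), with the relative sign of the parental and F1 log2
#' ratios separating reinforcing (cis_plus_trans) from opposing (cis_x_trans)
#' combinations. Combinations outside the table, and direction-dependent
#' categories with an undefined sign, are ambiguous.
#'
#' @param sig_p,sig_f1,sig_t Logical vectors of test significance.
#' @param sign_p,sign_f1 Signs of the parental and F1 log2 ratios.
#' @return Character vector of categories.
#' @export
classify_regulation <- function(sig_p, sig_f1, sig_t, sign_p, sign_f1) {
  n <- length(sig_p)
  out <- rep("ambiguous", n)
  same <- sign_p == sign_f1 & sign_p != 0 & sign_f1 != 0
  defined <- sign_p != 0 & sign_f1 != 0
  out[sig_p & sig_f1 & !sig_t] <- "cis"
  out[sig_p & !sig_f1 & sig_t] <- "trans"
  out[sig_p & sig_f1 & sig_t & defined & same] <- "cis_plus_trans"
  out[sig_p & sig_f1 & sig_t & defined & !same] <- "cis_x_trans"
  out[!sig_p & sig_f1 & sig_t] <- "compensatory"
  out[!sig_p & !sig_f1 & !sig_t] <- "conserved"
  out
}

#' Regulatory category labels
#' @return Character vector of the seven category labels.
#' @export
regulatory_categories <- function() {
  c("cis", "trans", "cis_plus_trans", "cis_x_trans",
    "compensatory", "conserved", "ambiguous")
}

.pooled_parental <- function(parents, strain, condition) {
  sel <- parents$samples$group == strain & parents$samples$condition == condition
  if (!any(sel)) stop("no parental samples for ", strain, " / ", condition)
  ids <- parents$samples$sample[sel]
  cols <- match(ids, colnames(parents$counts))
  lib <- sum(colSums(parents$counts[, cols, drop = FALSE]) *
               parents$norm_factors[cols])
  list(counts = rowSums(parents$counts[, cols, drop = FALSE]), lib = lib)
}

#' Two-step cis/trans inference for one cross and condition
#'
#' Runs the full hierarchy on the informative genes of one F1 cross in one
#' condition: exact binomial tests of parental divergence and F1 allelic
#' imbalance (BH within each family), the Fisher ratio comparison on genes
#' significant in step 1 (BH within that subset), category assignment, and
#' magnitude statistics (cis magnitude = |log2 F1 allelic ratio|, trans
#' magnitude = |log2 parental ratio - log2 F1 ratio|, percent cis =
#' cis / (cis + trans)).
#'
#' @param parents A `gene_counts` object holding the parental strains (TMM
#'   factors applied).
#' @param gac Aggregated F1 allele counts (replicates pooled) for the cross.
#' @param cross F1 cross label (must match `gac$cross`).
#' @param maternal,paternal Parental strain labels in `parents`; the maternal
#'   strain is the reference/numerator throughout.
#' @param condition `"control"` or `"TM"`.
#' @param fdr Significance threshold applied to every level (default 0.001).
#' @return Data frame, one row per informative gene, with the component
#'   p/q-values, signs, category and magnitudes.
#' @export
run_cistrans <- function(parents, gac, cross, maternal, paternal,
                         condition, fdr = 0.001) {
  stopifnot(inherits(parents, "gene_counts"))
  if (!paternal %in% parents$samples$group)
    stop("missing parental data for cross ", cross, ": strain ", paternal)
  sub <- gac[gac$cross == cross & gac$condition == condition, , drop = FALSE]
  genes <- informative_genes(sub, "cistrans")
  sub <- sub[match(genes, sub$gene), , drop = FALSE]
  mm <- .pooled_parental(parents, maternal, condition)
  pp <- .pooled_parental(parents, paternal, condition)
  a <- mm$counts[genes]; b <- pp$counts[genes]
  keep <- !is.na(a) & !is.na(b) & (a + b) > 0
  sub <- sub[keep, , drop = FALSE]
  a <- a[keep]; b <- b[keep]
  n <- nrow(sub)
  m_tot <- sub$maternal_total; p_tot <- sub$paternal_total
  total <- m_tot + p_tot

  std <- matrix(NA_integer_, n, 2)
  p_p <- p_f1 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    std[i, ] <- standardize_parental_pair(a[i], b[i], mm$lib, pp$lib, total[i])
    p_p[i] <- if (anyNA(std[i, ])) NA_real_ else
      binom_exact_two_sided(std[i, 1L], total[i], 0.5)
    p_f1[i] <- f1_allelic_test(m_tot[i], p_tot[i])
  }
  q_p <- q_f1 <- rep(NA_real_, n)
  q_p[!is.na(p_p)] <- bh_fdr(p_p[!is.na(p_p)])
  q_f1[!is.na(p_f1)] <- bh_fdr(p_f1[!is.na(p_f1)])
  sig_p <- !is.na(q_p) & q_p <= fdr
  sig_f1 <- !is.na(q_f1) & q_f1 <= fdr

  step2 <- which(sig_p | sig_f1)
  p_t <- q_t <- rep(NA_real_, n)
  for (i in step2)
    p_t[i] <- ratio_comparison_test(std[i, ], c(m_tot[i], p_tot[i]))
  tested <- step2[!is.na(p_t[step2])]
  q_t[tested] <- bh_fdr(p_t[tested])
  sig_t <- !is.na(q_t) & q_t <= fdr
  untestable <- setdiff(step2, tested)  # degenerate Fisher table

  ratio_p <- log2(((a + 0.5) / mm$lib) / ((b + 0.5) / pp$lib))
  ratio_f1 <- log2((m_tot + 0.5) / (p_tot + 0.5))
  category <- classify_regulation(sig_p, sig_f1, sig_t,
                                  sign(ratio_p), sign(ratio_f1))
  category[untestable] <- "ambiguous"
  cis_mag <- abs(ratio_f1)
  trans_mag <- abs(ratio_p - ratio_f1)
  pct_cis <- ifelse(cis_mag + trans_mag > 0,
                    cis_mag / (cis_mag + trans_mag), NA_real_)
  direction_same <- ifelse(sign(ratio_p) == 0 | sign(ratio_f1) == 0, NA,
                           sign(ratio_p) == sign(ratio_f1))
  data.frame(
    gene = sub$gene, cross = cross, condition = condition,
    n_snps = sub$n_snps,
    maternal_total = m_tot, paternal_total = p_tot,
    parental_maternal = std[, 1L], parental_paternal = std[, 2L],
    p_P = p_p, q_P = q_p, p_F1 = p_f1, q_F1 = q_f1, p_T = p_t, q_T = q_t,
    log2_parental_ratio = ratio_p, log2_f1_ratio = ratio_f1,
    direction_same = direction_same, category = category,
    cis_mag = cis_mag, trans_mag = trans_mag, pct_cis = pct_cis,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition dependence of regulatory calls
#'
#' For each gene informative in both conditions of one cross and each effect
#' type (cis, trans), labels whether the effect is found in both conditions,
#' only under control, only under TM, or in neither; for "both" genes the two
#' magnitudes are paired for correlation.
#'
#' @param calls_control,calls_tm [run_cistrans()] tables for the same cross.
#' @return Data frame with gene, effect_type, status and the per-condition
#'   magnitudes.
#' @export
compare_conditions <- function(calls_control, calls_tm) {
  stopifnot(all(calls_control$cross == calls_tm$cross[1L]))
  genes <- intersect(calls_control$gene, calls_tm$gene)
  ic <- match(genes, calls_control$gene)
  it <- match(genes, calls_tm$gene)
  out <- list()
  for (type in c("cis", "trans")) {
    in_c <- calls_control$category[ic] == type
    in_t <- calls_tm$category[it] == type
    status <- ifelse(in_c & in_t, "both",
                     ifelse(in_c, "control-only",
                            ifelse(in_t, "TM-only", "neither")))
    mag_col <- if (type == "cis") "cis_mag" else "trans_mag"
    out[[type]] <- data.frame(
      gene = genes, cross = calls_tm$cross[1L], effect_type = type,
      status = status,
      mag_control = calls_control[[mag_col]][ic],
      mag_tm = calls_tm[[mag_col]][it],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
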