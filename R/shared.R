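# Cross-F1 comparison of regulatory calls: shared vs unique cis/trans
# differences among crosses sharing the maternal strain, chi-squared strain
# effects on the magnitude of shared differences, and the condition contrast
# of sharing proportions.

#' Shared regulatory differences across F1 crosses
#'
#' A gene has a shared regulatory difference when it shows the same effect
#' type (cis with cis, trans with trans; direction is not required to match)
#' in two or more F1 crosses. Only genes informative in at least two crosses
#' are considered; genes with the effect in exactly one cross are unique.
#'
#' @param calls Named list (by cross) of [run_cistrans()] tables for one
#'   condition.
#' @param effect_type `"cis"` or `"trans"`.
#' @return Data frame with one row per gene carrying the effect in >= 1
#'   cross and informative in >= 2 crosses: informativeness and effect
#'   counts, the sharing flag and the crosses carrying the effect.
#' @export
find_shared <- function(calls, effect_type = c("cis", "trans")) {
  effect_type <- match.arg(effect_type)
  stopifnot(length(calls) >= 2L, !is.null(names(calls)))
  condition <- calls[[1L]]$condition[1L]
  genes <- sort(unique(unlist(lapply(calls, `[[`, "gene"))))
  inf <- vapply(calls, function(d) genes %in% d$gene, logical(length(genes)))
  eff <- vapply(calls, function(d) {
    i <- match(genes, d$gene)
    !is.na(i) & d$category[i] == effect_type
  }, logical(length(genes)))
  inf <- matrix(inf, nrow = length(genes)); eff <- matrix(eff, nrow = length(genes))
  n_inf <- rowSums(inf); n_eff <- rowSums(eff)
  keep <- which(n_inf >= 2L & n_eff >= 1L)
  crosses <- names(calls)
  out <- data.frame(
    gene = genes[keep],
    condition = rep(condition, length(keep)),
    effect_type = rep(effect_type, length(keep)),
    n_informative_crosses = as.integer(n_inf[keep]),
    n_crosses_with_effect = as.integer(n_eff[keep]),
    shared = n_eff[keep] >= 2L,
    crosses_with_effect = vapply(keep, function(r)
      paste(crosses[eff[r, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-squared strain effect on the magnitude of shared differences
#'
#' For each shared gene, tests whether the allelic proportion is homogeneous
#' across the crosses carrying the effect, on the pooled maternal/paternal
#' allele counts (a K x 2 Pearson chi-squared test), BH-corrected across
#' tested genes; a strain effect is called at `fdr`.
#'
#' @param shared A [find_shared()] table.
#' @param gac Aggregated allele counts (replicates pooled), all crosses.
#' @param condition Condition whose counts are tested.
#' @param fdr Significance threshold on q (default 0.05).
#' @return The shared table restricted to shared genes, with chi2, p, q,
#'   strain_effect and an `untestable` flag for degenerate tables.
#' @export
strain_effect_on_shared <- function(shared, gac, condition, fdr = 0.05) {
  sub <- shared[shared$shared, , drop = FALSE]
  n <- nrow(sub)
  chi2 <- p <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  gsub <- gac[gac$condition == condition, , drop = FALSE]
  for (i in seq_len(n)) {
    crosses <- strsplit(sub$crosses_with_effect[i], ";", fixed = TRUE)[[1L]]
    rows <- gsub[gsub$gene == sub$gene[i] & gsub$cross %in% crosses, ,
                 drop = FALSE]
    tab <- cbind(rows$maternal_total, rows$paternal_total)
    res <- tryCatch(chi2_heterogeneity(tab), error = function(e) NULL)
    if (is.null(res)) untestable[i] <- TRUE
    else { chi2[i] <- res$statistic; p[i] <- res$p.value }
  }
  q <- rep(NA_real_, n)
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  sub$chi2 <- chi2
  sub$p <- p
  sub$q <- q
  sub$strain_effect <- !is.na(q) & q <= fdr
  sub$untestable <- untestable
  rownames(sub) <- NULL
  sub
}

#' Condition contrast of sharing proportions
#'
#' Compares the proportion of shared (vs unique) regulatory differences
#' between control and TM with a 2x2 Pearson chi-squared test, overall and
#' stratified by the number of informative crosses.
#'
#' @param shared_control,shared_tm [find_shared()] tables for the two
#'   conditions (same effect type).
#' @return List with the 2x2 `table` (conditions x shared/unique), `p.value`,
#'   per-condition sharing proportions, and a stratified data frame.
#' @export
condition_sharing_contrast <- function(shared_control, shared_tm) {
  count2 <- function(d) c(shared = sum(d$shared), unique = sum(!d$shared))
  tab <- rbind(control = count2(shared_control), TM = count2(shared_tm))
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    chi2_heterogeneity(tab)$p.value else NA_real_
  strata <- sort(unique(c(shared_control$n_informative_crosses,
                          shared_tm$n_informative_crosses)))
  strat <- do.call(rbind, lapply(strata, function(s) {
    tc <- count2(shared_control[shared_control$n_informative_crosses == s, ])
    tt <- count2(shared_tm[shared_tm$n_informative_crosses == s, ])
    st <- rbind(tc, tt)
    ps <- if (all(rowSums(st) > 0) && all(colSums(st) > 0))
      chi2_heterogeneity(st)$p.value else NA_real_
    data.frame(n_informative_crosses = s,
               control_shared = tc[1L], control_unique = tc[2L],
               tm_shared = tt[1L], tm_unique = tt[2L], p = ps)
  }))
  rownames(strat) <- NULL
  list(table = tab, p.value = p,
       prop_shared = c(control = unname(tab[1L, 1L] / max(1, sum(tab[1L, ]))),
                       TM = unname(tab[2L, 1L] / max(1, sum(tab[2L, ])))),
       stratified = strat)
}
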