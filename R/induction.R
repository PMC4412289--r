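# Induction analysis of parental strains: TMM normalization, PCA-based
# condition QC, per-strain calling of TM-induced genes with a
# common-dispersion NB exact test, strain effects on induction magnitude,
# and the correlation network among variable responders.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes TMM scaling factors (via edgeR, the method's reference
#' implementation) against the sample whose upper quartile is closest to the
#' mean upper quartile; factors have geometric mean 1.
#'
#' @param x A [gene_counts()] object with at least two samples.
#' @param logratio_trim Fraction of extreme M-values trimmed (default 0.30).
#' @param sum_trim Fraction of extreme A-values trimmed (default 0.05).
#' @return Numeric vector of per-sample factors.
#' @export
tmm_factors <- function(x, logratio_trim = 0.30, sum_trim = 0.05) {
  stopifnot(inherits(x, "gene_counts"))
  if (ncol(x$counts) < 2L) stop("need at least two samples")
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x$counts)[lib == 0], collapse = ", "))
  edgeR::calcNormFactors(x$counts, lib.size = lib, method = "TMM",
                         logratioTrim = logratio_trim, sumTrim = sum_trim)
}

#' @rdname tmm_factors
#' @export
tmm_normalize <- function(x, logratio_trim = 0.30, sum_trim = 0.05) {
  x$norm_factors <- tmm_factors(x, logratio_trim, sum_trim)
  x
}

#' Normalized counts per million
#'
#' @param x A `gene_counts` object (normalization factors applied).
#' @param pseudocount Count added before scaling (default 0).
#' @return Matrix of normalized CPM values.
#' @export
normalized_cpm <- function(x, pseudocount = 0) {
  eff <- colSums(x$counts) * x$norm_factors
  sweep(x$counts + pseudocount, 2, eff / 1e6, "/")
}

.subset_samples <- function(x, keep) {
  gene_counts(x$counts[, keep, drop = FALSE],
              x$samples[x$samples$sample %in% keep, , drop = FALSE],
              x$norm_factors[match(keep, colnames(x$counts))])
}

#' Drop samples (e.g. QC outliers) from a count matrix
#'
#' @param x A `gene_counts` object.
#' @param samples Sample ids to remove.
#' @return The reduced `gene_counts` object (renormalize afterwards).
#' @export
drop_samples <- function(x, samples) {
  .subset_samples(x, setdiff(colnames(x$counts), samples))
}

#' Condition-outlier QC for one strain
#'
#' Projects log-normalized counts of one strain's samples onto the first two
#' principal components, partitions them into two groups by 2-means seeded at
#' the condition centroids (deterministic), and flags any sample whose group's
#' majority condition differs from its own. A flagged sample is removed only
#' when a leave-one-out check confirms it sits clearly closer to the opposite
#' condition's centroid, so overlapping (signal-free) conditions yield no
#' removals. Removal that would leave fewer than two replicates in either
#' condition is refused with an error naming the strain and condition.
#'
#' @param x A `gene_counts` object.
#' @param strain Strain whose samples are screened (both conditions present).
#' @return Character vector of sample ids to remove (possibly empty).
#' @export
qc_condition_outliers <- function(x, strain) {
  sel <- x$samples$group == strain
  if (!all(c("control", "TM") %in% x$samples$condition[sel]))
    stop("both conditions required for strain ", strain)
  sub <- .subset_samples(x, x$samples$sample[sel])
  lmat <- log2(normalized_cpm(sub, pseudocount = 0.5))
  lmat <- lmat[apply(lmat, 1, stats::sd) > 0, , drop = FALSE]
  proj <- stats::prcomp(t(lmat), center = TRUE, scale. = FALSE)$x
  proj <- proj[, seq_len(min(2L, ncol(proj))), drop = FALSE]
  cond <- sub$samples$condition
  centers <- rbind(colMeans(proj[cond == "control", , drop = FALSE]),
                   colMeans(proj[cond == "TM", , drop = FALSE]))
  # act only when the conditions actually separate on the projection:
  # the centroid gap must dominate the within-condition spread, otherwise
  # there is no condition structure to attribute samples to
  own_center <- centers[match(cond, c("control", "TM")), , drop = FALSE]
  within <- mean(rowSums((proj - own_center)^2))
  sep <- sum((centers[1L, ] - centers[2L, ])^2)
  if (sep <= 2 * within) return(character(0))
  cl <- stats::kmeans(proj, centers = centers)$cluster
  flagged <- integer(0)
  for (g in unique(cl)) {
    members <- which(cl == g)
    tab <- table(cond[members])
    if (length(tab) > 1L && tab[1L] == tab[2L]) next  # tie: no attribution
    majority <- names(which.max(tab))
    flagged <- c(flagged, members[cond[members] != majority])
  }
  # confirm each flagged sample with a leave-one-out margin: it must sit
  # clearly closer to the other condition's centroid than to its own, so that
  # overlapping (signal-free) conditions yield no removals
  confirmed <- vapply(flagged, function(i) {
    own <- which(cond == cond[i]); own <- setdiff(own, i)
    oth <- which(cond != cond[i])
    d_own <- sum((proj[i, ] - colMeans(proj[own, , drop = FALSE]))^2)
    d_oth <- sum((proj[i, ] - colMeans(proj[oth, , drop = FALSE]))^2)
    d_oth < 0.25 * d_own
  }, logical(1))
  removed <- sub$samples$sample[flagged[confirmed]]
  if (length(removed)) {
    left <- table(cond[!sub$samples$sample %in% removed])
    for (cc in c("control", "TM"))
      if (is.na(left[cc]) || left[cc] < 2L)
        stop(sprintf("QC error: removing outliers leaves < 2 %s replicates for strain %s",
                     cc, strain))
  }
  removed
}

#' Per-strain test of TM induction
#'
#' Compares TM to control samples of one strain with edgeR's exact
#' negative-binomial test under a single common dispersion, after TMM
#' normalization within the strain. A gene is called induced when its linear
#' fold-change point estimate is at least `min_fold` (upregulation only) and
#' its BH q-value is at most `fdr`.
#'
#' @param x A `gene_counts` object.
#' @param strain Strain to test (>= 2 replicates per condition).
#' @param fdr FDR threshold for the induced call (default 0.01).
#' @param min_fold Linear fold-change threshold (default 1.5).
#' @return Data frame with gene, strain, log2FC, p, q and induced; genes with
#'   zero counts in every sample are excluded and listed in the `excluded`
#'   attribute.
#' @export
test_induction <- function(x, strain, fdr = 0.01, min_fold = 1.5) {
  sel <- x$samples$group == strain
  cond <- x$samples$condition[sel]
  if (sum(cond == "control") < 2L || sum(cond == "TM") < 2L)
    stop("need >= 2 replicates per condition for strain ", strain)
  m <- x$counts[, x$samples$sample[sel], drop = FALSE]
  zero <- rowSums(m) == 0
  d <- edgeR::DGEList(counts = m[!zero, , drop = FALSE],
                      group = factor(cond, levels = c("control", "TM")))
  d <- edgeR::calcNormFactors(d, method = "TMM")
  d <- edgeR::estimateCommonDisp(d)
  et <- edgeR::exactTest(d, pair = c("control", "TM"))
  res <- data.frame(gene = rownames(et$table),
                    strain = strain,
                    log2FC = et$table$logFC,
                    p = et$table$PValue,
                    stringsAsFactors = FALSE)
  res$q <- bh_fdr(res$p)
  res$induced <- res$log2FC >= log2(min_fold) & res$q <= fdr
  attr(res, "excluded") <- rownames(m)[zero]
  res
}

#' Sharing spectrum of induced genes across strains
#'
#' For every gene induced in at least one strain, counts the strains in which
#' it is induced and assigns it to the unique (exactly one strain), shared
#' (two to K-1) or common (all K strains) class.
#'
#' @param results Named list of per-strain [test_induction()] tables.
#' @return Data frame with gene, n_strains and class.
#' @export
induced_gene_sets <- function(results) {
  k <- length(results)
  stopifnot(k >= 1L)
  induced <- lapply(results, function(r) r$gene[r$induced])
  genes <- sort(unique(unlist(induced)))
  if (length(genes) == 0L)
    return(data.frame(gene = character(0), n_strains = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  n <- rowSums(vapply(induced, function(g) genes %in% g, logical(length(genes))))
  cls <- ifelse(n == k, "common", ifelse(n == 1L, "unique", "shared"))
  data.frame(gene = genes, n_strains = as.integer(n), class = cls,
             stringsAsFactors = FALSE)
}

#' Per-replicate log2 fold changes against the median control
#'
#' For each strain, the TM-induced change of a gene in each TM replicate is
#' the log2 ratio of that replicate's normalized expression to the strain's
#' median control expression. Genes whose median control expression is zero in
#' a strain are dropped for that strain (reported in the `excluded`
#' attribute); a small CPM pseudocount stabilises the ratio.
#'
#' @param x A `gene_counts` object with TMM factors applied.
#' @param pseudocount CPM offset added to numerator and denominator
#'   (default 0.5).
#' @return Long data frame with gene, strain, replicate and log2fc.
#' @export
fold_change_table <- function(x, pseudocount = 0.5) {
  cpm <- normalized_cpm(x)
  out <- list(); excl <- list()
  for (s in unique(x$samples$group)) {
    ctrl <- x$samples$sample[x$samples$group == s &
                               x$samples$condition == "control"]
    tm <- x$samples$sample[x$samples$group == s & x$samples$condition == "TM"]
    if (length(ctrl) < 2L || length(tm) < 2L)
      stop("need >= 2 replicates per condition for strain ", s)
    med <- apply(cpm[, ctrl, drop = FALSE], 1, stats::median)
    ok <- med > 0
    excl[[s]] <- rownames(cpm)[!ok]
    for (r in seq_along(tm)) {
      out[[paste(s, r)]] <- data.frame(
        gene = rownames(cpm)[ok], strain = s, replicate = r,
        log2fc = log2((cpm[ok, tm[r]] + pseudocount) / (med[ok] + pseudocount)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excl
  res
}

#' Strain effect on TM-induced fold change
#'
#' One-way ANOVA of the replicate log2 fold changes across strains, per gene
#' (the model fold_change = mean + strain + error), BH-corrected across genes.
#' Genes with fewer than two strains carrying two or more TM replicates are
#' skipped and reported.
#'
#' @param fc A [fold_change_table()].
#' @param fdr Significance threshold on q (default 0.01).
#' @return Data frame with gene, F, p, q, significant; skipped genes in the
#'   `skipped` attribute.
#' @export
strain_effect <- function(fc, fdr = 0.01) {
  res <- lapply(split(fc, fc$gene), function(d) {
    groups <- split(d$log2fc, d$strain)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) return(NULL)
    a <- one_way_anova(groups)
    data.frame(gene = d$gene[1L], F = a$F, p = a$p.value,
               stringsAsFactors = FALSE)
  })
  skipped <- names(res)[vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(0), F = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$significant <- out$q <= fdr
  attr(out, "skipped") <- skipped
  out
}

#' Spearman correlation network among variable genes
#'
#' All pairwise Spearman correlations of per-replicate fold-change profiles
#' within a gene subset; edges are retained when the correlation p-value is
#' below `alpha`, with rho as edge weight. Genes with constant profiles are
#' dropped with a warning.
#'
#' @param fc A [fold_change_table()].
#' @param genes Gene subset to correlate.
#' @param alpha Edge significance threshold (default 0.05).
#' @return Edge-list data frame (gene1, gene2, rho, p).
#' @export
correlation_network <- function(fc, genes, alpha = 0.05) {
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      rho = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  genes <- intersect(genes, unique(fc$gene))
  if (length(genes) < 2L) return(empty)
  sub <- fc[fc$gene %in% genes, , drop = FALSE]
  obs <- paste(sub$strain, sub$replicate, sep = ".")
  mat <- tapply(sub$log2fc, list(sub$gene, obs), identity)
  if (anyNA(mat)) mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  keep <- apply(mat, 1, stats::sd) > 0
  if (any(!keep))
    warning("dropping constant fold-change profile(s): ",
            paste(rownames(mat)[!keep], collapse = ", "))
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2L) return(empty)
  gs <- rownames(mat)
  edges <- list()
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in seq(i + 1L, nrow(mat))) {
      ct <- spearman_cor(mat[i, ], mat[j, ])
      if (ct$p.value < alpha)
        edges[[length(edges) + 1L]] <- data.frame(
          gene1 = gs[i], gene2 = gs[j], rho = ct$rho, p = ct$p.value,
          stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L) return(empty)
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
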