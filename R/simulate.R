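# Synthetic-data generator: parental count matrices and F1 per-SNP allele
# counts with a known regulatory architecture (induction, cis, trans and
# stress-only effects), so every downstream stage can be validated by
# parameter recovery without any external data.

#' Expected maternal allelic proportion from a cis effect
#'
#' The cis effect `c` is the log2 maternal/paternal allelic ratio; in the F1
#' both alleles share one trans environment, so the expected maternal read
#' proportion is `2^c / (2^c + 1)`.
#'
#' @param c Cis effect on the log2 scale (finite, vectorised).
#' @return Expected maternal proportion in (0, 1).
#' @export
expected_allelic_proportion <- function(c) {
  stopifnot(all(is.finite(c)))
  r <- 2^c
  r / (r + 1)
}

#' Simulation configuration
#'
#' Defines the experimental design the generator emulates: inbred parental
#' strains (maternal reference first) measured in control and tunicamycin (TM)
#' conditions with replicates, plus F1 crosses sharing the maternal strain.
#' Per-gene expression is negative binomial; F1 allelic counts are binomial
#' (optionally beta-binomial) around the cis-determined proportion. Trans
#' effects shift parental strain means but cancel in the F1 allelic ratio;
#' stress-only cis effects are active under TM alone.
#'
#' @param n_genes Number of genes.
#' @param strains Parental strain labels, maternal reference first.
#' @param crosses Data frame with columns `cross` and `paternal` (paternal
#'   strain of each F1 cross); all crosses share the maternal strain.
#' @param n_replicates Replicates per strain/cross x condition.
#' @param library_size Mean reads per parental sample.
#' @param dispersion Negative-binomial dispersion of parental counts between
#'   replicates (0 gives Poisson).
#' @param f1_coverage Expected pooled allelic coverage per gene and condition
#'   in an F1 cross (control scale; TM coverage follows induction).
#' @param coverage_sd_log Log-normal sd of per-gene coverage variation.
#' @param snps_per_gene_lambda SNPs per gene and cross are `1 + Poisson(lambda)`.
#' @param frac_induced Fraction of genes upregulated by TM in >= 1 strain.
#' @param frac_induced_common,frac_induced_unique Of induced genes, the
#'   fractions induced in all strains and in exactly one strain (the rest are
#'   induced in an intermediate number of strains).
#' @param induction_log2fc Range of per-gene induction log2 fold changes.
#' @param frac_strain_effect Of induced genes, the fraction whose induction
#'   magnitude differs between strains.
#' @param strain_effect_delta Range of the added log2 difference for
#'   strain-effect genes.
#' @param frac_cis,frac_trans,frac_cis_plus_trans,frac_cis_x_trans,frac_compensatory
#'   Fractions of genes with each persistent regulatory architecture.
#' @param frac_tm_only_cis Fraction of genes with a cis effect present only
#'   under TM (the stress-only regulatory layer).
#' @param effect_size Range of |cis| and |trans| effect magnitudes (log2).
#' @param shared_frac Probability that a persistent effect is shared across
#'   two or more crosses (equal magnitude and sign); otherwise it is private
#'   to one cross. Stress-only effects are always cross-private.
#' @param artifact_frac Fraction of SNPs carrying an injected quality-flag
#'   artifact (for filter testing).
#' @param allelic_rho Beta-binomial intra-class correlation of allelic counts
#'   (0 = pure binomial, the default assumed by the exact tests).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       strains = c("B6", "A", "129", "NOD", "NZO",
                                   "CAST", "PWK", "WSB"),
                       crosses = data.frame(
                         cross = c("xCAST", "x129", "xNOD", "xNZO", "xWSB"),
                         paternal = c("CAST", "129", "NOD", "NZO", "WSB"),
                         stringsAsFactors = FALSE),
                       n_replicates = 3,
                       library_size = 1e7,
                       dispersion = 0.05,
                       f1_coverage = 300,
                       coverage_sd_log = 0.5,
                       snps_per_gene_lambda = 2.5,
                       frac_induced = 0.15,
                       frac_induced_common = 0.10,
                       frac_induced_unique = 0.38,
                       induction_log2fc = c(0.8, 3),
                       frac_strain_effect = 0.15,
                       strain_effect_delta = c(1, 2),
                       frac_cis = 0.05,
                       frac_trans = 0.02,
                       frac_cis_plus_trans = 0.01,
                       frac_cis_x_trans = 0.01,
                       frac_compensatory = 0.01,
                       frac_tm_only_cis = 0.02,
                       effect_size = c(0.5, 2),
                       shared_frac = 0.6,
                       artifact_frac = 0.05,
                       allelic_rho = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_induced, frac_induced_common, frac_induced_unique,
          frac_strain_effect, frac_cis, frac_trans, frac_cis_plus_trans,
          frac_cis_x_trans, frac_compensatory, frac_tm_only_cis,
          shared_frac, artifact_frac)
  if (any(fr < 0 | fr > 1)) stop("config error: fractions must lie in [0, 1]")
  if (frac_cis + frac_trans + frac_cis_plus_trans + frac_cis_x_trans +
      frac_compensatory + frac_tm_only_cis > 1)
    stop("config error: regulatory fractions sum to more than 1")
  if (frac_induced_common + frac_induced_unique > 1)
    stop("config error: induction sharing fractions sum to more than 1")
  if (dispersion < 0 || allelic_rho < 0 || allelic_rho >= 1)
    stop("config error: dispersion >= 0 and allelic_rho in [0, 1) required")
  if (n_genes < 1 || n_replicates < 2 || library_size <= 0 || f1_coverage <= 0)
    stop("config error: invalid design sizes")
  if (!all(crosses$paternal %in% strains[-1L]))
    stop("config error: every paternal strain must be a non-maternal strain")
  if (anyDuplicated(strains) || anyDuplicated(crosses$cross))
    stop("config error: duplicated strain or cross labels")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

.runif_sign <- function(n, range) {
  stats::runif(n, range[1L], range[2L]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a full dataset with known truth
#'
#' Generates parental gene x sample counts, F1 per-SNP allele records and the
#' generative truth tables under a [sim_config()]. All randomness flows from
#' the config seed; the same config yields identical output.
#'
#' @param config A `sim_config` object.
#' @return An object of class `sim_dataset`: list with `parents` (a
#'   [gene_counts()] object), `snps` (per-SNP allele records including sample
#'   annotations), `samples` (metadata for all samples, parental and F1),
#'   `truth` (list of `regulatory` gene x cross x condition effects and
#'   categories, `induction` per-strain log2 fold changes, `baseline` means)
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  strains <- config$strains
  maternal <- strains[1L]
  S <- length(strains)
  K <- nrow(config$crosses)
  R <- config$n_replicates
  genes <- sprintf("g%05d", seq_len(G))

  # baseline relative abundance (skewed, as in RNA-seq)
  w <- stats::rexp(G)
  rel <- w / sum(w)

  ## --- induction architecture -------------------------------------------
  ind <- matrix(0, G, S, dimnames = list(genes, strains))
  n_ind <- round(config$frac_induced * G)
  induced <- sample.int(G, n_ind)
  if (n_ind > 0) {
    u <- stats::runif(n_ind)
    n_strains_ind <- ifelse(
      u < config$frac_induced_common, S,
      ifelse(u < config$frac_induced_common + config$frac_induced_unique,
             1L,
             if (S > 2) sample(2:(S - 1), n_ind, replace = TRUE) else 1L))
    base_fc <- stats::runif(n_ind, config$induction_log2fc[1L],
                            config$induction_log2fc[2L])
    se_gene <- stats::runif(n_ind) < config$frac_strain_effect
    for (i in seq_len(n_ind)) {
      ss <- sample.int(S, n_strains_ind[i])
      ind[induced[i], ss] <- base_fc[i]
      if (se_gene[i] && length(ss) >= 2) {
        half <- sample(ss, ceiling(length(ss) / 2))
        ind[induced[i], half] <- base_fc[i] +
          stats::runif(1, config$strain_effect_delta[1L],
                       config$strain_effect_delta[2L])
      }
    }
  }

  ## --- regulatory architecture ------------------------------------------
  cis <- array(0, c(G, K, 2), dimnames = list(genes, config$crosses$cross,
                                              c("control", "TM")))
  trans <- cis
  n_cat <- round(G * c(cis = config$frac_cis, trans = config$frac_trans,
                       cis_plus_trans = config$frac_cis_plus_trans,
                       cis_x_trans = config$frac_cis_x_trans,
                       compensatory = config$frac_compensatory,
                       tm_only_cis = config$frac_tm_only_cis))
  pool <- sample.int(G, sum(n_cat))
  assign_cat <- rep(names(n_cat), n_cat)

  pick_crosses <- function(private) {
    if (K == 1L || private || stats::runif(1) >= config$shared_frac)
      return(sample.int(K, 1L))
    sample.int(K, sample(2:K, 1L))
  }
  for (i in seq_along(pool)) {
    g <- pool[i]; cat_i <- assign_cat[i]
    ks <- pick_crosses(private = (cat_i == "tm_only_cis"))
    e <- .runif_sign(1, config$effect_size)
    e2 <- stats::runif(1, config$effect_size[1L], config$effect_size[2L])
    conds <- if (cat_i == "tm_only_cis") 2L else 1:2
    for (cond in conds) {
      switch(cat_i,
        cis            = { cis[g, ks, cond] <- e },
        tm_only_cis    = { cis[g, ks, cond] <- e },
        trans          = { trans[g, ks, cond] <- e },
        cis_plus_trans = { cis[g, ks, cond] <- e
                           trans[g, ks, cond] <- sign(e) * e2 },
        cis_x_trans    = { cis[g, ks, cond] <- e
                           trans[g, ks, cond] <- -sign(e) * e2 },
        compensatory   = { cis[g, ks, cond] <- e
                           trans[g, ks, cond] <- -e })
    }
  }

  ## --- parental count matrix --------------------------------------------
  paternal_of <- stats::setNames(config$crosses$cross, config$crosses$paternal)
  conds <- c("control", "TM")
  sample_ids <- character(0); meta <- NULL
  counts <- matrix(0L, G, S * 2L * R, dimnames = list(genes, NULL))
  col <- 0L
  for (s in seq_len(S)) {
    shift_k <- if (strains[s] %in% names(paternal_of))
      match(paternal_of[[strains[s]]], config$crosses$cross) else 0L
    for (ci in 1:2) {
      mu <- rel * 2^(ind[, s] * (ci == 2L))
      if (shift_k > 0L)
        mu <- mu * 2^(-(cis[, shift_k, ci] + trans[, shift_k, ci]))
      mu <- mu / sum(mu) * config$library_size
      for (r in seq_len(R)) {
        col <- col + 1L
        sample_ids[col] <- paste(strains[s], conds[ci], r, sep = "_")
        counts[, col] <- if (config$dispersion > 0)
          stats::rnbinom(G, mu = mu, size = 1 / config$dispersion)
        else stats::rpois(G, mu)
      }
    }
  }
  colnames(counts) <- sample_ids
  meta_parent <- data.frame(
    sample = sample_ids,
    group = rep(strains, each = 2L * R),
    type = "parent",
    condition = rep(rep(conds, each = R), S),
    replicate = rep(seq_len(R), S * 2L),
    stringsAsFactors = FALSE)

  ## --- F1 per-SNP allele records ----------------------------------------
  f1_meta <- data.frame(
    sample = paste(rep(config$crosses$cross, each = 2L * R),
                   rep(rep(conds, each = R), K),
                   rep(seq_len(R), K * 2L), sep = "_"),
    group = rep(config$crosses$cross, each = 2L * R),
    type = "F1",
    condition = rep(rep(conds, each = R), K),
    replicate = rep(seq_len(R), K * 2L),
    stringsAsFactors = FALSE)

  nsnp <- 1L + stats::rpois(G * K, config$snps_per_gene_lambda)
  # skeleton: one row per gene x cross x snp; (g, k) pairs indexed (k-1)*G + g
  gidx <- rep(seq_len(G), K)[rep(seq_len(G * K), nsnp)]
  kidx <- rep(seq_len(K), each = G)[rep(seq_len(G * K), nsnp)]
  sidx <- sequence(nsnp)
  wsnp <- stats::rexp(length(gidx))
  gk <- (kidx - 1L) * G + gidx
  wsnp <- wsnp / ave(wsnp, gk, FUN = sum)
  flag <- character(length(gidx))
  art <- stats::runif(length(gidx)) < config$artifact_frac
  flag[art] <- sample(.FLAGS, sum(art), replace = TRUE)

  covfac <- stats::rlnorm(G * K, 0, config$coverage_sd_log)
  f1_ind <- (ind[, maternal] +
               ind[, config$crosses$paternal, drop = FALSE]) / 2  # G x K
  tm_mult <- 2^pmin(f1_ind, 3)

  nrec <- length(gidx)
  rows <- vector("list", 2L * R)
  ri <- 0L
  for (ci in 1:2) {
    prop <- expected_allelic_proportion(cis[cbind(gidx, kidx, ci)])
    cond_total <- config$f1_coverage * covfac[gk] *
      (if (ci == 2L) tm_mult[cbind(gidx, kidx)] else 1)
    for (r in seq_len(R)) {
      ri <- ri + 1L
      cov <- stats::rpois(nrec, cond_total * wsnp / R)
      if (config$allelic_rho > 0) {
        ab <- (1 - config$allelic_rho) / config$allelic_rho
        pg <- stats::rbeta(nrec, prop * ab, (1 - prop) * ab)
        m <- stats::rbinom(nrec, cov, pg)
      } else {
        m <- stats::rbinom(nrec, cov, prop)
      }
      rows[[ri]] <- data.frame(
        gene = genes[gidx],
        snp_id = paste0(genes[gidx], "_s", sidx),
        position = sidx * 150L + 37L,
        sample = paste(config$crosses$cross[kidx], conds[ci], r, sep = "_"),
        cross = config$crosses$cross[kidx],
        condition = conds[ci],
        replicate = r,
        maternal_count = m,
        paternal_count = cov - m,
        flags = flag,
        stringsAsFactors = FALSE)[cov > 0, , drop = FALSE]
    }
  }
  snps <- do.call(rbind, rows)
  rownames(snps) <- NULL

  ## --- truth tables -------------------------------------------------------
  reg <- expand.grid(gene = genes, cross = config$crosses$cross,
                     condition = conds, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  idx <- cbind(match(reg$gene, genes),
               match(reg$cross, config$crosses$cross),
               match(reg$condition, conds))
  reg$cis <- cis[idx]
  reg$trans <- trans[idx]
  reg$category <- true_category(reg$cis, reg$trans)
  # total condition effect per strain includes the regulatory shifts of
  # paternal strains (a TM-only cis/trans effect changes that strain's mean
  # under TM even without an induction term)
  shift <- matrix(0, G, S)
  for (s in seq_len(S)) {
    if (!strains[s] %in% names(paternal_of)) next
    k <- match(paternal_of[[strains[s]]], config$crosses$cross)
    shift[, s] <- -(cis[, k, 2L] + trans[, k, 2L]) +
      (cis[, k, 1L] + trans[, k, 1L])
  }
  induction_truth <- data.frame(
    gene = rep(genes, S),
    strain = rep(strains, each = G),
    log2fc = as.vector(ind),
    log2fc_total = as.vector(ind + shift),
    stringsAsFactors = FALSE)

  samples <- rbind(meta_parent, f1_meta)
  structure(list(
    parents = gene_counts(counts, meta_parent),
    snps = snps,
    samples = samples,
    truth = list(regulatory = reg,
                 induction = induction_truth,
                 baseline = data.frame(gene = genes,
                                       baseline_mean = rel * config$library_size,
                                       stringsAsFactors = FALSE)),
    config = config), class = "sim_dataset")
}

#' True regulatory category from generative cis/trans effects
#'
#' Maps the generative cis effect `c` (log2 F1 allelic ratio) and trans effect
#' `t` (log2 parental contribution absent from the F1 ratio) to the category
#' an ideal classifier should recover: conserved (both zero), cis (t = 0),
#' trans (c = 0), compensatory (t = -c, no net parental difference),
#' cis_plus_trans (same sign) or cis_x_trans (opposite sign).
#'
#' @param c,t Numeric vectors of generative effects (log2).
#' @return Character vector of categories.
#' @export
true_category <- function(c, t) {
  out <- rep("conserved", length(c))
  out[c != 0 & t == 0] <- "cis"
  out[c == 0 & t != 0] <- "trans"
  both <- c != 0 & t != 0
  out[both & t == -c] <- "compensatory"
  out[both & t != -c & sign(c) == sign(t)] <- "cis_plus_trans"
  out[both & t != -c & sign(c) != sign(t)] <- "cis_x_trans"
  out
}

#' Write / read the generative regulatory truth table
#'
#' TSV with one row per gene x cross x condition carrying the generative cis
#' and trans effects and the true category; round-trips losslessly.
#'
#' @param truth The `regulatory` component of a simulated dataset's truth.
#' @param path File path.
#' @param comments Extra provenance comment lines.
#' @export
write_truth <- function(truth, path, comments = character()) {
  cols <- c("gene", "cross", "condition", "cis", "trans", "category")
  stopifnot(all(cols %in% names(truth)))
  .write_tsv(truth[cols], path, .provenance(comments))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "cross", "condition", "cis", "trans",
                  "category") %in% names(tr)))
  tr
}
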