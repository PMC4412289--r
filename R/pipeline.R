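# End-to-end orchestration: simulate (or load) data, QC and normalize, call
# induction per strain, test strain effects, classify cis/trans divergence
# per cross and condition, test ASE changes, compare sharing across crosses,
# and write TSV tables plus a machine-readable JSON run report. All
# randomness flows from the simulation config seed; a fixed seed gives an
# identical report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Analysis thresholds
#'
#' The significance and effect-size thresholds used at each stage, recorded
#' verbatim in every output: induction requires >= `induction_fold` linear
#' upregulation at `induction_fdr`; the cis/trans hierarchy applies
#' `cistrans_fdr` at every level; strain effects on induction and on shared
#' differences use `strain_fdr` and `shared_fdr`; ASE changes use `ase_fdr`.
#'
#' @param induction_fold Linear fold-change floor for an induced call (1.5).
#' @param induction_fdr FDR for induction calls (0.01).
#' @param strain_fdr FDR for the strain-effect ANOVA (0.01).
#' @param cistrans_fdr FDR applied at every level of the cis/trans hierarchy
#'   (0.001).
#' @param ase_fdr FDR for ASE-change calls (0.05).
#' @param shared_fdr FDR for the chi-squared strain effect on shared
#'   differences (0.05).
#' @param network_alpha Edge p-value threshold of the correlation network.
#' @return A named list of thresholds.
#' @export
analysis_thresholds <- function(induction_fold = 1.5, induction_fdr = 0.01,
                                strain_fdr = 0.01, cistrans_fdr = 0.001,
                                ase_fdr = 0.05, shared_fdr = 0.05,
                                network_alpha = 0.05) {
  th <- list(induction_fold = induction_fold, induction_fdr = induction_fdr,
             strain_fdr = strain_fdr, cistrans_fdr = cistrans_fdr,
             ase_fdr = ase_fdr, shared_fdr = shared_fdr,
             network_alpha = network_alpha)
  fdrs <- unlist(th[grep("fdr|alpha", names(th))])
  if (any(fdrs <= 0 | fdrs > 1)) stop("thresholds must lie in (0, 1]")
  if (induction_fold < 1) stop("induction_fold must be >= 1")
  th
}

.th_comment <- function(th, config)
  sprintf("seed=%d; thresholds: %s", config$seed,
          paste(names(th), unlist(th), sep = "=", collapse = ", "))

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates a dataset under `config`, writes its files, reads them back
#' through the validating readers, and runs every stage: per-strain condition
#' QC and TMM normalization, induction calling and the sharing spectrum, the
#' strain-effect ANOVA and correlation network, per-cross/per-condition
#' cis/trans classification, condition comparison, ASE-change testing, and
#' the cross-sharing analysis. Writes per-stage TSV tables and a JSON report
#' of summary counts.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all file
#'   output.
#' @param thresholds An [analysis_thresholds()] list.
#' @return Invisibly, a list with every stage's tables and the `report`.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         thresholds = analysis_thresholds()) {
  th <- thresholds
  write_out <- !is.null(outdir)
  if (write_out && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name)
    if (write_out) .write_tsv(df, file.path(outdir, name),
                              .provenance(.th_comment(th, config)))

  ## simulate and round-trip through the validating readers
  sim <- simulate_dataset(config)
  if (write_out) {
    cm <- sprintf("seed=%d", config$seed)
    write_counts(sim$parents, file.path(outdir, "parent_counts.tsv"),
                 file.path(outdir, "samples.tsv"), cm)
    .write_tsv(sim$samples, file.path(outdir, "samples.tsv"), .provenance(cm))
    write_snp_records(sim$snps, file.path(outdir, "snp_allele_counts.tsv"), cm)
    write_truth(sim$truth$regulatory, file.path(outdir, "truth_regulatory.tsv"), cm)
    .write_tsv(sim$truth$induction, file.path(outdir, "truth_induction.tsv"),
               .provenance(cm))
    parents <- read_counts(file.path(outdir, "parent_counts.tsv"),
                           file.path(outdir, "samples.tsv"))
    snps <- read_snp_records(file.path(outdir, "snp_allele_counts.tsv"),
                             sim$samples)
  } else {
    parents <- sim$parents
    snps <- sim$snps
  }

  ## QC and normalization
  parents <- tmm_normalize(parents)
  strains <- unique(parents$samples$group)
  removed <- unlist(lapply(strains, function(s)
    qc_condition_outliers(parents, s)))
  if (length(removed))
    parents <- tmm_normalize(drop_samples(parents, removed))

  ## induction per strain + sharing spectrum
  induction <- lapply(stats::setNames(strains, strains), function(s)
    test_induction(parents, s, fdr = th$induction_fdr,
                   min_fold = th$induction_fold))
  for (s in strains) emit(induction[[s]], sprintf("induction_%s.tsv", s))
  spectrum <- induced_gene_sets(induction)
  emit(spectrum, "induction_sharing.tsv")

  ## strain effect on fold change + correlation network
  fc <- fold_change_table(parents)
  se <- strain_effect(fc, fdr = th$strain_fdr)
  emit(se, "strain_effect.tsv")
  top <- head(se$gene[order(se$q)][se$significant[order(se$q)]], 40L)
  network <- correlation_network(fc, top, alpha = th$network_alpha)
  emit(network, "correlation_network.tsv")

  ## allelic aggregation
  surviving <- filter_snps(snps)
  gac <- aggregate_gene_allele_counts(surviving, pool_replicates = TRUE)

  ## cis/trans per cross and condition
  maternal <- config$strains[1L]
  cistrans <- list(); patterns <- list()
  for (i in seq_len(nrow(config$crosses))) {
    cr <- config$crosses$cross[i]
    calls <- lapply(stats::setNames(c("control", "TM"), c("control", "TM")),
                    function(cond)
                      run_cistrans(parents, gac, cr, maternal,
                                   config$crosses$paternal[i], cond,
                                   fdr = th$cistrans_fdr))
    cistrans[[cr]] <- calls
    emit(rbind(calls$control, calls$TM), sprintf("cistrans_%s.tsv", cr))
    patterns[[cr]] <- compare_conditions(calls$control, calls$TM)
    emit(patterns[[cr]], sprintf("condition_patterns_%s.tsv", cr))
  }

  ## ASE change per cross
  induced_maternal <- induction[[maternal]]$gene[induction[[maternal]]$induced]
  ase <- list(); ase_summary <- list()
  for (cr in config$crosses$cross) {
    ase[[cr]] <- test_ase_change(gac, cr, fdr = th$ase_fdr)
    emit(ase[[cr]], sprintf("ase_change_%s.tsv", cr))
    ase_summary[[cr]] <- summarize_ase(ase[[cr]], induced_maternal)
  }
  ase_summary <- do.call(rbind, ase_summary)
  rownames(ase_summary) <- NULL
  emit(ase_summary, "ase_summary.tsv")

  ## sharing across crosses
  shared <- list(); contrast <- list(); shared_strain <- list()
  if (nrow(config$crosses) >= 2L) {
    for (type in c("cis", "trans")) {
      sc <- find_shared(lapply(cistrans, `[[`, "control"), type)
      st <- find_shared(lapply(cistrans, `[[`, "TM"), type)
      shared[[type]] <- list(control = sc, TM = st)
      emit(rbind(sc, st), sprintf("shared_%s.tsv", type))
      contrast[[type]] <- condition_sharing_contrast(sc, st)
      shared_strain[[type]] <- list(
        control = strain_effect_on_shared(sc, gac, "control", th$shared_fdr),
        TM = strain_effect_on_shared(st, gac, "TM", th$shared_fdr))
      emit(rbind(shared_strain[[type]]$control, shared_strain[[type]]$TM),
           sprintf("shared_%s_strain_effect.tsv", type))
    }
  }

  ## report
  cat_counts <- lapply(cistrans, function(calls)
    lapply(calls, function(d) as.list(table(d$category))))
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("stressdiv")),
    seed = config$seed,
    thresholds = th,
    qc = list(removed_samples = as.character(removed)),
    induction = list(
      induced_per_strain = lapply(induction, function(d) sum(d$induced)),
      n_induced_any = nrow(spectrum),
      sharing = as.list(table(spectrum$class)),
      n_strain_effect = sum(se$significant)),
    cistrans = lapply(cat_counts, function(cc) list(
      control = cc$control, TM = cc$TM)),
    ase = ase_summary,
    sharing = if (length(contrast)) lapply(contrast, function(ct) list(
      prop_shared = as.list(ct$prop_shared),
      p_value = ct$p.value)) else NULL)
  validate_report(report)
  if (write_out)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  invisible(list(sim = sim, parents = parents, induction = induction,
                 spectrum = spectrum, fold_changes = fc, strain_effect = se,
                 network = network, gac = gac, cistrans = cistrans,
                 condition_patterns = patterns, ase = ase,
                 ase_summary = ase_summary, shared = shared,
                 shared_strain_effect = shared_strain,
                 sharing_contrast = contrast, report = report))
}

#' Validate a pipeline report against its schema
#'
#' Checks the presence and basic types of the versioned report fields;
#' called on every write.
#'
#' @param report A report list as produced by [run_pipeline()].
#' @return TRUE invisibly; errors on schema violations.
#' @export
validate_report <- function(report) {
  need <- c("schema_version", "package_version", "seed", "thresholds",
            "qc", "induction", "cistrans", "ase")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("report schema violation: missing ", paste(missing, collapse = ", "))
  if (!identical(report$schema_version, REPORT_SCHEMA_VERSION))
    stop("report schema violation: unknown schema_version")
  stopifnot(is.numeric(report$seed), is.list(report$thresholds))
  invisible(TRUE)
}
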