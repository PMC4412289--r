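# Shared simulated datasets, generated once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .sim_cache))
    assign(name, fn(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# one-cross config for light unit tests
small_config <- function(seed = 42, ...) {
  defaults <- list(
    n_genes = 150, strains = c("B6", "CAST"),
    crosses = data.frame(cross = "xCAST", paternal = "CAST",
                         stringsAsFactors = FALSE),
    library_size = 3e5, dispersion = 0.002, f1_coverage = 1000,
    coverage_sd_log = 0, frac_induced = 0, frac_cis = 0.2, frac_trans = 0.2,
    frac_cis_plus_trans = 0, frac_cis_x_trans = 0, frac_compensatory = 0,
    frac_tm_only_cis = 0, effect_size = c(1, 1), artifact_frac = 0,
    seed = seed)
  override <- list(...)
  do.call(sim_config, utils::modifyList(defaults, override))
}

# category-recovery benchmark run (one cross, both conditions)
recovery_run <- function() cached("recovery", function() {
  sim <- simulate_dataset(sim_config_benchmark("recovery", seed = 1))
  parents <- tmm_normalize(sim$parents)
  gac <- aggregate_gene_allele_counts(filter_snps(sim$snps))
  calls <- lapply(stats::setNames(c("control", "TM"), c("control", "TM")),
                  function(cond) run_cistrans(parents, gac, "xCAST", "B6",
                                              "CAST", cond, fdr = 0.001))
  list(sim = sim, parents = parents, gac = gac, calls = calls)
})

# stress-only architecture benchmark run (five crosses, both conditions)
architecture_run <- function() cached("architecture", function() {
  cfg <- sim_config_benchmark("architecture", seed = 1)
  sim <- simulate_dataset(cfg)
  parents <- tmm_normalize(sim$parents)
  gac <- aggregate_gene_allele_counts(filter_snps(sim$snps))
  calls <- list()
  for (i in seq_len(nrow(cfg$crosses))) {
    cr <- cfg$crosses$cross[i]
    calls[[cr]] <- lapply(stats::setNames(c("control", "TM"),
                                          c("control", "TM")),
                          function(cond)
                            run_cistrans(parents, gac, cr, "B6",
                                         cfg$crosses$paternal[i], cond,
                                         fdr = 0.001))
  }
  list(cfg = cfg, sim = sim, parents = parents, gac = gac, calls = calls)
})

# full default pipeline run, with wall-clock time
default_run <- function() cached("default", function() {
  t0 <- Sys.time()
  res <- run_pipeline(sim_config(seed = 1))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(res = res, elapsed = elapsed)
})
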