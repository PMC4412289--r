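test_that("TMM factors are invariant to depth and have geometric mean one", {
  set.seed(1)
  base <- rpois(400, rexp(400) * 200) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base * 2L, s4 = rpois(400, base))
  rownames(m) <- sprintf("g%03d", 1:400)
  meta <- data.frame(sample = colnames(m), group = "B6", type = "parent",
                     condition = c("control", "control", "TM", "TM"),
                     replicate = c(1, 2, 1, 2))
  x <- gene_counts(m, meta)
  f <- tmm_factors(x)
  expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-12)
  # s3 is s1 at double depth: same composition, equal factors and equal
  # normalized expression
  expect_equal(unname(f[1]), unname(f[3]), tolerance = 1e-6)
  xn <- x; xn$norm_factors <- f
  cpm <- normalized_cpm(xn)
  expect_equal(unname(cpm[, "s1"]), unname(cpm[, "s3"]), tolerance = 1e-6)

  bad <- m; bad[, 2] <- 0L
  expect_error(tmm_factors(gene_counts(bad, meta)), "all-zero")
})

# strain fixture with a known condition signal and an optional mislabeled sample
induction_fixture <- function(mislabel = FALSE, seed = 77) {
  set.seed(seed)
  ng <- 300
  mu <- rexp(ng) * 100 + 5
  fc <- ifelse(seq_len(ng) <= 60, 4, 1)  # 20% of genes 4-fold induced
  cols <- list(
    c1 = rpois(ng, mu), c2 = rpois(ng, mu),
    c3 = rpois(ng, if (mislabel) mu * fc else mu),
    t1 = rpois(ng, mu * fc), t2 = rpois(ng, mu * fc), t3 = rpois(ng, mu * fc))
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("g%03d", seq_len(ng))
  meta <- data.frame(sample = colnames(m), group = "B6", type = "parent",
                     condition = rep(c("control", "TM"), each = 3),
                     replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  tmm_normalize(gene_counts(m, meta))
}

test_that("PCA condition QC flags only genuinely mislabeled samples", {
  clean <- induction_fixture(mislabel = FALSE)
  expect_identical(qc_condition_outliers(clean, "B6"), character(0))

  bad <- induction_fixture(mislabel = TRUE)
  expect_identical(qc_condition_outliers(bad, "B6"), "c3")

  # overlapping conditions (no induction signal): nothing to attribute
  sim <- simulate_dataset(small_config(n_genes = 100, seed = 6))
  x <- tmm_normalize(sim$parents)
  expect_identical(qc_condition_outliers(x, "B6"), character(0))
})

test_that("induction calling recovers known fold changes and is calibrated", {
  x <- induction_fixture()
  res <- test_induction(x, "B6")
  induced_true <- res$gene <= "g060"
  # 4-fold genes: log2FC near 2 and overwhelmingly called
  expect_equal(median(res$log2FC[induced_true]), 2, tolerance = 0.15)
  expect_gt(mean(res$induced[induced_true]), 0.9)
  expect_lt(mean(res$induced[!induced_true]), 0.02)
  # null genes: flat fold change estimates
  expect_lt(abs(median(res$log2FC[!induced_true])), 0.15)

  # type-I error on an all-null strain
  sim <- simulate_dataset(small_config(
    n_genes = 400, library_size = 8e5, dispersion = 0.05, seed = 14,
    frac_cis = 0, frac_trans = 0))
  r0 <- test_induction(tmm_normalize(sim$parents), "B6")
  expect_lt(mean(r0$p < 0.05), 0.09)
  expect_identical(sum(r0$induced), 0L)
})

test_that("the sharing spectrum partitions the induced union", {
  mk <- function(genes, induced) data.frame(
    gene = genes, strain = "s", log2FC = 1, p = 0.001, q = 0.001,
    induced = induced)
  res <- list(A = mk(c("g1", "g2", "g3"), c(TRUE, TRUE, FALSE)),
              B = mk(c("g1", "g2", "g3"), c(TRUE, TRUE, FALSE)),
              C = mk(c("g1", "g2", "g4"), c(TRUE, FALSE, TRUE)))
  spec <- induced_gene_sets(res)
  expect_identical(spec$class[spec$gene == "g1"], "common")
  expect_identical(spec$class[spec$gene == "g2"], "shared")
  expect_identical(spec$class[spec$gene == "g4"], "unique")
  expect_false("g3" %in% spec$gene)
  # partitions are disjoint and exhaustive over the induced union
  expect_identical(sort(spec$gene), c("g1", "g2", "g4"))
  expect_identical(sum(table(spec$class)), 3L)
})

test_that("strain effect ANOVA flags heterogeneous induction magnitudes", {
  fc <- data.frame(
    gene = rep(c("flat", "het"), each = 4),
    strain = rep(rep(c("A", "B"), each = 2), 2),
    replicate = rep(1:2, 4),
    log2fc = c(1, 1.2, 1.1, 1.1, 1, 1.2, 2, 2.2))
  se <- strain_effect(fc)
  expect_equal(se$F[se$gene == "het"], 50, tolerance = 1e-10)
  expect_lt(se$F[se$gene == "flat"], 5)
  # identical fold changes across strains: F = 0
  fc0 <- transform(fc, log2fc = 1)
  expect_true(all(strain_effect(fc0)$F == 0))
  # insufficient replication is skipped and reported
  fc1 <- fc[fc$gene == "het" & fc$strain == "A", ]
  s1 <- strain_effect(rbind(fc, transform(fc1, gene = "solo")))
  expect_identical(attr(s1, "skipped"), "solo")
})

test_that("strain-specific induction is recovered from simulated fold changes", {
  run <- default_run()$res
  truth <- run$sim$truth$induction
  # genes where per-strain true log2FCs differ by >= 1 (and the gene is
  # expressed) should be flagged; homogeneous genes should not
  spread <- tapply(truth$log2fc_total, truth$gene,
                   function(z) diff(range(z)))
  se <- run$strain_effect
  het <- names(spread)[spread >= 1]
  hom <- names(spread)[spread == 0]
  expect_gt(mean(se$significant[se$gene %in% het]), 0.9)
  # the shared control-median denominator correlates a strain's TM
  # replicates, so the null rate sits slightly above the nominal 1%
  expect_lt(mean(se$significant[se$gene %in% hom]), 0.08)
})

test_that("the correlation network finds co-responding genes at the set alpha", {
  set.seed(91)
  n_obs <- 24
  latent <- rnorm(n_obs, sd = 2)
  fc <- do.call(rbind, lapply(1:12, function(i) data.frame(
    gene = sprintf("g%02d", i),
    strain = rep(sprintf("s%d", 1:8), each = 3),
    replicate = rep(1:3, 8),
    log2fc = if (i <= 2) latent + rnorm(n_obs, sd = 0.3) else rnorm(n_obs))))
  net <- correlation_network(fc, sprintf("g%02d", 1:12))
  pair <- net[(net$gene1 == "g01" & net$gene2 == "g02") |
                (net$gene1 == "g02" & net$gene2 == "g01"), ]
  expect_identical(nrow(pair), 1L)
  expect_gt(pair$rho, 0.8)
  # independent genes: roughly alpha of the 45 null pairs
  null_edges <- nrow(net) - 1L
  expect_lt(null_edges, 10)
  # single-gene subset: empty edge list
  expect_identical(nrow(correlation_network(fc, "g01")), 0L)
  # constant profile dropped with a warning
  fc2 <- rbind(fc, data.frame(gene = "flat", strain = rep(sprintf("s%d", 1:8), each = 3),
                              replicate = rep(1:3, 8), log2fc = 0))
  expect_warning(correlation_network(fc2, c("g01", "g02", "flat")), "constant")
})
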