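test_that("component tests behave at their null and closed-form cases", {
  # parental DE: equal counts, equal libraries -> maximal p
  expect_equal(parental_de_test(50, 50, 1e6, 1e6), 1, tolerance = 0.15)
  # complete imbalance has the closed-form two-sided p
  expect_equal(log(parental_de_test(100, 0, 1e6, 1e6)), log(2 * 0.5^100),
               tolerance = 1e-10)
  # counts proportional to library sizes are null by construction
  expect_gt(parental_de_test(200, 100, 2e6, 1e6), 0.5)
  expect_true(is.na(parental_de_test(0, 0, 1e6, 1e6)))

  expect_equal(f1_allelic_test(50, 50), 1)
  expect_equal(log(f1_allelic_test(30, 0)), log(2 * 0.5^30), tolerance = 1e-10)
  expect_lt(f1_allelic_test(67, 33), 0.001)

  # ratio comparison: equal ratios -> p = 1; clear divergence -> tiny p
  expect_equal(ratio_comparison_test(c(80, 20), c(80, 20)), 1)
  expect_lt(ratio_comparison_test(c(80, 20), c(50, 50)), 0.001)
  # power grows monotonically with coverage
  p_seq <- vapply(c(1, 2, 4), function(s)
    ratio_comparison_test(c(70, 30) * s, c(50, 50) * s), numeric(1))
  expect_true(all(diff(p_seq) < 0))
  expect_true(is.na(ratio_comparison_test(c(0, 0), c(5, 5))))
})

test_that("depth standardization preserves the library-corrected ratio", {
  s <- standardize_parental_pair(3000, 1000, 1e6, 1e6, 400)
  expect_identical(s, c(300L, 100L))
  # library-size correction: equal expression at unequal depth -> balanced
  s2 <- standardize_parental_pair(2000, 1000, 2e6, 1e6, 100)
  expect_identical(s2, c(50L, 50L))
  expect_identical(sum(standardize_parental_pair(17, 5, 1.3e6, 0.9e6, 333)),
                   333L)
})

test_that("the category decision table is honored, including ambiguity", {
  cl <- function(...) classify_regulation(...)
  expect_identical(cl(TRUE, TRUE, FALSE, 1, 1), "cis")
  expect_identical(cl(TRUE, TRUE, FALSE, 1, -1), "cis")   # sign-free row
  expect_identical(cl(TRUE, FALSE, TRUE, 1, 0), "trans")
  expect_identical(cl(TRUE, TRUE, TRUE, 1, 1), "cis_plus_trans")
  expect_identical(cl(TRUE, TRUE, TRUE, 1, -1), "cis_x_trans")
  expect_identical(cl(FALSE, TRUE, TRUE, 0, 1), "compensatory")
  expect_identical(cl(FALSE, FALSE, FALSE, 1, 1), "conserved")
  # outside the table -> ambiguous
  expect_identical(cl(TRUE, FALSE, FALSE, 1, 1), "ambiguous")
  expect_identical(cl(FALSE, TRUE, FALSE, 1, 1), "ambiguous")
  expect_identical(cl(FALSE, FALSE, TRUE, 1, 1), "ambiguous")
  # direction-dependent category with undefined sign -> ambiguous
  expect_identical(cl(TRUE, TRUE, TRUE, 0, 1), "ambiguous")
})

test_that("the two-step hierarchy recovers simulated architectures", {
  sim <- cached("regdiv_small", function()
    simulate_dataset(small_config(seed = 11)))
  parents <- tmm_normalize(sim$parents)
  gac <- aggregate_gene_allele_counts(filter_snps(sim$snps))
  calls <- run_cistrans(parents, gac, "xCAST", "B6", "CAST", "control")
  tr <- sim$truth$regulatory
  tr <- tr[tr$condition == "control", ]
  m <- merge(calls, tr, by = "gene", suffixes = c("", ".true"))

  cis_true <- m$category.true == "cis"
  trans_true <- m$category.true == "trans"
  null_true <- m$category.true == "conserved"
  expect_gt(mean(m$category[cis_true] == "cis"), 0.9)
  expect_gt(mean(m$category[trans_true] == "trans"), 0.85)
  expect_gt(mean(m$category[null_true] == "conserved"), 0.95)
  # magnitudes near the generative |effect| = 1, percent cis near its pole
  expect_equal(median(m$cis_mag[cis_true]), 1, tolerance = 0.2)
  expect_equal(median(m$trans_mag[trans_true]), 1, tolerance = 0.2)
  expect_gt(median(m$pct_cis[cis_true]), 0.8)
  expect_lt(median(m$pct_cis[trans_true]), 0.2)
  expect_true(all(m$pct_cis >= 0 & m$pct_cis <= 1, na.rm = TRUE))
  # missing parental strain is a named error
  expect_error(run_cistrans(parents, gac, "xCAST", "B6", "PWK", "control"),
               "xCAST")
})

test_that("magnitudes are invariant to swapping maternal and paternal labels", {
  sim <- cached("regdiv_small", function()
    simulate_dataset(small_config(seed = 11)))
  parents <- tmm_normalize(sim$parents)
  gac <- aggregate_gene_allele_counts(filter_snps(sim$snps))
  fwd <- run_cistrans(parents, gac, "xCAST", "B6", "CAST", "control")
  swapped <- gac
  swapped$maternal_total <- gac$paternal_total
  swapped$paternal_total <- gac$maternal_total
  rev <- run_cistrans(parents, swapped, "xCAST", "CAST", "B6", "control")
  i <- match(fwd$gene, rev$gene)
  expect_equal(rev$cis_mag[i], fwd$cis_mag)
  expect_equal(rev$trans_mag[i], fwd$trans_mag, tolerance = 1e-6)
  expect_identical(rev$category[i], fwd$category)
})

test_that("condition comparison labels cis/trans persistence correctly", {
  mk <- function(genes, cats, cond) data.frame(
    gene = genes, cross = "xCAST", condition = cond, category = cats,
    cis_mag = seq_along(genes), trans_mag = 0.1 * seq_along(genes),
    stringsAsFactors = FALSE)
  ctrl <- mk(c("g1", "g2", "g3", "g4"),
             c("cis", "conserved", "cis", "trans"), "control")
  tm <- mk(c("g1", "g2", "g3", "g5"),
           c("cis", "cis", "conserved", "trans"), "TM")
  out <- compare_conditions(ctrl, tm)
  cis <- out[out$effect_type == "cis", ]
  expect_identical(cis$status[cis$gene == "g1"], "both")
  expect_identical(cis$status[cis$gene == "g2"], "TM-only")
  expect_identical(cis$status[cis$gene == "g3"], "control-only")
  # genes informative in only one condition are excluded entirely
  expect_false("g4" %in% out$gene)
  expect_false("g5" %in% out$gene)
  # magnitudes are paired for "both" genes
  expect_identical(cis$mag_control[cis$gene == "g1"], 1)
  expect_identical(cis$mag_tm[cis$gene == "g1"], 1)
})
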