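make_meta <- function(samples, group = "B6") {
  data.frame(sample = samples, group = group, type = "parent",
             condition = rep(c("control", "TM"), length.out = length(samples)),
             replicate = 1L, stringsAsFactors = FALSE)
}

test_that("gene_counts validates its schema", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- make_meta(c("s1", "s2"))
  expect_s3_class(gene_counts(m, meta), "gene_counts")

  bad <- m; bad[1] <- -1
  expect_error(gene_counts(bad, meta), "non-negative")
  bad <- m; rownames(bad) <- c("g1", "g1")
  expect_error(gene_counts(bad, meta), "duplicate gene")
  expect_error(gene_counts(m, meta[1, ]), "without metadata")
  expect_error(gene_counts(m, meta, norm_factors = c(1, -1)), "positive")
  meta_bad <- meta; meta_bad$condition[1] <- "treated"
  expect_error(gene_counts(m, meta_bad), "condition")
})

test_that("count matrices and SNP records round-trip through TSV", {
  sim <- simulate_dataset(small_config(n_genes = 40, seed = 2))
  d <- withr::local_tempdir()
  cp <- file.path(d, "counts.tsv"); mp <- file.path(d, "meta.tsv")
  write_counts(sim$parents, cp, mp)
  rt <- read_counts(cp, mp)
  expect_equal(rt$counts, sim$parents$counts)
  expect_equal(rt$samples, sim$parents$samples)

  sp <- file.path(d, "snps.tsv")
  write_snp_records(sim$snps, sp)
  rec <- read_snp_records(sp, sim$samples)
  expect_equal(rec$maternal_count, sim$snps$maternal_count)
  expect_equal(rec$cross, sim$snps$cross)
  expect_equal(rec$condition, sim$snps$condition)

  # provenance comments are written
  expect_match(readLines(cp, n = 1), "^# stressdiv")
})

test_that("the readers reject malformed inputs and floor averaged counts", {
  d <- withr::local_tempdir()
  cp <- file.path(d, "c.tsv"); mp <- file.path(d, "m.tsv")
  writeLines(c("gene\ts1\ts2", "g1\t5\t-2"), cp)
  write.table(make_meta(c("s1", "s2")), mp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_counts(cp, mp), "negative")

  # sample present in counts but absent from metadata
  writeLines(c("gene\ts1\tsX", "g1\t5\t2"), cp)
  expect_error(read_counts(cp, mp), "without metadata")

  # averaged (non-integer) counts are floored with a warning
  writeLines(c("gene\ts1\ts2", "g1\t5.5\t2"), cp)
  expect_warning(x <- read_counts(cp, mp), "floored")
  expect_identical(unname(x$counts[1, ]), c(5, 2))

  # unknown quality flags are rejected
  sp <- file.path(d, "s.tsv")
  writeLines(c("gene\tsnp_id\tposition\tsample\tmaternal_count\tpaternal_count\tflags",
               "g1\tg1_s1\t10\ts1\t4\t5\tbad_flag"), sp)
  expect_error(read_snp_records(sp, make_meta("s1")), "unknown quality flag")
})

test_that("SNP filtering enforces the coverage and quality rules", {
  rec <- data.frame(
    gene = "g1", snp_id = c("s1", "s1", "s2", "s2", "s3"),
    position = 1L, sample = "a", cross = "xCAST", condition = "control",
    replicate = 1L,
    maternal_count = c(2, 10, 5, 6, 7),
    paternal_count = c(1, 10, 5, 6, 7),
    flags = c("", "", "", "non_monoallelic_parent", ""),
    stringsAsFactors = FALSE)
  out <- filter_snps(rec)
  # coverage 3 record removed; flagged SNP removed in every sample;
  # clean covered records retained
  expect_identical(out$snp_id, c("s1", "s3"))
  expect_identical(out$maternal_count, c(10, 7))
  expect_identical(filter_snps(out), out)
  expect_identical(nrow(filter_snps(rec[0, ])), 0L)
})

test_that("aggregation pools SNPs and replicates and conserves reads", {
  rec <- data.frame(
    gene = "g1", snp_id = c("s1", "s2"), position = 1:2, sample = "a",
    cross = "xCAST", condition = "control", replicate = 1L,
    maternal_count = c(10, 20), paternal_count = c(5, 10), flags = "",
    stringsAsFactors = FALSE)
  g <- aggregate_gene_allele_counts(rec)
  expect_identical(g$maternal_total, 30L)
  expect_identical(g$paternal_total, 15L)
  expect_identical(g$n_snps, 2L)

  # pooling off: one row per replicate
  rec2 <- rbind(rec, transform(rec, replicate = 2L, sample = "b"))
  g2 <- aggregate_gene_allele_counts(rec2, pool_replicates = FALSE)
  expect_identical(nrow(g2), 2L)
  expect_identical(sum(g2$maternal_total), 60L)

  # aggregation conserves reads on simulated data
  sim <- simulate_dataset(small_config(n_genes = 30, seed = 4))
  surv <- filter_snps(sim$snps)
  gac <- aggregate_gene_allele_counts(surv)
  expect_identical(sum(gac$maternal_total), sum(surv$maternal_count))
  expect_identical(sum(gac$paternal_total), sum(surv$paternal_count))
})

test_that("informativeness applies the SNP-count and coverage thresholds per purpose", {
  gac <- data.frame(
    gene = c("gA", "gA", "gB", "gB", "gC", "gC", "gD"),
    cross = "xCAST",
    condition = c("control", "TM", "control", "TM", "control", "TM", "control"),
    maternal_total = c(11, 11, 250, 260, 30, 31, 500),
    paternal_total = c(10, 10, 250, 240, 30, 30, 400),
    n_snps = c(2L, 2L, 1L, 1L, 3L, 3L, 5L),
    stringsAsFactors = FALSE)
  # gA: 2 SNPs, coverage 21 -> cistrans only; gB: 1 SNP, huge coverage -> never;
  # gC: 3 SNPs, coverage 60/61 in both conditions -> both purposes;
  # gD: present in one condition only -> excluded
  expect_identical(informative_genes(gac, "cistrans"), c("gA", "gC"))
  expect_identical(informative_genes(gac, "ase"), "gC")
  expect_error(informative_genes(gac, "other"))
})
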