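test_that("two-sided binomial exact test matches enumeration and handles edge cases", {
  expect_equal(binom_exact_two_sided(5, 10, 0.5), 1)
  expect_equal(binom_exact_two_sided(10, 10, 0.5), 0.001953125)
  expect_equal(binom_exact_two_sided(0, 10, 0.5), 0.001953125)
  expect_error(binom_exact_two_sided(0, 0, 0.5), "trial")
  expect_error(binom_exact_two_sided(3, 2, 0.5), "lie in")
  expect_error(binom_exact_two_sided(1, 2, 0), "p0")

  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    p <- binom_exact_two_sided(k, n, p0)
    expect_lt(abs(p - oracle_binom_p(k, n, p0)), 1e-10)
    expect_lt(abs(p - binom.test(k, n, p0)$p.value), 1e-10)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(rbind(c(5, 5), c(5, 5))), 1)
  expect_equal(fisher_exact_two_sided(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10))
  expect_equal(fisher_exact_two_sided(rbind(c(3, 1), c(1, 3))),
               0.485714285714, tolerance = 1e-10)
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "empty")

  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    p <- fisher_exact_two_sided(tab)
    expect_lt(abs(p - oracle_fisher_p(tab)), 1e-10)
    expect_lt(abs(p - fisher.test(tab)$p.value), 1e-10)
  }
})

test_that("chi-squared heterogeneity test matches the Pearson statistic", {
  r <- chi2_heterogeneity(rbind(c(50, 50), c(50, 50)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r <- chi2_heterogeneity(rbind(c(20, 10), c(10, 20)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$p.value, 0.00982, tolerance = 1e-3)
  # identical rows of any composition give a zero statistic
  expect_equal(chi2_heterogeneity(rbind(c(7, 13), c(7, 13), c(7, 13)))$statistic, 0)
  expect_error(chi2_heterogeneity(rbind(c(0, 0), c(5, 5))), "degenerate")
  expect_error(chi2_heterogeneity(rbind(c(5, 0), c(7, 0))), "degenerate")

  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    tab <- matrix(rpois(2 * k, 20) + 1, k)
    ours <- chi2_heterogeneity(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH q-values match an independent step-up implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:30) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # step-up monotonicity in sorted-p order
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("Spearman correlation handles ties, perfect ranks, and small-n exactness", {
  x <- 1:6
  expect_equal(spearman_cor(x, x^2)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
  # midrank ties agree with cor(..., method = "spearman")
  set.seed(21)
  for (i in 1:20) {
    a <- sample(1:5, 8, replace = TRUE) + runif(8, 0, 0.01)
    b <- sample(1:4, 8, replace = TRUE) + runif(8, 0, 0.01)
    expect_equal(spearman_cor(a, b)$rho, cor(a, b, method = "spearman"))
  }
  # t-approximation is close to the exact permutation p at small n
  for (y in list(c(2, 1, 4, 5, 3), c(5, 3, 4, 1, 2), c(1, 3, 2, 5, 4))) {
    approx_p <- spearman_cor(1:5, y)$p.value
    exact_p <- oracle_spearman_exact_p(1:5, y)
    expect_lt(abs(approx_p - exact_p), 0.12)
  }
})

test_that("one-way ANOVA matches lm and flags zero residual variance", {
  a <- one_way_anova(list(c(1, 1.2), c(2, 2.2)))
  expect_equal(a$F, 50, tolerance = 1e-10)
  expect_equal(a$p.value, pf(50, 1, 2, lower.tail = FALSE))

  same <- one_way_anova(list(c(3, 3), c(3, 3, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p.value, 1)

  degen <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(degen$zero_residual)
  expect_equal(degen$p.value, 0)
  expect_error(one_way_anova(list(1:3)), "2 groups")

  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(2:6, 1), mean = j / 2))
    ours <- one_way_anova(g)
    d <- data.frame(y = unlist(g),
                    f = factor(rep(seq_len(k), lengths(g))))
    ref <- anova(lm(y ~ f, data = d))
    expect_equal(ours$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # p-values are approximately uniform under the null
  set.seed(41)
  ps <- replicate(400, one_way_anova(list(rnorm(3), rnorm(3), rnorm(3)))$p.value)
  expect_gt(mean(ps), 0.43)
  expect_lt(mean(ps), 0.57)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})
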