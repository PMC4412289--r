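# Exact statistical primitives shared by every downstream stage.
# Two-sided p-values for the exact tests use the minimum-likelihood definition
# (sum the point probabilities of all outcomes no more likely than the one
# observed), the convention of mainstream statistical software.

# relative tolerance when comparing point probabilities, to absorb floating
# point noise at the boundary of the rejection region
.PTOL <- 1 + 1e-07

#' Exact two-sided binomial test
#'
#' P-value for observing `k` successes in `n` trials against a null success
#' probability `p0`, summing the probabilities of all outcomes whose point
#' probability does not exceed that of `k`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @return A single p-value in (0, 1].
#' @examples
#' binom_exact_two_sided(5, 10, 0.5)   # 1
#' binom_exact_two_sided(10, 10, 0.5)  # 2 * 0.5^10
#' @export
binom_exact_two_sided <- function(k, n, p0 = 0.5) {
  if (length(k) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("k, n and p0 must be scalars")
  if (is.na(k) || is.na(n) || n < 1)
    stop("undefined test: need at least one trial")
  if (k < 0 || k > n)
    stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly inside (0, 1)")
  d <- stats::dbinom(0:n, n, p0)
  p <- sum(d[d <= d[k + 1L] * .PTOL])
  min(1, max(p, .Machine$double.xmin))
}

#' Fisher's exact test on a 2x2 table, two-sided
#'
#' Conditional on both margins, sums hypergeometric point probabilities no
#' larger than that of the observed table.
#'
#' @param tab A 2x2 matrix of non-negative counts (rows = group/condition,
#'   columns = allele/strain).
#' @return A single p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("tab must be a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must contain non-negative integer counts")
  if (sum(tab) == 0)
    stop("undefined test: empty table")
  m1 <- sum(tab[1L, ]); m2 <- sum(tab[2L, ]); n1 <- sum(tab[, 1L])
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  d <- stats::dhyper(lo:hi, m1, m2, n1)
  pobs <- stats::dhyper(tab[1L, 1L], m1, m2, n1)
  p <- sum(d[d <= pobs * .PTOL])
  min(1, max(p, .Machine$double.xmin))
}

#' Pearson chi-squared test of allelic-proportion homogeneity across crosses
#'
#' Tests whether the maternal/paternal proportion is constant across the K rows
#' of a K x 2 count table (df = K - 1, no continuity correction).
#'
#' @param counts A K x 2 matrix (K >= 2) of non-negative counts, one row per
#'   cross, columns maternal/paternal.
#' @return List with `statistic`, `df` and `p.value`.
#' @export
chi2_heterogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L || nrow(counts) < 2L)
    stop("counts must be a K x 2 table with K >= 2")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(rowSums(counts) == 0))
    stop("degenerate table: a row total is zero")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("degenerate table: an expected cell is zero")
  stat <- sum((counts - expected)^2 / expected)
  df <- nrow(counts) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Midranks are used for ties. The p-value comes from the large-sample
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df;
#' replicate counts in this design are small, so treat p-values near the
#' significance boundary with care.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p.value`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p.value = p)
}

#' One-way ANOVA from replicate groups
#'
#' Classical fixed-effects F test across groups. When the within-group variance
#' is exactly zero but group means differ, the F statistic is infinite; a
#' `zero_residual` flag is returned together with a p-value of 0 rather than
#' failing.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, at least
#'   one residual degree of freedom overall).
#' @return List with `F`, `df`, `p.value` and `zero_residual`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values are not supported")
  n <- length(x); k <- length(groups)
  if (n - k < 1L) stop("no residual degrees of freedom")
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(x)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((x - rep(means, sizes))^2)
  df <- c(k - 1L, n - k)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = 0, df = df, p.value = 1, zero_residual = FALSE))
    return(list(F = Inf, df = df, p.value = 0, zero_residual = TRUE))
  }
  fstat <- (ssb / df[1L]) / (ssw / df[2L])
  list(F = fstat, df = df,
       p.value = stats::pf(fstat, df[1L], df[2L], lower.tail = FALSE),
       zero_residual = FALSE)
}
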