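# Brute-force oracles, independent of the package's code paths.

# two-sided binomial p by direct enumeration of outcome probabilities
oracle_binom_p <- function(k, n, p0) {
  probs <- vapply(0:n, function(i)
    choose(n, i) * p0^i * (1 - p0)^(n - i), numeric(1))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-07)])
}

# two-sided Fisher p by enumerating all 2x2 tables with the observed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  probs <- vapply(lo:hi, prob, numeric(1))
  sum(probs[probs <= prob(tab[1, 1]) * (1 + 1e-07)])
}

# independent BH step-up: sort, scale, cumulative minimum from the tail
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# exact Spearman permutation p-value for small n (enumerates all n! pairings)
oracle_spearman_exact_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  obs <- abs(cor(rank(x), rank(y)))
  rhos <- vapply(perms(y), function(yy) cor(rank(x), rank(yy)), numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}
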