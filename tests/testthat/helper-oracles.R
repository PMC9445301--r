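# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Fast-relaxing parameter set for mRNA-level checks: protein turnover is fast
# so the stationary burn-in stays short, leaving the mRNA statistics of the
# (1, 3, 40, 1) telegraph benchmark untouched.
fast_params <- function(k_on = 1, k_off = 3, k_tx = 40, d_m = 1, ...) {
  burst_params(k_on = k_on, k_off = k_off, k_tx = k_tx, d_m = d_m,
               k_p = 0.5, d_p = 1, ...)
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# choose(n_a + n_b, n_a) group assignments (no ties assumed).
enumerate_u_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(n_a))
  us <- apply(utils::combn(length(pooled), n_a), 2, u_stat)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Textbook Pearson correlation from raw summations.
pearson_by_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Noiseless Hill force-pCa record (with a passive point at pCa 9).
exact_hill_curve <- function(F_max = 30, pCa50 = 5.55, nH = 2.5,
                             pCa = c(9.0, 6.0, 5.9, 5.74, 5.6, 5.54, 5.4,
                                     5.24, 5.0, 4.6, 4.18),
                             passive = 0) {
  f <- F_max / (1 + 10^(nH * (pCa - pCa50))) + passive
  f[pCa >= 9.0] <- passive
  list(pCa = pCa, force = f)
}

# Monte-Carlo standard error of a sample variance (delta method on the 4th
# central moment).
se_of_variance <- function(x) {
  n <- length(x)
  m <- mean(x)
  sqrt(max(0, mean((x - m)^4) - var(x)^2 * (n - 3) / (n - 1)) / n)
}
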