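# Shared fixtures: small simulated cohorts, built in code at test time.

small_cohort <- function(seed = 7, n_cpgs = 2000, n_risk = 60, n_age = 120,
                         n_vcpg = 40, ...) {
  simulate_cohort(sim_config(
    n_cpgs = n_cpgs, n_risk = n_risk, n_age = n_age, n_vcpg = n_vcpg,
    seed = seed, ...
  ))
}

# Independent textbook-formula Bartlett oracle (k = 2), coded directly from
# the chi-square formula, separate from the package's vectorized path.
bartlett_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2; k <- 2
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - k)
  C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - k)) / (3 * (k - 1))
  stat <- ((N - k) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)) / C
  list(stat = stat, p = pchisq(stat, df = k - 1, lower.tail = FALSE))
}

# Brute-force hypergeometric one-tailed enrichment p: enumerate the tail.
fisher_oracle_p <- function(a, b, c_, d) {
  n_cat <- a + c_
  n_sel <- a + b
  n_tot <- a + b + c_ + d
  ks <- a:min(n_cat, n_sel)
  sum(vapply(ks, function(k) {
    choose(n_cat, k) * choose(n_tot - n_cat, n_sel - k) / choose(n_tot, n_sel)
  }, numeric(1)))
}

# Exact two-sided binomial skew by full enumeration (doubled smaller tail).
binom_oracle_p <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# O(n^2) pair-counting AUC oracle (ties count one half).
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (i in seq_along(sp)) {
    tot <- tot + sum(sp[i] > sn) + 0.5 * sum(sp[i] == sn)
  }
  tot / (length(sp) * length(sn))
}
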