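# Independent oracles used to cross-check package implementations.

# Brute-force Benjamini-Hochberg step-up: q_(k) = min_{j >= k} n p_(j) / j,
# computed directly from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (k in seq_len(n)) {
    q[k] <- min(1, min(n * ps[k:n] / (k:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (probability-ordering rule).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small-cohort factory with per-session caching so multiple test files can
# share one generated cohort.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, config) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, generate_cohort(config), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

null_config <- function(n_subjects = 100, n_probes = 2000, seed = 1) {
  cohort_config(
    n_subjects = n_subjects, n_probes = n_probes,
    trajectory = list(n_per_class = 0, d14 = 0, d90 = 0),
    n_ti_probes = 0, n_sex_probes = 0,
    mediation = list(n_triplets = 0, a = 0, b = 0, c_prime = 0,
                     noise1 = 0.3),
    variance_fractions = c(methylation = 0, metabolites = 0, proteins = 0,
                           genetics = 0),
    seed = seed
  )
}

small_cohort <- function() {
  cached_cohort("small", cohort_config(n_subjects = 60, n_probes = 200,
                                       seed = 101))
}
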