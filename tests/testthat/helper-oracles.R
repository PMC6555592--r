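# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately brute-force and share no code with the package.

# BH step-up by direct enumeration of the rule:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(vapply(i:m, function(j) min(1, m * ps[j] / j), 0))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail P(X >= k) over all C(N, n) draws
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "marked" population
  mean(hits >= k)
}

# Monte-Carlo critical value of the Dunnett max-|t| statistic for k
# balanced comparisons vs a shared control, n per group, alpha level
dunnett_crit_mc <- function(k, n, alpha = 0.05, reps = 50000, seed = 42) {
  set.seed(seed)
  df <- (k + 1) * (n - 1)
  maxt <- replicate(reps, {
    y <- matrix(rnorm((k + 1) * n), ncol = k + 1)
    means <- colMeans(y)
    s2 <- sum(apply(y, 2, function(col) sum((col - mean(col))^2))) / df
    max(abs(means[-1] - means[1]) / sqrt(s2 * 2 / n))
  })
  unname(quantile(maxt, 1 - alpha))
}

# small quick study configuration used across module tests
small_config <- function(seed = 11, ...) {
  defaults <- list(
    n_genes = 300,
    treatments = c("LPS", "Pentavac", "saline"),
    n_modules = 2, module_size_range = c(20, 25),
    n_biomarkers = 5, n_decoy_sets = 5, n_soluble_decoys = 10,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# the default-scale study is expensive; build it once per test run
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 101) {
  key <- paste0("study", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(sim_config(seed = seed))
  }
  .study_cache[[key]]
}

default_de <- function(seed = 101) {
  key <- paste0("de", seed)
  if (is.null(.study_cache[[key]])) {
    st <- default_study(seed)
    norm <- lapply(st$expression, quantile_normalize)
    .study_cache[[key]] <- run_de(norm, st$samples)
  }
  .study_cache[[key]]
}
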