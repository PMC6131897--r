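# Shared fixtures: cohorts are generated in code and cached per (seed, extra)
# so expensive full-size simulations are built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed, extra_normal_only = 0, n_samples = 1000,
                          genes_per_group = 100) {
  key <- paste(seed, extra_normal_only, n_samples, genes_per_group, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(
      sim_config(n_samples = n_samples, genes_per_group = genes_per_group,
                 extra_normal_only = extra_normal_only),
      seed = seed)
  .cohort_cache[[key]]
}

tiny_cohort <- function(seed = 1, n_samples = 200, genes_per_group = 10, ...) {
  simulate_cohort(sim_config(n_samples = n_samples,
                             genes_per_group = genes_per_group, ...),
                  seed = seed)
}

# eqtl_scan logs the purity-sign convention once per session; keep tests quiet
quiet_scan <- function(...) suppressMessages(eqtl_scan(...))

# step-up FDR oracle, written directly from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j  on the sorted p-values
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
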