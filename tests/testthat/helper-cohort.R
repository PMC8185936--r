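# Small shared fixtures, built in code at load time.

small_cohort <- function(n = 300, m = 20, seed = 11, ...) {
  simulate_cohort(cohort_config(n_samples = n, n_variants = m,
                                seed = seed, ...))
}

# deterministic toy design for regression tests
toy_design <- function(n, p, seed = 1) {
  set.seed(seed)
  cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
}
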