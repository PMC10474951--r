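## Independent oracles and small fixture builders used across the suite.

## O(m^2) brute-force Benjamini-Hochberg: for each p_i, q_i is the minimum
## over all p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  rank_le <- colSums(outer(p, p, "<="))   # for each j, #\{l : p_l <= p_j\}
  level <- m * p / rank_le
  vapply(seq_len(m), function(i) min(1, level[p >= p[i]]), numeric(1))
}

## Brute-force upper-tail hypergeometric: sum the exact mass over x >= k.
hyper_brute <- function(k, K, N, n) {
  xs <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

## Tiny null cohort (no mutation effect) for permutation machinery tests.
null_cohort <- function(seed = 1, n_patients = 60, n_features = 120) {
  sim <- simulate_cohort(sim_config(seed = seed, n_patients = n_patients,
                                    n_features = n_features, n_genes = 2,
                                    mutation_freqs = c(0.2, 0.3)))
  sim$cohort
}

## A fast DE engine for permutation-heavy tests: NB-GLM on a reduced
## feature panel is still the real engine, just on fewer features.
fast_engine <- function() de_engine_nbglm()
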