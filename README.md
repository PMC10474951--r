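# mirimpact

Permutation-calibrated assessment of how broadly a gene's somatic
mutations dysregulate a count-based transcriptome (miRNA sequencing counts
in the motivating application), plus aggregative survival prognosis for
the responsive feature set.  Written for computational cancer biologists
who have a somatic mutation table (MAF-style), a feature-by-sample raw
count matrix, and per-patient survival endpoints, and who want
"number of dysregulated features" to mean something comparable across
genes and cohorts.

## The statistics

For one cohort and one gene, patients split into mutant vs wild-type (a
*mutation context*, kept when both class frequencies exceed 5%).  A
negative binomial GLM (TMM offsets, 1-df LRT, BH adjustment) yields the DE
count *N* = #{q < 0.05}.  Because *N* inflates with sample size and class
balance even for random labels, *N* is referred to a permutation null
matched on the cohort and on the discrete frequency category
c ∈ {0.05, …, 0.50} nearest to min(f, 1−f): B = 1000 label permutations
with exactly round(c·n) mutants give null counts N*₁…N*_B, and

- empirical P = (#{N*_b ≥ N} + 1) / (B + 1), floored at ≈ .001;
- z = (N − μ*)/σ*;
- NB-modified P = P(X ≥ N) under a method-of-moments Negative Binomial
  fit (size μ*²/(σ*²−μ*), prob μ*/σ*²) to the null counts — the
  tie-resolving statistic used for significance calls.

Responsive sets are then tested for collective prognostic value: a
direction-adjusted mean z-score composite of log-CPM, its Cox
likelihood-ratio p-value s ∈ [0,1] as statistic, a permutation P that
re-selects directions inside every permutation (so selection bias is part
of the null), and a Beta-distribution approximation of the permuted
statistics for sub-floor resolution.  Hypergeometric over-representation
against user-supplied annotation sets (e.g. disease–miRNA maps) rounds out
the workflow.

## Worked example

Everything below is synthetic and reproducible — the simulator ships with
the package and doubles as the fixture generator for the test suite.

```r
library(mirimpact)

sim <- simulate_cohort(sim_config(
  seed = 3, n_patients = 100, n_features = 300,
  mutation_freqs = seq(0.1, 0.4, length.out = 10),
  effects = list(list(gene = 1, k = 60, log2fc = 1.5))))

co   <- sim$cohort
norm <- tmm_normalize(co$counts)
de   <- de_engine_nbglm()

ctx <- build_contexts(sim$mutations, co)
cx  <- ctx[[1]]                      # GENE01, the truly impacted gene
cx
#> mutation context SYNTH / GENE01: f = 0.100 (category 0.10), 10 mutant / 90 wild-type

null <- simulate_null(co, cx$category, B = 1000, seed = 5,
                      de = de, norm = norm)
null
#> permutation null (SYNTH, category 0.10): B = 1000, mean 0.3, sd 1.3 [nbinom fit]

assess_impact(cx, co, setNames(list(null), "0.10"), de = de, norm = norm)
#> impact SYNTH / GENE01: N = 65, p_emp = 0.000999, z = 50.47, p_nb = 3.98e-08 *
```

Reading the output: 65 features shifted with GENE01's mutation status,
against a null that produces 0.3 ± 1.3 false discoveries for random
10%/90% splits of this cohort — far beyond the permutation floor
(p_emp ≈ .001), with the NB-modified P resolving how far.  The trailing
`*` marks significance at α = 0.05, so this context would proceed to the
prognosis stage.  A null gene in the same cohort (e.g. `GENE02`) lands at
N near 0 and p_nb near 1.

The file-based pipeline wraps the same calls: `run_all(run_config(...))`
reads the mutation/counts/clinical TSVs, caches the per-category nulls,
writes `contexts.tsv`, `impact.tsv`, `prognosis.tsv`, `responsive.tsv`,
`enrichment.tsv`, an OncoPrint-style mutation table and a JSON manifest;
`summarize_results()` rebuilds cross-cohort summaries from those outputs.
A thin CLI lives at `inst/cli/mirimpact.R` (subcommands `simulate`,
`run-all`, `summarize`).

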