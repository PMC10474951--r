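Package: mirimpact
Title: Permutation-Based Assessment of Somatic Mutation Impact on miRNA
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how broadly a gene's somatic mutation status
    dysregulates a count-based feature transcriptome (miRNA sequencing
    counts in the motivating application) while controlling for sample
    size and class imbalance.  Gene-level nonsilent mutation status splits
    a cancer cohort into mutant and wild-type classes (a "mutation
    context"); the number of differentially expressed features is then
    referred to a mutation-frequency-matched permutation null
    distribution, yielding an empirical P-value, a Gaussian z-score, and a
    Negative-Binomial-approximated P-value that resolves ties below the
    permutation floor.  Responsive feature sets are further tested for
    aggregative prognostic value through a composite expression score with
    a built-in permutation procedure and a Beta-distribution
    approximation.  Includes a negative binomial GLM differential
    expression engine with TMM normalization, hypergeometric
    over-representation analysis against user-supplied annotation sets, a
    synthetic cohort simulator, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
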