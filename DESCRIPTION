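Package: synmito
Title: Synteny-Based Tests of Mitonuclear Gene Movement and Abundance on Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether nuclear genes encoding mitochondrially
    targeted proteins (mitonuclear, mt-N, genes) moved off a sex chromosome
    after its formation or were already scarce on the ancestral autosomes.
    Implements reciprocal-best-hit orthology with e-value and top-hit
    identity filters, collinear synteny-block chaining and 10 Mb block
    merging, classification of interchromosomal gene movements against a
    size-based null with an exact Freeman-Halton 2x3 test, mt-N abundance
    bias statistics with percentile bootstrap confidence intervals and exact
    2x2 tests, an exact two-tailed sign test across independent sex
    chromosomes, and a genome-evolution simulator (rearrangements plus
    single-gene movement with a truth log) that emits every input format the
    pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
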