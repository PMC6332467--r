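Package: mitoload
Title: Mitochondrial DNA Variant Load and Haplogroup Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association analysis of human mitochondrial DNA
    variation. Annotates single-nucleotide variants against an
    rCRS-coordinate mitochondrial genome using the vertebrate mitochondrial
    genetic code, assigns top-level haplogroups by marker matching, and
    computes per-individual pathogenicity-score variant loads (sums of
    MutPred-style scores over qualifying non-synonymous substitutions).
    Implements the accompanying statistical battery: exact 2x2 and r x c
    (Freeman-Halton) contingency-table tests with a Monte Carlo fallback,
    adjusted standardized residual post-hoc analysis with phi effect sizes,
    one-way ANOVA from raw data or printed summaries, Dunnett many-to-one
    comparisons against a shared control, and Bonferroni correction. A
    synthetic cohort generator with haplogroup-structured common variants
    and Poisson-distributed rare private variants supports calibration and
    power studies without access to real sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    multcomp,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
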