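---
title: "The mtDNA variant-load association model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mtDNA variant-load association model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoload)
```

## The model

Mitochondrial haplogroup association studies test whether deep common
variation of the mtDNA phylogeny is over- or under-represented in a
disease cohort. They are vulnerable to population stratification and to
the fact that most mildly deleterious variation is rare and sits at the
tips of the phylogeny. The variant-load model addresses this by scoring
each non-synonymous substitution with a pathogenicity probability
(a MutPred-style score in [0, 1]) and summarising each individual by

$$L = \sum_{v \,:\, s(v) > \tau} s(v),$$

the sum over the individual's qualifying variants: non-synonymous,
operationally homoplasmic, with score strictly above the threshold
$\tau$. Cohorts are then compared on $L$ (ANOVA and Dunnett many-to-one
comparisons) and on derived categorical summaries (carrier yes/no,
0/1/2+ carrier counts, combinations of common and rare qualifying
variants), alongside the classical haplogroup-distribution analysis.

`mitoload` implements the complete battery. Scores are always inputs:
the package never computes a pathogenicity score itself, it consumes a
table keyed by (position, alternate allele).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 0.5 | strict lower bound for a qualifying score ("above 0.5"); 0.7 is used as a stricter secondary threshold |
| `homoplasmy_cutoff` | 0.95 | minimum alternate-allele fraction for a variant to be treated as operationally homoplasmic |
| rarity bands | < 0.1 %, > 1 % | population-frequency bounds for *rare* and *common*; the band in between is *intermediate* |
| `mc_replicates` | 1e5 | Monte Carlo replicates for exact tests and Dunnett adjustment |

"Operationally homoplasmic" has no universal definition; 0.95 is a
common working cutoff for high-coverage short-read mtDNA data and is
configurable. Heteroplasmic variants are excluded from load computation
but deliberately **not** from the proven-pathogenic screen, which reports
carriers at any fraction (a heteroplasmic m.1555A>G is still worth
flagging).

The threshold comparison is strict (`score > 0.5`): a variant scoring
exactly 0.5 never qualifies. Intermediate-frequency variants count
towards the load (the load definition has no frequency filter) but are
dropped from the rare-versus-common contingency tables, which only use
the < 0.1 % and > 1 % bands; in the combination classification they are
grouped with common variants.

## Annotation

Variants are classified against a 16,569-bp rCRS-coordinate genome with
the vertebrate mitochondrial genetic code (TGA=Trp, ATA=Met,
AGA/AGG=Stop; NCBI table 2). Design choices:

* Coordinates are 1-based inclusive everywhere, matching "m." HGVS-style
  notation; 0-based half-open coordinates appear only in the BED export.
* Only single-nucleotide substitutions are accepted; indels and MNVs are
  rejected with an explicit error, because the load model is defined over
  amino-acid substitutions.
* Overlapping genes (ATP8/ATP6, ND4L/ND4) yield one consequence call per
  gene, but a substitution counts **once** downstream: scores are keyed
  by (position, alt), not by gene.
* MT-ND6 and other light-strand features are reverse-complemented before
  translation.
* Genes whose stop codon is completed by polyadenylation have 1–2
  trailing bases that belong to no complete codon; substitutions there
  are reported `untranslatable`, never guessed. Codons containing `N`
  are likewise untranslatable.

## Haplogroup assignment

Production classifiers walk the full Phylotree. The analysis here only
uses fifteen top-level labels, so `assign_haplogroup()` ranks labels by
the *fraction* of their defining markers present in the sample (fraction
rather than raw count, so marker-rich labels are not favoured), breaking
ties by matched count and then label order. This is documented as
non-equivalent to Phylotree-walking tools: back mutations and private
variants are ignored, and no sub-haplogroup resolution is attempted.
The packaged marker table is a synthetic stand-in (see below).

## The statistical battery

**Exact 2×2 test.** Two-sided p by the point-probability method: the sum
of hypergeometric probabilities of all margin-fixed tables no more
probable than the observed one. This matches the convention of the major
commercial statistics packages; the mid-p variant is intentionally not
offered. Computation is in log space; zero margins return p = 1 with a
degenerate flag.

**Freeman–Halton r×c test.** The same principle with multivariate
hypergeometric point probabilities. For two-column tables the number of
margin-fixed tables is first counted by polynomial convolution; when it
is at most `max_enumeration` the p-value is computed by exhaustive
recursive enumeration, otherwise tables are sampled with fixed margins
(Patefield's conditional-hypergeometric filling, via `r2dtable`) and the
add-one estimator $\hat p = (1 + \#\{\text{prob} \le \text{obs}\})/(1 + B)$
is reported with its standard error — the add-one form keeps $\hat p > 0$.
The "no more probable" comparison uses a 1e-9 relative tolerance so that
floating-point noise cannot misclassify tied tables. The total
probability over all enumerated tables is checked to equal 1 within 1e-9
in the test suite.

**Adjusted standardized residuals.** Per cell,
$r_{ij} = (O_{ij} - E_{ij}) / \sqrt{E_{ij}(1 - p_{i\cdot})(1 - p_{\cdot j})}$,
approximately standard normal under independence, with two-sided normal
p-values, per-cell $\varphi_{ij} = r_{ij}/\sqrt{N}$, and Bonferroni
correction over the number of rows tested. For 2×2 tables $|r_{ij}|$ is
identical in all four cells and equals the square root of the uncorrected
Pearson chi-square — an identity the tests exploit.

**ANOVA.** The summary form takes printed (n, mean, sd) triples and
recovers the exact decomposition ($SSB = \sum n_i(m_i - \bar m)^2$,
$SSW = \sum (n_i - 1) s_i^2$); the raw form summarises and delegates, so
the two are identical by construction and are cross-checked against
`oneway.test` in the suite. Note that an ANOVA recomputed from summaries
rounded to two decimals can differ from the raw-data analysis in the
second digit of p — with the published cohort summaries the
reconstruction gives p ≈ 0.080 where the raw-data analysis reported
0.096; both lead to the same inference.

**Dunnett comparisons.** With a shared control,
$t_i = (m_i - m_0)/\sqrt{MSE(1/n_i + 1/n_0)}$ with MSE pooled over all
groups. The family-wise two-tailed adjusted p-value
$p_i = P(\max_j |T_j| \ge |t_i|)$ is estimated by Monte Carlo from the
shared-control construction $T_j = (Z_j - Z_0)/(S\sqrt{1/n_j + 1/n_0})$,
which realises the equicorrelated multivariate t with
$\rho_{ij} = \sqrt{\lambda_i \lambda_j}$, $\lambda_i = n_i/(n_i+n_0)$,
and handles unbalanced designs (e.g. 100 vs 115) without any balanced
approximation. Each result records the replicate count, seed and Monte
Carlo standard error. The suite verifies the k = 1 reduction to the
pooled t-test, agreement with the `multcomp`/`mvtnorm` quadrature, and
that the α = 0.05 balanced critical value from `mvtnorm::qmvt` yields
family-wise rejection probability 0.05.

**Unique variants.** For the rare/common contingency builds, a variant
is *unique* when it occurs in exactly one of all cohorts in the run (not
merely one of the two compared), mirroring the "present exclusively in
each of the studied groups" construction; uniqueness is assessed after
the homoplasmy and non-synonymous filters. The order of those two
filters is a genuine open choice; filtering first keeps the uniqueness
definition aligned with what the load model actually uses.

## Synthetic data: what it emulates and what it does not

`generate_cohorts()` produces cohorts with the structure the analysis
assumes — by default three case cohorts of 100 and one control cohort of
115, the study's design:

* each sample draws a top-level haplogroup from the control cohort's
  published frequency vector and inherits all marker variants of that
  label, including the thirteen high-scoring common haplogroup-associated
  variants of the packaged score fixture;
* rare private variants are added per individual as Poisson(λ = 0.5)
  draws from the pool of all possible non-synonymous substitutions
  (fixture positions excluded, each rare variant private to one sample),
  with scores Beta(2, 2) rescaled to [0.3, 0.9] — a unimodal spread
  straddling the 0.5 threshold — and population frequencies below 0.1 %;
* `inject_effect()` gives each treated case sample, with probability π,
  one extra qualifying variant, so the expected mean load shift is
  π · E[score]; π = 0.22/0.6 with a constant score of 0.6 reproduces the
  published atherosclerosis-minus-control mean difference of 0.22.

All draws derive from one master seed through fixed substreams, so a
cohort's content does not depend on the other cohorts generated in the
same run.

What the generator does **not** emulate: phylogenetic tree structure
below the top-level labels, mutation-rate and site-specific realism,
back mutations, heteroplasmy drift, or linkage between rare variants and
haplogroup background. Passing tests on synthetic data therefore
demonstrate correctness of the computational pipeline and calibration of
the tests under the generator's assumptions — not that the biological
claims transfer to any real cohort.

The packaged genome (`mt_genome_synthetic.fasta`) is itself a synthetic
stand-in: real rCRS gene coordinates, random non-stop codons elsewhere,
with the codons of the thirteen scored variants set to the amino-acid
contexts in which those substitutions are non-synonymous. It is built
deterministically by `data-raw/make_genome.R`. The marker table is
likewise synthetic: three unique control-region markers per label plus
the scored variants attached to plausible labels. Neither file is a
substitute for the real rCRS record or Phylotree when analysing real
data; both are declared via their file names and documentation.

## Numerical choices and degenerate inputs

* Exact-test tie comparison: 1e-9 relative tolerance in log space;
  log-factorials throughout, no large-integer arithmetic needed.
* Monte Carlo p-values use the add-one estimator and report standard
  errors; seeds are recorded in every result object, and the global RNG
  state of the caller is restored after every randomized call.
* Zero row/column margins: 2×2 test returns p = 1 flagged degenerate;
  r×c tests drop zero margins (they carry no information) and flag the
  result; residual cells in zero margins are NA.
* All-zero within-group variance in ANOVA yields a degenerate flag with
  NA p rather than an arbitrary F.
* Ties in haplogroup ranking break deterministically (fraction, then
  matched count, then lexicographic label), so calls are reproducible
  regardless of input order.

## Problem sizes used in the checks

The suite runs the exhaustive annotation oracle on toy genomes of ~70 bp
(all 3L substitutions), enumerates exact tests on 3×2 tables with N
around 200, uses 1e5 Monte Carlo replicates for the 15×2 tables and the
Dunnett adjustment, 1000 replicate cohort pairs at study size
(100 vs 115) for type-I calibration, and 60 + 60 replicate four-cohort
runs for the Dunnett power comparison. These sizes were chosen so each
statistical property is measured with a 3-standard-error margin.

## Known limitations

* Haplogroup calls are top-level only and not comparable to
  Phylotree-walking classifiers on real data.
* The r×c "exact test statistic" printed by some commercial packages
  (distinct from the p-value) has no published definition and is not
  reproduced; only p-values are.
* Heteroplasmy is reduced to a single allele-fraction cutoff; no
  quantitative heteroplasmy modelling.
* No FDR procedures: the battery applies Bonferroni only, matching the
  analysis it implements.
* Variant input is limited to single-nucleotide substitutions.
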