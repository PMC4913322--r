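---
title: "Scoring oncogene and tumor suppressor candidates from five data types"
author: "omicprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring oncogene and tumor suppressor candidates from five data types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicprio)
```

## The model

`omicprio` prioritizes candidate cancer genes by counting, per gene and
cancer type, in how many of five data types the gene shows an
*activating* or an *inactivating* aberration when tumors are compared
with tissue-matched normal samples.  Writing $a_g$ for the number of
data types with an activating call and $i_g$ for the inactivating
count,

$$\mathrm{OG}_g = a_g,\qquad \mathrm{TS}_g = i_g,\qquad
\mathrm{overall}_g = a_g - i_g,\qquad \mathrm{aberration}_g = a_g + i_g,$$

so a gene altered in one data type contributes exactly one score unit,
all data types are weighted equally, a positive overall score reads
"oncogene-like" and the aberration score measures total evidence
regardless of direction.  The design deliberately favors genes aberrated
in several data types over genes with a single strong signal: a gene
that is only, say, frequently mutated will never exceed an aberration
score of 1.

The per-data-type calls are:

* **Expression.** Paired Wilcoxon signed-rank test per gene, tumor
  versus matched normal, Benjamini–Hochberg (BH) across all tested
  genes.  Significantly higher expression (q < 0.05) is activating,
  lower is inactivating; the direction is the sign of the mean paired
  difference.
* **Copy number.** Same paired test on gene-level log-ratios (segmented
  input is lifted to genes by overlap-length-weighted means).  Three
  conditions must hold: q < 0.05; absolute mean tumor−normal difference
  strictly greater than 0.1 log-ratio units (this keeps minute shifts in
  large cohorts from becoming "significant"); and, among genes passing
  both, a significantly *positive* Spearman correlation between copy
  number and the gene's expression across tumor samples (BH across that
  gene set).  Gains are activating, losses inactivating.  A dosage
  change that expression does not follow is treated as a passenger.
* **Methylation.** Probe-wise unpaired rank-sum tests (tumor and normal
  methylation cohorts usually overlap imperfectly), BH across probes,
  with a strict 0.1 mean beta-difference gate.  For each eligible
  probe–gene link the Spearman correlation between probe beta and gene
  expression across tumors is computed (BH across eligible links).  The
  gene-body/other distinction then decides direction: body probes that
  gain methylation and correlate positively with expression are
  activating evidence, body probes that lose methylation with positive
  correlation are inactivating; probes in any other context act in the
  mirrored directions with negative correlation.  A gene needs only one
  qualifying probe per flag, and different probes may set both flags.
* **Mutations.** A 20/20-rule classification: missense and in-frame
  indels are oncogene-type, truncating and splice-site mutations
  tumor-suppressor-type.  With $d_{og}$ distinct oncogene-type changes
  (keyed on chromosome, position, alleles and class) among $n$ total
  recorded mutations, the oncogene mutation rate is
  $\mathrm{OGMR} = 1 - d_{og}/n$ (high when activating mutations recur
  at few sites) and $\mathrm{TSMR} = d_{ts}/n$ (high when truncating
  mutations are spread out).  A gene is activating when
  OGMR > 0.2 and TSMR < 0.05, inactivating when TSMR > 0.2 or
  (OGMR > 0.2 and TSMR > 0.05); each flag additionally requires at
  least five mutations of its class.  The two flags cannot co-occur.
* **shRNA screens.** Per gene, the 25th/75th percentiles of its
  knock-down viability across *all* screened cell lines define reference
  quartiles.  If at least a quarter of one cancer type's lines fall
  strictly below the lower quartile the gene is activating evidence for
  that type (its knock-down hurts those lines); at least a quarter
  strictly above the upper quartile is inactivating.  Only genes with a
  single "gene solution" are used.

Downstream, cards aggregate into pathway scores (means of overall
scores over the pathway members that were scored; unmeasured members
are excluded, not imputed as zero), affected-sample fractions (a tumor
sample is affected when its tumor−normal difference lies strictly more
than one sample SD from the mean of the difference distribution), and
cohort comparisons (Pearson correlation of two pathway-score vectors,
e.g. tumors versus cell lines).  Dual-role genes are those with
OG ≥ 2 in one cancer type and TS ≥ 2 in a *different* one.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `fdr_threshold` | FDR | 0.05 | operating point of every BH stage |
| `min_cn_diff` | log-ratio | 0.1 (strict >) | effect-size floor for CN calls |
| `min_beta_diff` | beta | 0.1 (strict >) | effect-size floor for methylation |
| `min_class_count` | mutations | 5 | minimum class evidence for a 20/20 flag |
| `min_fraction` | fraction | 0.25 (inclusive ≥) | shRNA quarter-of-lines rule |
| `min_pairs` | pairs | 3 | below this a gene is unavailable, not tested |

The inequality conventions are part of the contract: the effect gates
are strict ("larger than 0.1"), the shRNA fraction threshold is
inclusive ("at least 25%") while its percentile comparisons are strict
("lower/greater than the percentile"), and the affected-sample rule is
strict ("more than one standard deviation").  The boundary fixtures in
`boundary_fixture()` probe each of these on exact grids, and the test
suite asserts that the recovered decision boundaries sit exactly at the
printed values.

## Statistical engine

The rank tests are self-contained.  Both Wilcoxon tests use the exact
conditional permutation distribution — computed by a shift-distribution
dynamic program over doubled mid-ranks, which handles ties without
special cases — whenever the effective sample size is at most 49, and a
tie-corrected normal approximation (no continuity correction) above.
The crossover follows the convention of R's `wilcox.test`, and it
matters scientifically: cohorts of a few dozen pairs are common, and at
n = 20 a uniformly positive difference vector has exact two-sided
p = 2·2⁻²⁰ ≈ 1.9×10⁻⁶, while the normal approximation saturates around
10⁻⁴ — the difference between surviving and missing a genome-wide BH
correction at rank 1.  Near the crossover the two paths agree to well
under 0.02 in two-sided p (asserted on random instances in the test
suite).  Degenerate cases are defined, not errors: all-zero paired
differences give p = 1 and direction 0; a constant vector makes
Spearman's rho undefined and the result is flagged degenerate, which
downstream scoring treats as "no significant correlation".

Spearman correlations use Pearson on mid-ranks, with the full n!
permutation null enumerated for n ≤ 8 and the t approximation above.
BH adjustment wraps `stats::p.adjust(method = "BH")` with validation
and NA pass-through (missing entries do not count as tests); the
hand-applied step-up formula serves as the independent oracle in the
tests.  Quantiles are linear-interpolation ("type 7") throughout.

Two staging choices deserve a note because the procedure is
order-sensitive.  The correlation-stage BH for copy number and
methylation runs across only the genes/links that passed the
difference filter, reflecting the conditional phrasing of the
procedure ("for genes with significant difference … we calculated the
correlation").  And the 0.1 gates are applied after testing but before
the correlation stage; since both the gate and the q-threshold must
hold, their order does not change which genes pass both.

## Cohort preprocessing

Recurrent and metastatic samples are dropped so that every analysis
compares primary tumors with normals; if a patient has several primary
samples, *all* of that patient's samples are removed (no principled way
to choose a representative exists).  The operation is idempotent, and
scoring functions refuse sample maps that have not passed it.
Correlation stages use all tumor samples carrying both measurements,
not only the paired ones.  Methylation probes annotated to several
genes are evaluated once per (probe, gene, region) link; probe contexts
are collapsed to a binary body/other distinction because the scoring
rules only distinguish those two.

## The synthetic cohort generator

`generate_cohort()` draws a complete input bundle with known truth.
The reference design — 1000 genes, 50 tumor/normal pairs, 20 planted
oncogenes and 20 planted tumor suppressors with large effects in four
data types (expression, copy number, methylation, mutations), plus a
100-line shRNA screen — mirrors the scale at which the method's
decision thresholds operate while keeping a full pipeline run in
seconds.  Noise models: Gaussian for expression, copy number and
viability; logit-normal (hence bounded in [0, 1] by construction) for
beta values; Poisson background mutations at distinct sites.  Planted
effects are coupled the way the scorers expect real biology to be
coupled: tumor-side copy-number deviations feed into tumor expression,
and planted body-probe betas share a latent term with standardized
tumor expression, so the correlation stages see strong positive
associations.  Planted effect sizes (2 noise-SD expression shift, 0.5
log-ratio CN shift, 0.25 beta shift, 10 recurrent missense / 8 distinct
nonsense mutations, 3-SD viability displacement) are chosen to sit far
from every gate, because the generator's job in validation is parameter
*recovery*, not power estimation.

On this cohort, genes with aberration score ≥ 3 recover the planted
drivers with precision and recall ≥ 0.9 (in practice 1.0), and null
cohorts produce no gene at score ≥ 3 across seeds — both asserted in
the test suite.

What the generator does **not** emulate: genomic linkage (no shared
arm-level segments between neighboring genes — every gene's copy number
is independent), platform batch effects (inputs are assumed
pre-harmonized; batch correction is out of scope), probe-level
cross-reactivity, subclonality, and realistic mutation spectra.
Passing the recovery tests therefore demonstrates that the scoring
machinery implements its decision rules correctly at realistic scale,
not that the method has any particular sensitivity or specificity on
real tumor cohorts, where effect sizes are smaller and correlated
structure can inflate per-data-type calls.

A related caveat visible even on synthetic data: with a 20-line cancer
type and exchangeable viability, the expected fraction of lines beyond
a global quartile is exactly 25%, so isolated shRNA flags arise by
chance for roughly half of all null genes.  The shRNA rule is
deliberately lenient; specificity comes from the aggregation across
data types, which is why validation thresholds on the aberration score
rather than on single flags.

## Numerical choices

* Exact binary boundary fixtures: the 0.1-gate probes add a zero-mean
  jitter whose values are exact multiples of 2⁻²⁰, so the shifted
  group's mean is bit-exactly the nominal shift and the strict `>`
  comparison at 0.1 is well defined rather than an accident of rounding.
* Standard deviations use the n−1 denominator everywhere.
* The affected-sample and quantile rules are deterministic; ties in
  rankings of genes are broken alphabetically so reruns are
  byte-identical (asserted in the tests).
* OGMR equals 1 for a gene with zero oncogene-type mutations — a direct
  consequence of the defining formula; the five-mutation class gate is
  what prevents spurious oncogene calls in that situation.
* The mutation-rate denominator counts *all* recorded mutations for the
  gene, including `other`-class records such as silent changes.
* Features with fewer than three complete tumor/normal pairs are marked
  unavailable instead of erroring, so sparse genes degrade gracefully.

## Known limitations

* Copy-number and methylation calls require expression data: the
  correlation condition is mandatory, so a gene absent from the
  expression matrix cannot receive those flags (it is reported
  unavailable).  This is a faithful reading of the procedure, not an
  implementation shortcut.
* The mutation model keys distinctness on genomic change, not protein
  change, because only the genomic MAF columns are consumed.
* No positional clustering statistic beyond recurrence (distinct versus
  total counts) is computed.
* Pathway scores average only scored genes; pathways dominated by
  unmeasured genes rest on few members (`n_genes_scored` and
  `n_missing` are reported so this is visible).
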