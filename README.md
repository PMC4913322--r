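# omicprio

Multi-omics prioritization of candidate oncogenes and tumor suppressor
genes.

Most driver-gene methods lean on somatic mutations alone, which misses
genes that tumors deregulate through dosage, methylation or expression
without mutating them.  `omicprio` scores **every gene, per cancer
type**, by counting in how many of five data types it carries an
activating or an inactivating aberration relative to tissue-matched
normal samples:

| data type | activating call | inactivating call |
|---|---|---|
| mRNA expression | significantly up in tumors (paired Wilcoxon, BH q < 0.05) | significantly down |
| DNA copy number | gain with mean shift > 0.1 and CN–expression Spearman ρ > 0 (q < 0.05) | loss, same conditions |
| DNA methylation | ≥ 1 probe: body probe up + positive β–expression correlation, or other probe down + negative correlation | mirrored criteria |
| somatic mutations | 20/20 rule: OGMR > 0.2 and TSMR < 0.05, ≥ 5 oncogene-class mutations | TSMR > 0.2 (or OGMR > 0.2 and TSMR > 0.05), ≥ 5 TS-class mutations |
| shRNA knock-down | ≥ 25% of the type's cell lines below the gene's global 25th viability percentile | ≥ 25% above the 75th percentile |

With `a` activating and `i` inactivating data types per gene,

```
OG score = a        TS score = i
overall  = a − i    aberration = a + i
```

so each data type contributes at most one score unit per direction,
positive overall scores read "oncogene-like", and the aberration score
measures total evidence.  Here OGMR = 1 − (distinct oncogene-type
mutations)/(total mutations) is high for recurrently hit sites and
TSMR = (distinct truncating mutations)/(total mutations) is high for
broadly distributed truncations.  On top of the per-gene cards the
package computes pathway scores (mean overall score of scored members),
affected-sample fractions (strict one-SD rule on tumor−normal
differences), dual-role genes (OG ≥ 2 in one cancer type, TS ≥ 2 in
another) and tumor-versus-cell-line comparisons (Pearson correlation of
pathway-score vectors).

Inputs are plain text: TSV feature×sample matrices, SEG segments
(mapped to genes by overlap-weighted means), a MAF column subset, GMT
gene sets, and TSV sample/probe/cell-line annotations.  A seeded
synthetic-cohort generator with planted drivers
(`generate_cohort()`) and deterministic threshold-probing fixtures
(`boundary_fixture()`) are part of the package.

## Worked example

Score a synthetic cohort with 20 planted oncogenes and 20 planted tumor
suppressors (1000 genes, 50 tumor/normal pairs, effects in four data
types):

```r
library(omicprio)

bundle <- generate_cohort(cohort_spec(seed = 1))
res <- score_cohort(bundle$cancer_type, bundle$sample_map,
                    expr_tumor = bundle$expr_tumor,
                    expr_normal = bundle$expr_normal,
                    cn_tumor  = bundle$cn_tumor,  cn_normal  = bundle$cn_normal,
                    meth_tumor = bundle$meth_tumor,
                    meth_normal = bundle$meth_normal,
                    probe_annotation = bundle$probe_annotation,
                    mutations = bundle$mutations)
cards <- res$cards

cards[match(rank_genes(cards, "overall")[1:5], cards$gene),
      c("gene", "og_score", "ts_score", "overall_score", "aberration_score")]
#>   gene og_score ts_score overall_score aberration_score
#>  G0129        4        0             4                4
#>  G0187        4        0             4                4
#>  G0270        4        0             4                4
#>  G0277        4        0             4                4
#>  G0299        4        0             4                4

table(role = merge(cards, bundle$truth)$role,
      score = merge(cards, bundle$truth)$aberration_score)
#>                   score
#> role                 0   1   3   4
#>   null             955   5   0   0
#>   oncogene           0   0   1  19
#>   tumor_suppressor   0   0   0  20
```

The top-ranked genes are planted oncogenes flagged in all four supplied
data types (score 4 = one unit per data type).  Every planted gene
reaches aberration score ≥ 3 while no null gene exceeds 1 — the handful
of null genes at score 1 are single-data-type false positives at the
nominal FDR, which the multi-evidence aggregation screens out.  Pathway
scores summarize the same cards:

```r
pathway_scores(cards, list(
  planted_og = bundle$truth$gene[bundle$truth$role == "oncogene"],
  random     = bundle$truth$gene[5:24]))
#>  pathway_id mean_overall n_genes_scored n_missing
#>  planted_og         3.95             20         0
#>      random         0.00             20         0
```

A thin command-line wrapper is installed with the package
(`inst/scripts/omicprio`), with subcommands `score`, `pathways`,
`compare` and `simulate` exposing the same functions with the default
thresholds as flags.

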