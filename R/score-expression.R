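#' Score differential expression between tumors and matched normals
#'
#' Per gene, a paired Wilcoxon signed-rank test of tumor versus matched
#' normal expression; nominal p-values are Benjamini-Hochberg adjusted
#' across all tested genes.  A gene significantly higher in tumors
#' (q below the FDR threshold, positive mean paired difference) is flagged
#' activating; significantly lower, inactivating.  Genes with fewer than
#' `min_pairs` complete pairs are marked unavailable rather than tested.
#'
#' @param cohort A [paired_cohort()] with expression matrices.
#' @param cfg A [scoring_config()].
#' @param min_pairs Minimum complete tumor/normal pairs per gene.
#' @return An [aberration_calls()] data frame (`data_type = "expression"`)
#'   with supporting columns `p`, `q`, `effect` (mean tumor-normal
#'   difference) and `n_pairs`.
#' @export
score_expression <- function(cohort, cfg = scoring_config(),
                             min_pairs = 3L) {
  stopifnot(inherits(cohort, "paired_cohort"))
  res <- paired_gene_tests(cohort, min_pairs)
  q <- bh_adjust(res$p)
  hit <- res$available & !is.na(q) & q < cfg$fdr_threshold
  activating <- hit & res$effect > 0
  inactivating <- hit & res$effect < 0
  aberration_calls(res$gene, "expression", activating, inactivating,
                   res$available,
                   stats = data.frame(p = res$p, q = q, effect = res$effect,
                                      n_pairs = res$n_pairs))
}

# shared by expression and copy-number scoring: per-gene paired
# signed-rank tests over the cohort's matched columns
paired_gene_tests <- function(cohort, min_pairs = 3L) {
  tum <- cohort$tumor$values[, cohort$pairs$tumor_sample, drop = FALSE]
  nor <- cohort$normal$values[, cohort$pairs$normal_sample, drop = FALSE]
  genes <- rownames(tum)
  n <- length(genes)
  p <- rep(NA_real_, n)
  effect <- rep(NA_real_, n)
  n_pairs <- integer(n)
  available <- logical(n)
  for (i in seq_len(n)) {
    ti <- tum[i, ]
    ni <- nor[i, ]
    ok <- !(is.na(ti) | is.na(ni))
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] < min_pairs) next
    available[i] <- TRUE
    tst <- wilcoxon_signed_rank(ti[ok], ni[ok])
    p[i] <- tst$p_two_sided
    effect[i] <- mean(ti[ok] - ni[ok])
  }
  list(gene = genes, p = p, effect = effect, n_pairs = n_pairs,
       available = available)
}
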