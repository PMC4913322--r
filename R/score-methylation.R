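#' Score DNA methylation aberrations probe-wise
#'
#' Works at the probe level and lifts calls to genes through the probe
#' annotation.  Per probe: an unpaired rank-sum test of tumor versus
#' normal beta values, BH-adjusted across all tested probes; a probe is
#' eligible only if its q-value is below the FDR threshold and the
#' absolute mean beta difference exceeds the 0.1 gate (strict).  For each
#' eligible probe-gene link whose gene has expression data, the Spearman
#' correlation between probe beta and gene expression is computed across
#' the tumor samples shared by both matrices, with BH across eligible
#' links; a link counts only when its correlation q-value is below the
#' threshold.
#'
#' Gene-level flags follow the region-aware rules: a gene is flagged
#' *inactivating* (tumor-suppressor-like) if at least one probe is (1) in
#' the gene body, significantly lower in tumors and positively correlated
#' with expression, or (2) in any other context, significantly higher in
#' tumors and negatively correlated with expression.  It is flagged
#' *activating* under the mirror image: (1) body probe higher in tumors
#' with positive correlation, or (2) other probe lower in tumors with
#' negative correlation.  The two flags are independent and may co-occur
#' when different probes support each.
#'
#' @param tumor_meth,normal_meth `omics_matrix` objects with tag
#'   `"methylation"` (probes x samples).
#' @param annot A [probe_annotation()]; probes absent from it are
#'   ignored, links to genes missing from `tumor_expr` are skipped.
#' @param tumor_expr `omics_matrix` of tumor expression.
#' @param cfg A [scoring_config()].
#' @param min_per_group Minimum non-missing samples per group for the
#'   probe test.
#' @return [aberration_calls()] (`data_type = "methylation"`).  The
#'   supporting columns report, per gene, the triggering probe
#'   (`probe_act` / `probe_inact`) and link-level statistics are attached
#'   as the `links` attribute.
#' @export
score_methylation <- function(tumor_meth, normal_meth, annot, tumor_expr,
                              cfg = scoring_config(), min_per_group = 3L) {
  stopifnot(inherits(tumor_meth, "omics_matrix"),
            inherits(normal_meth, "omics_matrix"),
            inherits(annot, "probe_annotation"),
            inherits(tumor_expr, "omics_matrix"))
  probes <- intersect(feature_ids(tumor_meth), feature_ids(normal_meth))
  probes <- probes[probes %in% annot$probe_id]

  p <- rep(NA_real_, length(probes))
  effect <- rep(NA_real_, length(probes))
  names(p) <- names(effect) <- probes
  for (pr in probes) {
    tv <- tumor_meth$values[pr, ]
    nv <- normal_meth$values[pr, ]
    tv <- tv[!is.na(tv)]
    nv <- nv[!is.na(nv)]
    if (length(tv) < min_per_group || length(nv) < min_per_group) next
    tst <- wilcoxon_rank_sum(tv, nv)
    p[pr] <- tst$p_two_sided
    effect[pr] <- mean(tv) - mean(nv)
  }
  q <- bh_adjust(p)
  eligible <- !is.na(q) & q < cfg$fdr_threshold &
    abs(effect) > cfg$min_beta_diff

  # probe-gene links whose probe was tested and whose gene has expression
  links <- annot[annot$probe_id %in% probes, , drop = FALSE]
  links <- links[links$gene %in% feature_ids(tumor_expr), , drop = FALSE]
  links <- as.data.frame(links)
  links$p_probe <- p[links$probe_id]
  links$q_probe <- q[links$probe_id]
  links$effect <- effect[links$probe_id]
  links$eligible <- eligible[links$probe_id]
  links$rho <- rep(NA_real_, nrow(links))
  links$p_rho <- rep(NA_real_, nrow(links))

  shared <- intersect(sample_ids(tumor_meth), sample_ids(tumor_expr))
  for (j in which(links$eligible)) {
    bv <- tumor_meth$values[links$probe_id[j], shared]
    ev <- tumor_expr$values[links$gene[j], shared]
    ok <- !(is.na(bv) | is.na(ev))
    if (sum(ok) < 3L) next
    sp <- spearman_cor(bv[ok], ev[ok])
    if (!sp$degenerate) {
      links$rho[j] <- sp$rho
      links$p_rho[j] <- sp$p_two_sided
    }
  }
  links$q_rho <- bh_adjust(links$p_rho)
  corr_sig <- !is.na(links$q_rho) & links$q_rho < cfg$fdr_threshold

  body <- links$region == "body"
  up <- links$effect > 0
  pos <- !is.na(links$rho) & links$rho > 0
  neg <- !is.na(links$rho) & links$rho < 0
  links$ts_hit <- links$eligible & corr_sig &
    ((body & !up & pos) | (!body & up & neg))
  links$og_hit <- links$eligible & corr_sig &
    ((body & up & pos) | (!body & !up & neg))

  genes <- sort(unique(links$gene))
  tested_probe <- !is.na(links$p_probe)
  available <- vapply(genes, function(g) {
    any(tested_probe[links$gene == g])
  }, logical(1L))
  activating <- vapply(genes, function(g) {
    any(links$og_hit[links$gene == g])
  }, logical(1L))
  inactivating <- vapply(genes, function(g) {
    any(links$ts_hit[links$gene == g])
  }, logical(1L))
  probe_of <- function(g, hit) {
    i <- which(links$gene == g & hit)
    if (length(i)) links$probe_id[i[1L]] else NA_character_
  }
  probe_act <- vapply(genes, probe_of, character(1L), hit = links$og_hit)
  probe_inact <- vapply(genes, probe_of, character(1L), hit = links$ts_hit)

  out <- aberration_calls(genes, "methylation", activating, inactivating,
                          available,
                          stats = data.frame(probe_act = probe_act,
                                             probe_inact = probe_inact,
                                             stringsAsFactors = FALSE))
  attr(out, "links") <- links
  out
}
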