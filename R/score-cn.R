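#' Map copy-number segments onto genes
#'
#' Produces a gene-level copy-number matrix from segmented data: for each
#' gene and sample, the overlap-length-weighted mean of `seg_mean` over
#' all segments intersecting the gene's interval.  Genes with no
#' overlapping segment in a sample are missing there.  Coordinates are
#' 1-based inclusive (SEG convention).
#'
#' @param seg Data frame from [read_seg()] (`sample`, `chrom`, `start`,
#'   `end`, `seg_mean`).
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @return An `omics_matrix` with tag `"cna"` (genes x samples).
#' @export
map_segments_to_genes <- function(seg, genes) {
  req <- c("gene", "chrom", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss)) {
    stop("gene intervals missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    stop("malformed gene interval: end < start", call. = FALSE)
  }
  if (any(seg$end < seg$start)) {
    stop("malformed SEG interval: end < start", call. = FALSE)
  }
  # shared seqlevel universe so per-sample chromosome gaps are ordinary
  # no-overlap cases
  chroms <- union(unique(genes$chrom), unique(seg$chrom))
  gr_genes <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = chroms),
    IRanges::IRanges(genes$start, genes$end))
  samples <- unique(seg$sample)
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene, samples))
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    gr_seg <- GenomicRanges::GRanges(
      factor(ss$chrom, levels = chroms),
      IRanges::IRanges(ss$start, ss$end))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(
      IRanges::pintersect(gr_genes[qh], gr_seg[sh]))
    wsum <- tapply(w, qh, sum)
    vsum <- tapply(w * ss$seg_mean[sh], qh, sum)
    idx <- as.integer(names(wsum))
    out[idx, s] <- as.numeric(vsum) / as.numeric(wsum)
  }
  omics_matrix(out, "cna")
}

#' Score copy-number aberrations
#'
#' A gene is copy-number aberrated only if three conditions hold: (1) its
#' copy-number log-ratio differs significantly between tumors and matched
#' normals (paired signed-rank test, BH-adjusted q below the FDR
#' threshold); (2) the absolute mean tumor-normal difference exceeds the
#' 0.1 log-ratio gate (strict), which keeps tiny shifts from reaching
#' significance in large cohorts; and (3) among the genes passing both,
#' copy number is significantly positively Spearman-correlated with the
#' gene's expression across tumor samples (BH across that set, q below
#' the threshold, rho > 0).  Gains are activating, losses inactivating.
#' Genes absent from the expression matrix cannot satisfy the correlation
#' requirement and are marked unavailable.
#'
#' @param cohort A [paired_cohort()] of copy-number matrices.
#' @param tumor_expr `omics_matrix` of tumor expression; correlations use
#'   all tumor samples present in both matrices.
#' @param cfg A [scoring_config()].
#' @param min_pairs Minimum complete pairs per gene.
#' @return [aberration_calls()] (`data_type = "cna"`) with columns `p`,
#'   `q`, `effect`, `rho`, `p_rho`, `q_rho`.
#' @export
score_copy_number <- function(cohort, tumor_expr, cfg = scoring_config(),
                              min_pairs = 3L) {
  stopifnot(inherits(cohort, "paired_cohort"),
            inherits(tumor_expr, "omics_matrix"))
  res <- paired_gene_tests(cohort, min_pairs)
  genes <- res$gene
  in_expr <- genes %in% feature_ids(tumor_expr)
  available <- res$available & in_expr
  q <- bh_adjust(ifelse(available, res$p, NA_real_))
  pass <- available & !is.na(q) & q < cfg$fdr_threshold &
    abs(res$effect) > cfg$min_cn_diff

  rho <- rep(NA_real_, length(genes))
  p_rho <- rep(NA_real_, length(genes))
  shared <- intersect(sample_ids(cohort$tumor), sample_ids(tumor_expr))
  for (i in which(pass)) {
    cn_v <- cohort$tumor$values[genes[i], shared]
    ex_v <- tumor_expr$values[genes[i], shared]
    ok <- !(is.na(cn_v) | is.na(ex_v))
    if (sum(ok) < 3L) next
    sp <- spearman_cor(cn_v[ok], ex_v[ok])
    if (!sp$degenerate) {
      rho[i] <- sp$rho
      p_rho[i] <- sp$p_two_sided
    }
  }
  q_rho <- bh_adjust(p_rho)
  corr_ok <- !is.na(q_rho) & q_rho < cfg$fdr_threshold & !is.na(rho) & rho > 0
  activating <- pass & corr_ok & res$effect > 0
  inactivating <- pass & corr_ok & res$effect < 0
  aberration_calls(genes, "cna", activating, inactivating, available,
                   stats = data.frame(p = res$p, q = q, effect = res$effect,
                                      rho = rho, p_rho = p_rho,
                                      q_rho = q_rho, n_pairs = res$n_pairs))
}
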