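#' Run all available scorers for one cancer type
#'
#' The per-cancer-type driver: deduplicates the sample map, builds paired
#' cohorts for expression and copy number, runs whichever scorers have
#' inputs, and aggregates the calls into score cards.  At least one data
#' type must be provided; with partial availability the remaining data
#' types simply do not contribute and `n_data_types_available` records the
#' mask.  Methylation matrices and the mutation table are restricted to
#' samples present in the (deduplicated) map.
#'
#' @param cancer_type Cohort label stamped on the cards.
#' @param sample_map A [sample_map()] (deduplicated or not).
#' @param expr_tumor,expr_normal,cn_tumor,cn_normal,meth_tumor,meth_normal
#'   `omics_matrix` inputs; give both members of a pair or neither.
#' @param probe_annotation Required with methylation input.
#' @param mutations A `mutation_table`, or `NULL`.
#' @param screen An [shrna_screen()], or `NULL`; the single-solution
#'   filter is applied here.
#' @param cfg A [scoring_config()].
#' @return List with `cards` (a `gene_score_cards` data frame) and
#'   `calls` (the per-data-type [aberration_calls()]).
#' @export
score_cohort <- function(cancer_type, sample_map,
                         expr_tumor = NULL, expr_normal = NULL,
                         cn_tumor = NULL, cn_normal = NULL,
                         meth_tumor = NULL, meth_normal = NULL,
                         probe_annotation = NULL,
                         mutations = NULL,
                         screen = NULL,
                         cfg = scoring_config()) {
  map <- if (is_deduplicated(sample_map)) sample_map else
    deduplicate_samples(sample_map)
  calls <- list()

  if (!is.null(expr_tumor) || !is.null(expr_normal)) {
    if (is.null(expr_tumor) || is.null(expr_normal)) {
      stop("expression requires both tumor and normal matrices",
           call. = FALSE)
    }
    co <- paired_cohort(expr_tumor, expr_normal, map)
    calls$expression <- score_expression(co, cfg)
  }
  if (!is.null(cn_tumor) || !is.null(cn_normal)) {
    if (is.null(cn_tumor) || is.null(cn_normal)) {
      stop("copy number requires both tumor and normal matrices",
           call. = FALSE)
    }
    if (is.null(expr_tumor)) {
      stop("copy-number scoring requires tumor expression for the ",
           "correlation stage", call. = FALSE)
    }
    co <- paired_cohort(cn_tumor, cn_normal, map)
    calls$cna <- score_copy_number(co, expr_tumor, cfg)
  }
  if (!is.null(meth_tumor) || !is.null(meth_normal)) {
    if (is.null(meth_tumor) || is.null(meth_normal)) {
      stop("methylation requires both tumor and normal matrices",
           call. = FALSE)
    }
    if (is.null(probe_annotation)) {
      stop("methylation scoring requires a probe annotation", call. = FALSE)
    }
    if (is.null(expr_tumor)) {
      stop("methylation scoring requires tumor expression for the ",
           "correlation stage", call. = FALSE)
    }
    df <- as.data.frame(map)
    tum_samples <- df$sample_id[df$sample_class == "tumor_primary"]
    nor_samples <- df$sample_id[df$sample_class == "normal"]
    mt <- restrict_samples(meth_tumor, tum_samples)
    mn <- restrict_samples(meth_normal, nor_samples)
    calls$methylation <- score_methylation(mt, mn, probe_annotation,
                                           expr_tumor, cfg)
  }
  if (!is.null(mutations)) {
    df <- as.data.frame(map)
    tum_samples <- df$sample_id[df$sample_class == "tumor_primary"]
    mut <- mutations[mutations$sample_id %in% tum_samples, , drop = FALSE]
    if (nrow(mut)) calls$mutation <- score_mutations(mutation_table(mut))
  }
  if (!is.null(screen)) {
    flt <- filter_single_solution(screen)
    if (nrow(flt$viability$values)) {
      calls$shrna <- score_shrna(flt, cancer_type)
    }
  }
  if (!length(calls)) {
    stop("at least one data type must be provided", call. = FALSE)
  }
  cards <- combine_scores(calls, cancer_type)
  list(cards = cards, calls = calls)
}

restrict_samples <- function(x, samples) {
  keep <- intersect(sample_ids(x), samples)
  omics_matrix(x$values[, keep, drop = FALSE], x$tag)
}
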