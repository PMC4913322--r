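#' Combine per-data-type calls into gene score cards
#'
#' The oncogene score of a gene is the number of data types in which it
#' carries an activating aberration; the tumor suppressor score counts
#' inactivating aberrations.  The overall score is their difference
#' (positive = oncogene-like) and the aberration score their sum (total
#' evidence, direction ignored).  Data types in which a gene was not
#' measured contribute nothing and reduce `n_data_types_available`.
#'
#' @param calls A list of [aberration_calls()] objects (at most one per
#'   data type; a duplicated data type, or duplicated gene within one call
#'   set, is an error).
#' @param cancer_type Cancer-type label stamped on every card.
#' @return A `gene_score_cards` data frame: `gene`, `cancer_type`, one
#'   `<data_type>_call` column per supplied data type (`activating`,
#'   `inactivating`, `both`, `none`, or `NA` if unavailable), `og_score`,
#'   `ts_score`, `overall_score`, `aberration_score`,
#'   `n_data_types_available`.
#' @export
combine_scores <- function(calls, cancer_type = "all") {
  if (inherits(calls, "aberration_calls")) calls <- list(calls)
  stopifnot(length(calls) >= 1L)
  types <- vapply(calls, function(cs) cs$data_type[1L], character(1L))
  dup <- unique(types[duplicated(types)])
  if (length(dup)) {
    stop("duplicate call set(s) for data type(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  names(calls) <- types
  genes <- sort(unique(unlist(lapply(calls, function(cs) cs$gene))))
  n <- length(genes)
  og <- ts <- avail <- integer(n)
  call_cols <- list()
  for (tp in types) {
    cs <- calls[[tp]]
    idx <- match(genes, cs$gene)
    act <- ifelse(is.na(idx), FALSE, cs$activating[idx])
    inact <- ifelse(is.na(idx), FALSE, cs$inactivating[idx])
    av <- ifelse(is.na(idx), FALSE, cs$available[idx])
    og <- og + as.integer(act)
    ts <- ts + as.integer(inact)
    avail <- avail + as.integer(av)
    lab <- rep(NA_character_, n)
    lab[av] <- "none"
    lab[av & act & !inact] <- "activating"
    lab[av & !act & inact] <- "inactivating"
    lab[av & act & inact] <- "both"
    call_cols[[paste0(tp, "_call")]] <- lab
  }
  cards <- data.frame(gene = genes, cancer_type = cancer_type,
                      stringsAsFactors = FALSE)
  for (nm in names(call_cols)) cards[[nm]] <- call_cols[[nm]]
  cards$og_score <- og
  cards$ts_score <- ts
  cards$overall_score <- og - ts
  cards$aberration_score <- og + ts
  cards$n_data_types_available <- avail
  cards <- structure(cards, class = c("gene_score_cards", "data.frame"))
  validate_cards(cards)
  cards
}

#' Check the structural identities of a score-card table
#'
#' Asserts, for every card, `overall = og - ts`, `aberration = og + ts`,
#' non-negative component scores bounded by the number of available data
#' types.  Called after every [combine_scores()]; exported so pipelines
#' can re-assert after transformations.
#'
#' @param cards A `gene_score_cards` data frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_cards <- function(cards) {
  stopifnot(is.data.frame(cards))
  with(cards, {
    if (any(overall_score != og_score - ts_score)) {
      stop("overall_score != og_score - ts_score", call. = FALSE)
    }
    if (any(aberration_score != og_score + ts_score)) {
      stop("aberration_score != og_score + ts_score", call. = FALSE)
    }
    if (any(og_score < 0 | ts_score < 0)) {
      stop("negative component score", call. = FALSE)
    }
    if (any(og_score > n_data_types_available |
              ts_score > n_data_types_available)) {
      stop("component score exceeds available data types", call. = FALSE)
    }
  })
  invisible(TRUE)
}

#' Rank genes by a score
#'
#' Stable descending (or ascending) sort on the chosen score, ties broken
#' by gene symbol so the order is deterministic across runs.
#'
#' @param cards `gene_score_cards`.
#' @param by One of `"og"`, `"ts"`, `"overall"`, `"aberration"`.
#' @param descending Sort direction.
#' @return Character vector of gene symbols in rank order.
#' @export
rank_genes <- function(cards, by = c("og", "ts", "overall", "aberration"),
                       descending = TRUE) {
  by <- match.arg(by)
  score <- cards[[paste0(by, "_score")]]
  ord <- order(if (descending) -score else score, cards$gene)
  cards$gene[ord]
}

#' Genes with opposite roles in different cancer types
#'
#' Returns genes that look oncogene-like in one cancer type and tumor
#' suppressor-like in a *different* one, each side supported by at least
#' `min_data_types` data types (component score >= `min_data_types`).
#'
#' @param cards `gene_score_cards` spanning several cancer types (one row
#'   per gene x cancer type).
#' @param min_data_types Minimum per-cancer-type component score.
#' @return Sorted character vector of dual-role gene symbols.
#' @export
dual_role_genes <- function(cards, min_data_types = 2L) {
  if (length(unique(cards$cancer_type)) < 2L) {
    stop("need cards from at least two cancer types", call. = FALSE)
  }
  out <- vapply(unique(cards$gene), function(g) {
    sub <- cards[cards$gene == g, ]
    og_types <- unique(sub$cancer_type[sub$og_score >= min_data_types])
    ts_types <- unique(sub$cancer_type[sub$ts_score >= min_data_types])
    # some type supports each role, and the two roles are not confined to
    # one and the same cancer type
    length(og_types) > 0L && length(ts_types) > 0L &&
      length(union(og_types, ts_types)) >= 2L
  }, logical(1L))
  sort(names(out)[out])
}

#' Average overall scores over pathway gene sets
#'
#' A pathway's score is the mean overall score of its member genes that
#' are present in the scored universe; absent members are excluded from
#' the mean (not imputed as zero) and counted in `n_missing`.  A pathway
#' disjoint from the universe gets a missing score.
#'
#' @param cards `gene_score_cards` for one cohort.
#' @param pathways Named list of gene-symbol vectors (see [read_gmt()]).
#' @return Data frame `pathway_id`, `mean_overall`, `n_genes_scored`,
#'   `n_missing`.
#' @export
pathway_scores <- function(cards, pathways) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  rows <- lapply(names(pathways), function(pid) {
    members <- pathways[[pid]]
    scored <- intersect(members, cards$gene)
    data.frame(
      pathway_id = pid,
      mean_overall = if (length(scored)) {
        mean(cards$overall_score[match(scored, cards$gene)])
      } else NA_real_,
      n_genes_scored = length(scored),
      n_missing = length(members) - length(scored),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of tumor samples affected per gene
#'
#' Builds, per gene, the distribution of tumor-normal differences (paired
#' subtraction when `pairs` is supplied, otherwise each tumor minus the
#' mean over all normals) and calls a sample affected when its difference
#' lies strictly more than one sample standard deviation (n-1 denominator)
#' from the mean of that distribution.  A sample exactly at one SD is not
#' affected; a degenerate distribution (SD 0) affects nobody.
#'
#' @param tumor,normal `omics_matrix` objects sharing feature ids.
#' @param pairs Optional data frame with columns `tumor_sample`,
#'   `normal_sample` (e.g. from a [paired_cohort()]); omit for the
#'   unpaired analysis.
#' @return Data frame `gene`, `frac_up`, `frac_down`, `n` (differences
#'   used).  `frac_up + frac_down <= 1` by construction.
#' @export
affected_fractions <- function(tumor, normal, pairs = NULL) {
  stopifnot(inherits(tumor, "omics_matrix"), inherits(normal, "omics_matrix"))
  genes <- intersect(feature_ids(tumor), feature_ids(normal))
  if (!is.null(pairs)) {
    d_mat <- tumor$values[genes, pairs$tumor_sample, drop = FALSE] -
      normal$values[genes, pairs$normal_sample, drop = FALSE]
  } else {
    ref <- rowMeans(normal$values[genes, , drop = FALSE], na.rm = TRUE)
    d_mat <- tumor$values[genes, , drop = FALSE] - ref
  }
  frac_up <- frac_down <- rep(NA_real_, length(genes))
  nn <- integer(length(genes))
  for (i in seq_along(genes)) {
    d <- d_mat[i, ]
    d <- d[!is.na(d)]
    nn[i] <- length(d)
    if (length(d) < 2L) next
    mu <- mean(d)
    s <- stats::sd(d)
    if (s == 0) {
      frac_up[i] <- 0
      frac_down[i] <- 0
    } else {
      frac_up[i] <- mean(d - mu > s)
      frac_down[i] <- mean(d - mu < -s)
    }
  }
  data.frame(gene = genes, frac_up = frac_up, frac_down = frac_down,
             n = nn, stringsAsFactors = FALSE)
}

#' Pearson correlation of two pathway-score profiles
#'
#' Used to compare cohorts (typically tumors versus cell lines of the
#' same cancer type) through their pathway-score vectors.
#'
#' @param scores_a,scores_b Data frames from [pathway_scores()].
#' @return Pearson r over the shared pathways with non-missing scores
#'   (>= 3 required).
#' @export
compare_cohorts <- function(scores_a, scores_b) {
  m <- merge(scores_a[, c("pathway_id", "mean_overall")],
             scores_b[, c("pathway_id", "mean_overall")],
             by = "pathway_id", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3L) {
    stop("need at least 3 shared pathways with non-missing scores",
         call. = FALSE)
  }
  stats::cor(m$mean_overall_a, m$mean_overall_b)
}
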