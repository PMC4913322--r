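#' Per-gene aberration calls for one data type
#'
#' Each scorer returns one of these: per gene, two booleans (`activating`,
#' `inactivating`), an availability flag, and the supporting statistics
#' that led to the call.  For expression, copy number and mutations the
#' two flags are mutually exclusive; for methylation and shRNA a gene can
#' carry both (different probes, or cell lines in both extreme quartiles).
#'
#' @param gene Character vector of gene symbols (unique).
#' @param data_type One of `expression`, `cna`, `methylation`, `mutation`,
#'   `shrna`.
#' @param activating,inactivating Logical vectors.
#' @param available Logical vector; where `FALSE`, both flags must be
#'   `FALSE`.
#' @param stats Optional data frame of supporting statistics (p, q,
#'   effect, rho, ... as applicable), recycled columns cbind-ed onto the
#'   result.
#' @return An `aberration_calls` data frame.
#' @export
aberration_calls <- function(gene, data_type, activating, inactivating,
                             available, stats = NULL) {
  data_type <- match.arg(data_type, call_data_types())
  stopifnot(length(activating) == length(gene),
            length(inactivating) == length(gene),
            length(available) == length(gene))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup)) {
    stop("duplicate gene(s) in call set: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  activating <- as.logical(activating)
  inactivating <- as.logical(inactivating)
  available <- as.logical(available)
  activating[is.na(activating)] <- FALSE
  inactivating[is.na(inactivating)] <- FALSE
  if (any((activating | inactivating) & !available)) {
    stop("unavailable genes cannot carry aberration flags", call. = FALSE)
  }
  if (data_type %in% c("expression", "cna", "mutation") &&
      any(activating & inactivating)) {
    stop("activating and inactivating flags are mutually exclusive for ",
         data_type, call. = FALSE)
  }
  df <- data.frame(gene = as.character(gene),
                   data_type = rep_len(data_type, length(gene)),
                   activating = activating, inactivating = inactivating,
                   available = available, stringsAsFactors = FALSE)
  if (!is.null(stats)) df <- cbind(df, as.data.frame(stats))
  rownames(df) <- NULL
  structure(df, class = c("aberration_calls", "data.frame"))
}

#' @export
call_data_types <- function() {
  c("expression", "cna", "methylation", "mutation", "shrna")
}

#' Scoring thresholds
#'
#' The defaults are the published operating point of the method: FDR 0.05
#' for every Benjamini-Hochberg stage, and minimum absolute mean
#' differences of 0.1 copy-number log-ratio units and 0.1 beta units for
#' the copy-number and methylation scorers (both strict inequalities, so
#' an effect of exactly 0.1 does not pass).
#'
#' @param fdr_threshold FDR level for all BH stages.
#' @param min_cn_diff Copy-number gate, log-ratio units.
#' @param min_beta_diff Methylation gate, beta units.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(fdr_threshold = 0.05, min_cn_diff = 0.1,
                           min_beta_diff = 0.1) {
  if (fdr_threshold <= 0 || min_cn_diff <= 0 || min_beta_diff <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(list(fdr_threshold = fdr_threshold, min_cn_diff = min_cn_diff,
                 min_beta_diff = min_beta_diff), class = "scoring_config")
}

#' Match tumor and normal samples into a paired cohort
#'
#' Links each patient's primary tumor column to their normal column for a
#' given data type.  Requires a deduplicated [sample_map()]; one pair per
#' patient (if a patient somehow has several normals, the
#' lexicographically first is used).
#'
#' @param tumor,normal `omics_matrix` objects of the same tag.
#' @param map A deduplicated `sample_map`.
#' @return A `paired_cohort`: list with `tumor`, `normal` (the matrices)
#'   and `pairs` (data frame `patient_id`, `tumor_sample`,
#'   `normal_sample`).
#' @export
paired_cohort <- function(tumor, normal, map) {
  stopifnot(inherits(tumor, "omics_matrix"), inherits(normal, "omics_matrix"))
  if (tumor$tag != normal$tag) {
    stop("tumor and normal matrices must share a data-type tag",
         call. = FALSE)
  }
  if (!is_deduplicated(map)) {
    stop("sample map must be deduplicated first (deduplicate_samples)",
         call. = FALSE)
  }
  df <- as.data.frame(map)
  tum <- df[df$sample_class == "tumor_primary" &
              df$sample_id %in% sample_ids(tumor), c("patient_id", "sample_id")]
  nor <- df[df$sample_class == "normal" &
              df$sample_id %in% sample_ids(normal), c("patient_id", "sample_id")]
  nor <- nor[order(nor$patient_id, nor$sample_id), ]
  nor <- nor[!duplicated(nor$patient_id), ]
  pairs <- merge(tum, nor, by = "patient_id",
                 suffixes = c("_tumor", "_normal"))
  pairs <- data.frame(patient_id = pairs$patient_id,
                      tumor_sample = pairs$sample_id_tumor,
                      normal_sample = pairs$sample_id_normal,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$patient_id), ]
  rownames(pairs) <- NULL
  structure(list(tumor = tumor, normal = normal, pairs = pairs),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort [%s]> %d genes, %d pairs\n",
              x$tumor$tag, nrow(x$tumor$values), nrow(x$pairs)))
  invisible(x)
}
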