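#' Classify a variant class as oncogene- or tumor-suppressor-type
#'
#' The 20/20-rule dichotomy: missense mutations and in-frame
#' insertions/deletions are oncogene-type (they can recurrently activate);
#' frame-shift insertions/deletions, nonsense and splice-site mutations
#' are tumor-suppressor-type (they truncate or disrupt).  Everything else
#' (silent, UTR, ...) is `other`.
#'
#' @param variant_class Character vector over [variant_classes()].
#' @return Character vector over `oncogene`, `tumor_suppressor`, `other`.
#' @export
classify_mutation <- function(variant_class) {
  bad <- setdiff(unique(variant_class), variant_classes())
  if (length(bad)) {
    stop("unknown variant_class token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- rep("other", length(variant_class))
  out[variant_class %in% c("missense", "in_frame_ins", "in_frame_del")] <-
    "oncogene"
  out[variant_class %in% c("frame_shift_ins", "frame_shift_del",
                           "nonsense", "splice_site")] <- "tumor_suppressor"
  out
}

#' Mutation rates for a single gene
#'
#' OGMR (oncogene mutation rate) is one minus the number of *distinct*
#' oncogene-type mutations divided by the gene's total mutation count, so
#' it is high when activating mutations recur at few sites.  TSMR (tumor
#' suppressor mutation rate) is the number of distinct
#' tumor-suppressor-type mutations divided by the total count, high when
#' truncating mutations are spread along the gene.  Distinctness is keyed
#' on the genomic change `(chrom, pos, ref, alt, variant_class)`.  The
#' denominator is all recorded mutations for the gene, including
#' `other`-class records.
#'
#' @param records A `mutation_table` (or compatible data frame) whose rows
#'   all belong to one gene.
#' @return A one-row data frame: `gene`, `n_total`, `n_og`, `n_ts`,
#'   `n_og_distinct`, `n_ts_distinct`, `ogmr`, `tsmr`.
#' @export
mutation_rates <- function(records) {
  if (!nrow(records)) stop("no mutation records", call. = FALSE)
  g <- unique(records$gene)
  if (length(g) != 1L) {
    stop("records must all belong to one gene, got: ",
         paste(g, collapse = ", "), call. = FALSE)
  }
  cls <- classify_mutation(records$variant_class)
  ident <- paste(records$chrom, records$pos, records$ref, records$alt,
                 records$variant_class, sep = "\r")
  n_total <- nrow(records)
  n_og <- sum(cls == "oncogene")
  n_ts <- sum(cls == "tumor_suppressor")
  n_og_distinct <- length(unique(ident[cls == "oncogene"]))
  n_ts_distinct <- length(unique(ident[cls == "tumor_suppressor"]))
  data.frame(gene = g, n_total = n_total, n_og = n_og, n_ts = n_ts,
             n_og_distinct = n_og_distinct, n_ts_distinct = n_ts_distinct,
             ogmr = 1 - n_og_distinct / n_total,
             tsmr = n_ts_distinct / n_total,
             stringsAsFactors = FALSE)
}

#' Rate table for every gene in a mutation table
#'
#' @param table A `mutation_table`.
#' @return Data frame with one [mutation_rates()] row per gene, sorted by
#'   gene symbol.
#' @export
mutation_rate_table <- function(table) {
  stopifnot(inherits(table, "mutation_table") || is.data.frame(table))
  if (!nrow(table)) {
    return(mutation_rates(table))  # informative error
  }
  parts <- split(as.data.frame(table), table$gene)
  out <- do.call(rbind, lapply(parts, mutation_rates))
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Score mutations by the 20/20 rule
#'
#' A gene is flagged activating (oncogene-like) when `OGMR > 0.2` and
#' `TSMR < 0.05`; inactivating (tumor-suppressor-like) when `TSMR > 0.2`,
#' or when `OGMR > 0.2` and `TSMR > 0.05`.  All inequalities are strict.
#' Each flag additionally requires at least `min_class_count` mutations of
#' the corresponding class (counting all, not only distinct, mutations).
#' The two flags are mutually exclusive by construction: activating needs
#' TSMR below 0.05, inactivating needs it above.
#'
#' @param table A `mutation_table`; genes absent from it are simply not in
#'   the output (unavailable).
#' @param min_class_count Minimum oncogene- (resp. tumor-suppressor-)
#'   class mutations to allow the corresponding flag.
#' @return [aberration_calls()] (`data_type = "mutation"`) with the rate
#'   table columns as supporting statistics.
#' @export
score_mutations <- function(table, min_class_count = 5L) {
  rates <- mutation_rate_table(table)
  activating <- rates$ogmr > 0.2 & rates$tsmr < 0.05 &
    rates$n_og >= min_class_count
  inactivating <- (rates$tsmr > 0.2 |
                     (rates$ogmr > 0.2 & rates$tsmr > 0.05)) &
    rates$n_ts >= min_class_count
  aberration_calls(rates$gene, "mutation", activating, inactivating,
                   available = rep(TRUE, nrow(rates)),
                   stats = rates[, setdiff(names(rates), "gene")])
}
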