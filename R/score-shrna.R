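#' Container for an shRNA knock-down screen
#'
#' Gene-level knock-down viability scores ("gene solutions") across a
#' cell-line panel, with the number of alternative gene solutions reported
#' per gene and a cancer-type label per cell line.
#'
#' @param viability `omics_matrix` with tag `"shrna"` (genes x cell
#'   lines).
#' @param gene_solution_count Named integer vector, gene -> number of gene
#'   solutions (must be >= 1 where present).
#' @param line_type Named character vector, cell line -> cancer type;
#'   every line in `viability` must be labeled.
#' @return An `shrna_screen` list.
#' @export
shrna_screen <- function(viability, gene_solution_count, line_type) {
  stopifnot(inherits(viability, "omics_matrix"))
  if (viability$tag != "shrna") {
    stop("viability matrix must carry the 'shrna' tag", call. = FALSE)
  }
  missing_lines <- setdiff(sample_ids(viability), names(line_type))
  if (length(missing_lines)) {
    stop("cell line(s) without cancer-type label: ",
         paste(missing_lines, collapse = ", "), call. = FALSE)
  }
  gsc <- gene_solution_count
  if (any(!is.na(gsc) & gsc < 1L)) {
    stop("gene_solution_count must be >= 1", call. = FALSE)
  }
  structure(list(viability = viability,
                 gene_solution_count = gsc,
                 line_type = line_type),
            class = "shrna_screen")
}

#' Keep only genes with a single gene solution
#'
#' Genes for which the screen provides multiple alternative gene solutions
#' have ambiguous viability estimates and are excluded; genes without a
#' recorded solution count are excluded as well.
#'
#' @param screen An [shrna_screen()].
#' @return The filtered `shrna_screen` (possibly with zero genes).
#' @export
filter_single_solution <- function(screen) {
  stopifnot(inherits(screen, "shrna_screen"))
  genes <- feature_ids(screen$viability)
  gsc <- screen$gene_solution_count[genes]
  keep <- !is.na(gsc) & gsc == 1L
  vals <- screen$viability$values[keep, , drop = FALSE]
  screen$viability <- if (nrow(vals)) {
    omics_matrix(vals, "shrna")
  } else {
    structure(list(values = vals, tag = "shrna"), class = "omics_matrix")
  }
  screen
}

#' Score knock-down viability for one cancer type
#'
#' Per gene, the 25th and 75th percentiles (linear interpolation) of its
#' viability scores across *all* cell lines define the reference
#' quartiles.  The gene is flagged activating (oncogene-like, i.e. the
#' cancer type depends on it) if at least 25% of the type's cell lines
#' have viability strictly below the lower quartile; inactivating if at
#' least 25% have viability strictly above the upper quartile.  The
#' fraction thresholds are inclusive, the percentile comparisons strict;
#' both flags may hold at once.
#'
#' @param screen An [shrna_screen()], typically after
#'   [filter_single_solution()].
#' @param cancer_type Cancer-type label; must have >= 1 cell line.
#' @param min_fraction Required fraction of the type's lines beyond the
#'   quartile (default 0.25).
#' @return [aberration_calls()] (`data_type = "shrna"`) with columns
#'   `q1`, `q3`, `frac_low`, `frac_high`, `n_lines`.
#' @export
score_shrna <- function(screen, cancer_type, min_fraction = 0.25) {
  stopifnot(inherits(screen, "shrna_screen"))
  lines <- names(screen$line_type)[screen$line_type == cancer_type]
  lines <- intersect(lines, sample_ids(screen$viability))
  if (!length(lines)) {
    stop("no cell lines for cancer type: ", cancer_type, call. = FALSE)
  }
  genes <- feature_ids(screen$viability)
  n <- length(genes)
  q1 <- q3 <- frac_low <- frac_high <- rep(NA_real_, n)
  n_lines <- integer(n)
  available <- logical(n)
  for (i in seq_len(n)) {
    v_all <- screen$viability$values[i, ]
    v_all <- v_all[!is.na(v_all)]
    v_type <- screen$viability$values[i, lines]
    v_type <- v_type[!is.na(v_type)]
    n_lines[i] <- length(v_type)
    if (!length(v_all) || !length(v_type)) next
    available[i] <- TRUE
    q1[i] <- quantile_linear(v_all, 0.25)
    q3[i] <- quantile_linear(v_all, 0.75)
    frac_low[i] <- mean(v_type < q1[i])
    frac_high[i] <- mean(v_type > q3[i])
  }
  activating <- available & frac_low >= min_fraction
  inactivating <- available & frac_high >= min_fraction
  activating[is.na(activating)] <- FALSE
  inactivating[is.na(inactivating)] <- FALSE
  aberration_calls(genes, "shrna", activating, inactivating, available,
                   stats = data.frame(q1 = q1, q3 = q3,
                                      frac_low = frac_low,
                                      frac_high = frac_high,
                                      n_lines = n_lines))
}
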