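#' Closed vocabulary of variant classes
#' @export
variant_classes <- function() {
  c("missense", "in_frame_ins", "in_frame_del", "frame_shift_ins",
    "frame_shift_del", "nonsense", "splice_site", "other")
}

maf_class_map <- c(
  Missense_Mutation = "missense",
  In_Frame_Ins      = "in_frame_ins",
  In_Frame_Del      = "in_frame_del",
  Frame_Shift_Ins   = "frame_shift_ins",
  Frame_Shift_Del   = "frame_shift_del",
  Nonsense_Mutation = "nonsense",
  Splice_Site       = "splice_site"
)

#' Construct a mutation table
#'
#' Per-mutation records: gene, sample, variant class (closed vocabulary,
#' see [variant_classes()]) and the genomic identity of the change
#' (chromosome, 1-based position, reference and alternate alleles).
#'
#' @param df Data frame with columns `gene`, `sample_id`, `variant_class`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return A `mutation_table` (data frame subclass).
#' @export
mutation_table <- function(df) {
  req <- c("gene", "sample_id", "variant_class", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, req]
  bad <- setdiff(unique(df$variant_class), variant_classes())
  if (length(bad)) {
    stop("unknown variant_class token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  if (any(!is.na(df$pos) & df$pos < 1L)) {
    stop("mutation position must be >= 1 (1-based MAF convention)",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("mutation_table", "data.frame"))
}

#' Read a MAF column subset
#'
#' Consumes the seven MAF columns needed for mutation scoring
#' (`Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`).  MAF `Variant_Classification` strings are mapped
#' onto the closed vocabulary; anything unmapped (e.g. `Silent`,
#' `3'UTR`) becomes `other`.
#'
#' @param path Path to a tab-separated MAF(-subset) file.
#' @return A `mutation_table`.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
           "Chromosome", "Start_Position", "Reference_Allele",
           "Tumor_Seq_Allele2")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("MAF file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vc <- unname(maf_class_map[df$Variant_Classification])
  vc[is.na(vc)] <- "other"
  mutation_table(data.frame(
    gene = as.character(df$Hugo_Symbol),
    sample_id = as.character(df$Tumor_Sample_Barcode),
    variant_class = vc,
    chrom = as.character(df$Chromosome),
    pos = as.integer(df$Start_Position),
    ref = as.character(df$Reference_Allele),
    alt = as.character(df$Tumor_Seq_Allele2),
    stringsAsFactors = FALSE))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate pathway id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- ids[lengths(sets) == 0L]
  if (length(empty)) {
    stop("empty gene set(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- ids
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                 character(1L))
  names(desc) <- ids
  attr(sets, "description") <- desc
  sets
}

probe_regions <- function() c("body", "other")

# Illumina annotation contexts collapsed onto the binary body/other
# distinction used by methylation scoring.
region_token_map <- c(
  Body = "body", body = "body",
  other = "other", Other = "other",
  TSS200 = "other", TSS1500 = "other",
  "5'UTR" = "other", "3'UTR" = "other",
  "1stExon" = "other", IGR = "other"
)

#' Read a methylation probe annotation TSV
#'
#' One row per probe-gene link (multi-mapped probes appear once per gene),
#' with the probe's genomic context.  Contexts are collapsed to a binary
#' `body` / `other` distinction: `Body` maps to `body`; promoter and UTR
#' contexts (`TSS200`, `TSS1500`, `5'UTR`, `3'UTR`, `1stExon`, `IGR`) map
#' to `other`.  Unknown tokens are an error.
#'
#' @param path TSV with columns `probe_id`, `gene`, `region`.
#' @return A `probe_annotation` data frame with columns `probe_id`, `gene`,
#'   `region` (`body`/`other`).
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param df Data frame with columns `probe_id`, `gene`, `region`.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "gene", "region")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("probe annotation missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, req]
  reg <- unname(region_token_map[df$region])
  bad <- unique(df$region[is.na(reg)])
  if (length(bad)) {
    stop("unknown region token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$region <- reg
  key <- paste(df$probe_id, df$gene, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate (probe_id, gene) pair(s): ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("probe_annotation", "data.frame"))
}

#' Read segmented copy-number data (SEG)
#'
#' Columns `sample`, `chrom`, `start`, `end`, optional `num_mark`,
#' `seg_mean`; coordinates 1-based inclusive.
#'
#' @param path Path to a SEG file.
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean`.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  req <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, req]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$seg_mean <- as.numeric(df$seg_mean)
  if (any(df$end < df$start)) {
    stop("malformed SEG interval: end < start", call. = FALSE)
  }
  df
}

#' Write / read a gene score table
#'
#' One row per gene and cancer type, with the per-data-type call columns
#' (`expression_call`, `cna_call`, `methylation_call`, `mutation_call`,
#' `shrna_call`; values `activating`, `inactivating`, `both`, `none` or
#' `NA` when the data type was unavailable) and the four scores.
#' `read_scores(write_scores(cards, path))` reproduces the table exactly.
#'
#' @param cards A `gene_score_cards` data frame from [combine_scores()].
#' @param path Output (input) path.
#' @export
write_scores <- function(cards, path) {
  stopifnot(inherits(cards, "gene_score_cards"))
  utils::write.table(as.data.frame(cards), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  int_cols <- c("og_score", "ts_score", "overall_score", "aberration_score",
                "n_data_types_available")
  for (cl in intersect(int_cols, names(df))) df[[cl]] <- as.integer(df[[cl]])
  structure(df, class = c("gene_score_cards", "data.frame"))
}
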