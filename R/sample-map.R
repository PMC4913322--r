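#' Sample map: patient/sample links with class and cancer type
#'
#' A `sample_map` records, for every profiled sample, which patient it
#' belongs to, whether it is a primary tumor, a recurrent/metastatic tumor
#' or a normal sample, and the cancer-type label of the cohort.  Downstream
#' scoring only accepts maps that have passed [deduplicate_samples()]
#' (tracked by the `deduplicated` attribute).
#'
#' @param df Data frame with columns `patient_id`, `sample_id`,
#'   `sample_class`, `cancer_type`.
#' @param deduplicated Internal; set by [deduplicate_samples()].
#' @return A `sample_map` (data frame subclass).
#' @export
sample_map <- function(df, deduplicated = FALSE) {
  req <- c("patient_id", "sample_id", "sample_class", "cancer_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("sample map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, req]
  for (cl in req) df[[cl]] <- as.character(df[[cl]])
  bad <- setdiff(unique(df$sample_class), sample_classes())
  if (length(bad)) {
    stop("unknown sample_class token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("sample_map", "data.frame"),
            deduplicated = isTRUE(deduplicated))
}

#' @export
sample_classes <- function() {
  c("tumor_primary", "tumor_recurrent_or_met", "normal")
}

#' @rdname sample_map
#' @param x A `sample_map`.
#' @export
is_deduplicated <- function(x) isTRUE(attr(x, "deduplicated"))

#' Read a sample map TSV
#'
#' @param path TSV with columns `patient_id`, `sample_id`, `sample_class`,
#'   `cancer_type`.
#' @return A `sample_map` (pre-deduplication).
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_map(df)
}

#' Resolve multiple samples per patient
#'
#' Cohort preprocessing applied before any scoring: recurrent or metastatic
#' tumor samples are dropped so that only primary tumors are analyzed, and
#' patients for whom several primary samples exist are removed entirely
#' (all of their samples, including normals), since no single representative
#' primary can be chosen.  Normal samples of retained patients are kept.
#' The operation is idempotent.
#'
#' @param map A `sample_map`.
#' @return A `sample_map` with `is_deduplicated()` `TRUE`, containing at
#'   most one primary tumor per patient and no recurrent/metastatic
#'   samples.
#' @export
deduplicate_samples <- function(map) {
  stopifnot(inherits(map, "sample_map"))
  df <- as.data.frame(map)
  primaries <- df$patient_id[df$sample_class == "tumor_primary"]
  multi <- unique(primaries[duplicated(primaries)])
  keep <- !(df$patient_id %in% multi) &
    df$sample_class != "tumor_recurrent_or_met"
  sample_map(df[keep, , drop = FALSE], deduplicated = TRUE)
}
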