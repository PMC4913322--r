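#' Construct a feature-by-sample omics matrix
#'
#' The basic container for a single data type: a numeric matrix with
#' feature (gene or probe) rows and sample columns, tagged with the kind of
#' measurement it holds.  Units depend on the tag: log2 expression for
#' `"expression"`, copy-number log-ratios for `"cna"`, beta values in
#' \[0, 1\] for `"methylation"`, and knock-down viability scores for
#' `"shrna"`.
#'
#' @param values Numeric matrix with unique feature rownames and unique
#'   sample colnames.  Missing measurements are `NA`.
#' @param tag One of `"expression"`, `"cna"`, `"methylation"`, `"shrna"`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values` and `tag`.
#' @export
omics_matrix <- function(values, tag) {
  tag <- match.arg(tag, omics_tags())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature rownames and sample colnames",
         call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) {
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (tag == "methylation") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "beta value outside [0, 1] at feature '%s', sample '%s' (value %g)",
        rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]],
        values[bad[1L, , drop = FALSE]]), call. = FALSE)
    }
  }
  structure(list(values = values, tag = tag), class = "omics_matrix")
}

#' @export
omics_tags <- function() c("expression", "cna", "methylation", "shrna")

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix [%s]> %d features x %d samples\n",
              x$tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a feature-by-sample TSV matrix
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' the body is numeric with empty fields or `NA` for missing values.
#' Validation (unique ids; beta range for methylation) happens in
#' [omics_matrix()].
#'
#' @param path Path to a tab-separated file.
#' @param tag Data-type tag, see [omics_matrix()].
#' @return An `omics_matrix`.
#' @export
read_matrix <- function(path, tag) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("matrix file needs id column plus >=1 sample: ",
                          path, call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  omics_matrix(vals, tag)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_matrix()]; finite values round-trip exactly (written
#' with full precision).
#'
#' @param x An `omics_matrix`.
#' @param path Output path.
#' @param id_column Header for the feature-id column.
#' @export
write_matrix <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "omics_matrix"))
  body <- apply(x$values, 2L, format_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x$values))
  df <- data.frame(feature_ids(x), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, sample_ids(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# full-precision decimal rendering so read_matrix(write_matrix(x)) == x
format_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) NA_character_ else sprintf("%.17g", z)
  }, character(1L))
  out
}
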