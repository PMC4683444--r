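# Readers and writers for the tab-delimited interchange formats.

#' Read / write an expression matrix
#'
#' TSV with a header row of sample ids and the feature id in the first
#' column. Values are numeric normalized (log2) intensities.
#'
#' @param path file path.
#' @return `read_expression_matrix`: numeric matrix features x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_expression_matrix
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param id_col name of the first (feature id) column.
#' @export
write_expression_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an activity matrix (samples x circuits)
#'
#' TSV with a `sample_id` first column and one column per circuit.
#' @param path file path.
#' @return `read_activity_matrix`: numeric matrix samples x circuits.
#' @export
read_activity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  attr(m, "level") <- "circuit"
  m
}

#' @rdname read_activity_matrix
#' @param m samples x circuits numeric matrix.
#' @export
write_activity_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample drug-response table
#'
#' TSV with header columns `sample_id`, `drug`, `cancer`, `ic50_ln_uM`
#' (IC50 on the natural-log micromolar scale). (sample_id, drug) pairs must
#' be unique and IC50 finite.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_response_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "drug", "cancer", "ic50_ln_uM")
  if (!all(need %in% names(df)))
    stop("response table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("sample_id", "drug")]))
    stop("(sample_id, drug) pairs must be unique", call. = FALSE)
  if (any(!is.finite(df$ic50_ln_uM)))
    stop("non-finite IC50 values", call. = FALSE)
  df
}

#' Read a probeset-to-gene platform map
#'
#' TSV with header columns `probeset_id` and `gene_id` (extra columns kept).
#' @param path file path.
#' @return data.frame.
#' @export
read_platform_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probeset_id", "gene_id") %in% names(df)))
    stop("platform map must have columns probeset_id, gene_id", call. = FALSE)
  df
}
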