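#' Validate a gene-expression matrix
#'
#' An expression matrix is a plain numeric matrix with samples in rows and
#' genes in columns, unique row (sample) and column (gene) names, and no
#' missing or non-finite values.
#'
#' @param X Numeric matrix, n samples x p genes. If row/column names are
#'   absent, default identifiers `sample_1..n` / `gene_1..p` are added.
#' @return The validated matrix, with names guaranteed.
#' @export
as_expression_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("expression data must be a numeric matrix (samples x genes)")
  }
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (ncol(X) < 1L) stop("need at least 1 gene")
  if (anyNA(X) || !all(is.finite(X))) {
    stop("expression matrix contains missing or non-finite values")
  }
  if (is.null(rownames(X))) rownames(X) <- paste0("sample_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("gene_", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(X))) stop("gene ids must be unique")
  X
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers; the delimiter is inferred from the file extension
#' (`.csv` means comma, anything else tab).
#'
#' @param path File path.
#' @return Validated expression matrix (samples x genes).
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_expression_matrix(as.matrix(df))
}

#' Read a sample label file
#'
#' Two columns: `sample_id` and `label`, where `label` is 0, 1 or NA
#' (NA marks an unlabeled sample awaiting selection).
#'
#' @param path File path (TSV or CSV by extension).
#' @return Data frame with columns `sample_id` (character) and
#'   `label` (integer, NA allowed).
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns sample_id, label")
  names(df)[1:2] <- c("sample_id", "label")
  df$sample_id <- as.character(df$sample_id)
  lab <- df$label
  if (!all(lab %in% c(0L, 1L, NA))) stop("labels must be 0, 1 or NA")
  df$label <- as.integer(lab)
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  df[, c("sample_id", "label")]
}
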