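#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample / cell-type identifiers and a first column
#' of gene identifiers; values are linear-scale expression. The separator is
#' taken from the file extension (`.csv` uses comma, everything else tab).
#'
#' @param path file path.
#' @return Numeric matrix with gene row names and sample/cell-type column
#'   names.
#' @export
read_expression_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = 1, colClasses = NA),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  M <- as.matrix(df)
  if (!is.numeric(M))
    stop("non-numeric entries in ", path)
  if (anyDuplicated(rownames(M)))
    stop("duplicate gene identifiers in ", path)
  M
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; values round-trip to better than
#' 1e-12 relative precision.
#'
#' @param M numeric matrix with row and column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(M, path) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("g", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("s", seq_len(ncol(M)))
  df <- data.frame(id = rownames(M),
                   format(M, digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene weights from a two-column TSV
#'
#' @param path file with columns `gene_id` and `weight` (header required).
#' @return Named numeric vector of weights.
#' @export
read_gene_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2) stop("gene-weight file needs two columns (gene_id, weight)")
  g <- as.numeric(df[[2]])
  names(g) <- as.character(df[[1]])
  g
}

#' Write gene weights to a two-column TSV
#'
#' @param g named numeric vector of gene weights.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_weights <- function(g, path) {
  if (is.null(names(g))) names(g) <- paste0("g", seq_along(g))
  df <- data.frame(gene_id = names(g),
                   weight = format(g, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
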