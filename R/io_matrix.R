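#' Read a relationship matrix from file
#'
#' Auto-detects the format: a MatrixMarket header (\code{%%MatrixMarket})
#' is read as a coordinate symmetric matrix via the Matrix package
#' (ids taken as 1..n unless supplied); anything else is read as a
#' dense TSV with an id header row and an id first column.
#'
#' @param file path.
#' @param kind kind tag for the result (default \code{"custom"}).
#' @param ids optional ids for MatrixMarket input.
#' @return A \code{rel_matrix}.
#' @export
read_relmat <- function(file, kind = "custom", ids = NULL) {
  first <- readLines(file, n = 1)
  if (grepl("^%%MatrixMarket", first)) {
    M <- as.matrix(Matrix::readMM(file))
    M <- (M + t(M)) / 2
    if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
    return(rel_matrix(M, ids = ids, kind = kind, check = FALSE))
  }
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE)
  rn <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- rn
  rel_matrix(M, ids = rn, kind = kind)
}

#' Write a relationship matrix to file
#'
#' @param K a \code{rel_matrix}.
#' @param file output path.
#' @param format \code{"tsv"} (dense, id header row/column) or
#'   \code{"mm"} (MatrixMarket coordinate symmetric; ids are dropped).
#' @export
write_relmat <- function(K, file, format = c("tsv", "mm")) {
  format <- match.arg(format)
  V <- rm_values(K)
  if (format == "mm") {
    m <- methods::as(Matrix::forceSymmetric(Matrix::Matrix(V, sparse = TRUE)),
                     "CsparseMatrix")
    Matrix::writeMM(m, file)
  } else {
    df <- data.frame(id = rm_ids(K), V, check.names = FALSE)
    colnames(df) <- c("id", rm_ids(K))
    utils::write.table(df, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(file)
}
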