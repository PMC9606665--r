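#' Genotype-matrix container
#'
#' Holds an individuals-by-markers matrix of biallelic genotypes plus
#' per-marker allele frequencies. Three codings are accepted and all
#' are stored internally on the centered-friendly -1/0/1 scale (count
#' of the reference allele minus 1):
#' \describe{
#'   \item{\code{"dosage"}}{0/1/2 allele counts, mapped to -1/0/1.}
#'   \item{\code{"inbred01"}}{0/1 homozygote calls on inbred lines,
#'     mapped to -1/+1.}
#'   \item{\code{"centered"}}{already -1/0/1.}
#' }
#'
#' @param dosages numeric matrix, individuals in rows, markers in
#'   columns; row names are ids, column names marker names.
#' @param coding input coding, see Details.
#' @param ids,markers optional overrides for dimnames.
#' @param allele_freqs optional fixed per-marker frequencies of the
#'   reference allele; by default observed frequencies are computed
#'   from the genotypes.
#'
#' @return A list of class \code{geno_matrix} with elements \code{M}
#'   (-1/0/1 matrix), \code{p} (allele frequencies), \code{ids},
#'   \code{markers}.
#' @export
geno_matrix <- function(dosages, coding = c("dosage", "inbred01", "centered"),
                        ids = rownames(dosages),
                        markers = colnames(dosages),
                        allele_freqs = NULL) {
  coding <- match.arg(coding)
  M <- as.matrix(dosages)
  storage.mode(M) <- "double"
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(M)))
  rng <- switch(coding, dosage = c(0, 2), inbred01 = c(0, 1),
                centered = c(-1, 1))
  if (any(M < rng[1] | M > rng[2], na.rm = TRUE) ||
      any(M != round(M), na.rm = TRUE))
    stop("genotypes outside the declared '", coding, "' coding range")
  M <- switch(coding,
              dosage   = M - 1,
              inbred01 = 2 * M - 1,
              centered = M)
  if (is.null(allele_freqs)) {
    p <- colMeans(M + 1, na.rm = TRUE) / 2
  } else {
    p <- as.numeric(allele_freqs)
    if (length(p) != ncol(M))
      stop("allele_freqs length must equal the number of markers")
  }
  names(p) <- markers
  dimnames(M) <- list(as.character(ids), markers)
  structure(list(M = M, p = p, ids = as.character(ids),
                 markers = markers),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix: %d individuals x %d markers>\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Drop markers by minor allele frequency
#'
#' Removes markers whose minor allele frequency \code{min(p, 1-p)}
#' falls below the threshold.
#'
#' @param geno a [geno_matrix()].
#' @param maf threshold (default 0.02).
#' @return The filtered \code{geno_matrix}; the number of dropped
#'   markers is stored in attribute \code{"n_dropped"}.
#' @export
maf_filter <- function(geno, maf = 0.02) {
  keep <- pmin(geno$p, 1 - geno$p) >= maf
  out <- geno_matrix(geno$M[, keep, drop = FALSE], coding = "centered",
                     ids = geno$ids, markers = geno$markers[keep],
                     allele_freqs = geno$p[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read genotypes from a delimited file
#'
#' First column: id; remaining columns: integer genotypes; marker
#' names in the header. Both whitespace- and comma-delimited files are
#' accepted.
#'
#' @param file path.
#' @param coding genotype coding, see [geno_matrix()].
#' @return A \code{geno_matrix}.
#' @export
read_genotypes <- function(file, coding = "dosage") {
  first <- readLines(file, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  geno_matrix(M, coding = coding, ids = ids, markers = colnames(M))
}

#' Write genotypes to a delimited file
#' @param geno a \code{geno_matrix} (written back as 0/1/2 dosages).
#' @param file output path.
#' @export
write_genotypes <- function(geno, file) {
  df <- data.frame(id = geno$ids, geno$M + 1, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}
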