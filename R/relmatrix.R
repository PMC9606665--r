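#' Relationship-matrix container
#'
#' A dense symmetric relationship matrix (or inverse) tagged with the
#' kind of matrix it holds. The object is a plain numeric matrix with
#' id dimnames plus a \code{kind} attribute, so all base matrix algebra
#' applies directly.
#'
#' @param values square numeric matrix.
#' @param ids individual identifiers (defaults to existing rownames).
#' @param kind one of \code{"A"}, \code{"G"}, \code{"H"}, \code{"A_inv"},
#'   \code{"G_inv"}, \code{"H_inv"}, \code{"custom"}.
#' @param check verify symmetry (within 1e-8 relative tolerance).
#'
#' @return A matrix of class \code{rel_matrix}.
#' @export
rel_matrix <- function(values, ids = rownames(values), kind = "custom",
                       check = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("relationship matrix must be square")
  kinds <- c("A", "G", "H", "A_inv", "G_inv", "H_inv", "custom")
  kind <- match.arg(kind, kinds)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("length(ids) must equal the matrix dimension")
  if (check && nrow(values) > 0) {
    asym <- max(abs(values - t(values)))
    scale <- max(abs(values), 1)
    if (asym > 1e-8 * scale)
      stop("matrix is not symmetric (max asymmetry ", signif(asym, 3), ")")
    values <- (values + t(values)) / 2
  }
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  class(values) <- c("rel_matrix", class(values))
  values
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix kind=%s, %d x %d>\n", rm_kind(x),
              nrow(x), ncol(x)))
  y <- unclass(x)
  attr(y, "kind") <- NULL
  if (nrow(x) <= 10) print(y, ...) else {
    print(y[1:6, 1:6], ...)
    cat("...\n")
  }
  invisible(x)
}

#' Accessors for relationship matrices
#'
#' \code{rm_kind} returns the kind tag, \code{rm_ids} the identifier
#' index, and \code{rm_values} the bare numeric matrix (class and tag
#' stripped). They also accept plain matrices, for which the kind
#' defaults to \code{"custom"} and ids to the row names (or
#' \code{1..n}).
#'
#' @param x a \code{rel_matrix} or plain matrix.
#' @return A character scalar, character vector, or numeric matrix
#'   respectively.
#' @name rel_matrix_accessors
NULL

#' @rdname rel_matrix_accessors
#' @export
rm_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) "custom" else k
}

#' @rdname rel_matrix_accessors
#' @export
rm_ids <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) as.character(seq_len(nrow(x))) else ids
}

#' @rdname rel_matrix_accessors
#' @export
rm_values <- function(x) {
  x <- as.matrix(unclass(x))
  attr(x, "kind") <- NULL
  x
}

# reorder/subset to a given id vector, failing loudly on mismatch
rm_align <- function(x, ids) {
  ids <- as.character(ids)
  have <- rm_ids(x)
  if (!all(ids %in% have))
    stop("ids absent from relationship matrix: ",
         paste(utils::head(setdiff(ids, have), 5), collapse = ", "))
  rel_matrix(rm_values(x)[ids, ids, drop = FALSE], ids = ids,
             kind = rm_kind(x), check = FALSE)
}

#' Subset a relationship matrix to a set of ids
#'
#' Returns the block of the matrix over \code{ids}, in the order
#' given (e.g. the genotyped block A22 of a pedigree matrix).
#'
#' @param K a \code{rel_matrix}.
#' @param ids ids to keep, all of which must be present.
#' @return A \code{rel_matrix} of the same kind.
#' @export
subset_relmat <- function(K, ids) {
  rm_align(K, ids)
}

stopifnot_same_ids <- function(x, y) {
  if (!identical(rm_ids(x), rm_ids(y)))
    stop("relationship matrices are not indexed by the same ids ",
         "in the same order")
  invisible(TRUE)
}
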