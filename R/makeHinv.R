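#' Inverse hybrid relationship matrix for single-step evaluation
#'
#' Assembles \eqn{H^{-1} = A^{-1} + \Delta}, where \eqn{\Delta} is zero
#' except on the genotyped block, which receives
#' \eqn{G^{-1} - A_{22}^{-1}} (G here being the blended genomic matrix
#' restricted to the genotyped individuals, and A22 the pedigree
#' relationships among them). No extra tau/omega weighting is applied.
#'
#' @param A_inv \code{rel_matrix} of kind \code{"A_inv"} over the full
#'   pedigree.
#' @param G_blend blended genomic \code{rel_matrix} indexed by the
#'   genotyped ids.
#' @param A22 pedigree \code{rel_matrix} restricted to the genotyped
#'   ids (same order as \code{G_blend}).
#' @param genotyped_ids ids of the genotyped individuals; defaults to
#'   the ids of \code{G_blend}. May be empty, in which case A^-1 is
#'   returned unchanged (re-tagged).
#' @return A \code{rel_matrix} of kind \code{"H_inv"}.
#' @export
makeHinv <- function(A_inv, G_blend, A22, genotyped_ids = rm_ids(G_blend)) {
  ids <- rm_ids(A_inv)
  H <- rm_values(A_inv)
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) == 0)
    return(rel_matrix(H, ids = ids, kind = "H_inv", check = FALSE))
  if (!all(genotyped_ids %in% ids))
    stop("genotyped ids absent from the pedigree: ",
         paste(utils::head(setdiff(genotyped_ids, ids), 5), collapse = ", "))
  G_blend <- rm_align(G_blend, genotyped_ids)
  A22 <- rm_align(A22, genotyped_ids)
  Gi <- tryCatch(invert_relmat(G_blend), error = function(e)
    stop("blended G is singular on the genotyped block: ",
         conditionMessage(e)))
  A22i <- tryCatch(invert_relmat(A22), error = function(e)
    stop("A22 is singular on the genotyped block: ", conditionMessage(e)))
  idx <- match(genotyped_ids, ids)
  H[idx, idx] <- H[idx, idx] + rm_values(Gi) - rm_values(A22i)
  rel_matrix(H, ids = ids, kind = "H_inv", check = FALSE)
}
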