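#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds \eqn{G = W W' / (2 \sum_l p_l (1 - p_l))}, where the column
#' l of W holds the centered genotypes \eqn{M_{il} - 2 p_l + 1} with
#' \eqn{M_{il} \in \{-1, 0, 1\}} and \eqn{p_l} the frequency of the
#' reference allele. Diagonal elements grow with homozygosity
#' (especially for rare alleles); off-diagonals grow with shared
#' homozygosity between the pair.
#'
#' @param geno a [geno_matrix()]; its stored allele frequencies are
#'   used (observed frequencies by default, or the fixed override
#'   supplied at construction).
#' @return A \code{rel_matrix} of kind \code{"G"}.
#' @export
makeG <- function(geno) {
  p <- geno$p
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic: VanRaden denominator ",
         "2*sum(p(1-p)) is zero")
  W <- sweep(geno$M, 2, 2 * p - 1, "-")
  G <- tcrossprod(W) / denom
  rel_matrix(G, ids = geno$ids, kind = "G", check = FALSE)
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' Returns \code{weight * G + (1 - weight) * A}, the standard ridge
#' used to guarantee an invertible G in single-step evaluations
#' (default 0.95 G + 0.05 A).
#'
#' @param G genomic \code{rel_matrix}.
#' @param A pedigree \code{rel_matrix} on the same ids in the same
#'   order (typically the genotyped block A22).
#' @param weight weight on G in [0, 1], default 0.95.
#' @return A \code{rel_matrix} of kind \code{"G"}.
#' @export
blendGA <- function(G, A, weight = 0.95) {
  stopifnot_same_ids(G, A)
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  rel_matrix(weight * rm_values(G) + (1 - weight) * rm_values(A),
             ids = rm_ids(G), kind = "G", check = FALSE)
}
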