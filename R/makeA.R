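#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: processing individuals in pedigree order,
#' \eqn{a_{ij} = (a_{js} + a_{jd})/2} for j preceding i, and
#' \eqn{a_{ii} = 1 + a_{sd}/2}, with unknown-parent terms dropped.
#' Diagonal elements equal 1 + F, where F is the inbreeding
#' coefficient.
#'
#' @param ped a [pedigree()] object (parents before offspring).
#' @return A \code{rel_matrix} of kind \code{"A"}.
#' @export
makeA <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  p <- parent_index(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$s[i]; d <- p$d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (s > 0) row <- row + A[s, j]
      if (d > 0) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  rel_matrix(A, ids = ped$id, kind = "A", check = FALSE)
}

#' Inbreeding coefficients from a pedigree
#'
#' F_i is half the additive relationship between the parents of i
#' (zero when either parent is unknown), evaluated exactly with the
#' tabular relationship table.
#'
#' @param ped a [pedigree()] object.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- makeA(ped)
  f <- diag(rm_values(A)) - 1
  names(f) <- ped$id
  f
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Builds A^-1 directly from the pedigree without inverting A: each
#' individual-sire-dam trio contributes to at most nine cells, scaled
#' by the inverse Mendelian-sampling variance
#' \eqn{d_i = 0.5 - 0.25 (F_s + F_d)} (both parents known),
#' \eqn{0.75 - 0.25 F_p} (one parent), or 1 (no parents).
#'
#' @param ped a [pedigree()] object.
#' @param use_inbreeding account for parental inbreeding in the
#'   Mendelian-sampling variances (default TRUE). With FALSE the
#'   classical rules for a non-inbred pedigree are applied, which no
#'   longer invert A exactly when the pedigree is inbred.
#' @return A \code{rel_matrix} of kind \code{"A_inv"}.
#' @export
makeAinv <- function(ped, use_inbreeding = TRUE) {
  validate_pedigree(ped)
  n <- nrow(ped)
  p <- parent_index(ped)
  f <- if (use_inbreeding) unname(inbreeding(ped)) else numeric(n)
  Ai <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$s[i]; d <- p$d[i]
    di <- if (s > 0 && d > 0) 0.5 - 0.25 * (f[s] + f[d])
          else if (s > 0) 0.75 - 0.25 * f[s]
          else if (d > 0) 0.75 - 0.25 * f[d]
          else 1
    b <- 1 / di
    Ai[i, i] <- Ai[i, i] + b
    for (q in c(s, d)) {
      if (q > 0) {
        Ai[i, q] <- Ai[i, q] - b / 2
        Ai[q, i] <- Ai[q, i] - b / 2
      }
    }
    if (s > 0) Ai[s, s] <- Ai[s, s] + b / 4
    if (d > 0) Ai[d, d] <- Ai[d, d] + b / 4
    if (s > 0 && d > 0) {
      Ai[s, d] <- Ai[s, d] + b / 4
      Ai[d, s] <- Ai[d, s] + b / 4
    }
  }
  rel_matrix(Ai, ids = ped$id, kind = "A_inv", check = FALSE)
}
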