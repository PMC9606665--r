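#' Invert a symmetric positive-definite relationship matrix
#'
#' Dense inversion via the Cholesky factor. Failure to factorize is
#' reported as a singularity error carrying the smallest eigenvalue,
#' rather than silently regularizing.
#'
#' @param K a \code{rel_matrix} (or plain symmetric matrix).
#' @return A \code{rel_matrix} holding the inverse; kind \code{"A"},
#'   \code{"G"}, \code{"H"} map to their \code{"*_inv"} tags (and back),
#'   anything else stays \code{"custom"}.
#' @export
invert_relmat <- function(K) {
  V <- rm_values(K)
  R <- tryCatch(chol(V), error = function(e) e)
  bad <- inherits(R, "error")
  if (!bad && nrow(V) > 0) {
    piv <- diag(R)^2
    bad <- min(piv) <= 1e-10 * max(piv)  # numerically rank-deficient
  }
  if (bad) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop("matrix is numerically singular / not positive definite ",
         "(smallest eigenvalue ", signif(ev, 4), "); cannot invert")
  }
  inv <- chol2inv(R)
  inv <- (inv + t(inv)) / 2
  kind <- rm_kind(K)
  inv_kind <- c(A = "A_inv", G = "G_inv", H = "H_inv",
                A_inv = "A", G_inv = "G", H_inv = "H",
                custom = "custom")[[kind]]
  rel_matrix(inv, ids = rm_ids(K), kind = inv_kind, check = FALSE)
}

#' Numerical-condition diagnostics for a relationship matrix
#'
#' Reports the extreme eigenvalues, the condition number, and whether
#' a Cholesky factorization succeeds. Alongside these direct
#' indicators it reports the indirect symptoms of an ill-conditioned K
#' visible in K^-1 when it exists: a negative or very large mean of
#' diag(K^-1) and very large standard deviations of its elements.
#' Diagnostics never raise an error.
#'
#' @param K a symmetric \code{rel_matrix} or plain matrix.
#' @return A list of class \code{condition_report}: \code{min_eigen},
#'   \code{max_eigen}, \code{condition_number}, \code{positive_definite},
#'   and (when invertible) \code{inv_diag_mean}, \code{inv_diag_sd},
#'   \code{inv_offdiag_sd}.
#' @export
condition_report <- function(K) {
  V <- rm_values(K)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  R <- tryCatch(chol(V), error = function(e) NULL)
  pd <- !is.null(R)
  if (pd && nrow(V) > 0) {
    piv <- diag(R)^2
    if (min(piv) <= 1e-10 * max(piv)) pd <- FALSE  # same guard as invert
  }
  out <- list(
    min_eigen = min(ev),
    max_eigen = max(ev),
    condition_number = if (min(ev) > 0) max(ev) / min(ev) else Inf,
    positive_definite = pd,
    inv_diag_mean = NA_real_,
    inv_diag_sd = NA_real_,
    inv_offdiag_sd = NA_real_
  )
  if (pd) {
    inv <- chol2inv(R)
    d <- diag(inv)
    off <- inv[upper.tri(inv)]
    out$inv_diag_mean <- mean(d)
    out$inv_diag_sd <- stats::sd(d)
    out$inv_offdiag_sd <- if (length(off) > 1) stats::sd(off) else NA_real_
  }
  class(out) <- "condition_report"
  out
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf(
    "eigenvalues [%.4g, %.4g], condition %.4g, PD: %s\n",
    x$min_eigen, x$max_eigen, x$condition_number, x$positive_definite))
  if (x$positive_definite)
    cat(sprintf("inverse diag: mean %.4g, sd %.4g; offdiag sd %.4g\n",
                x$inv_diag_mean, x$inv_diag_sd, x$inv_offdiag_sd))
  invisible(x)
}
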