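#' Distribution summary of relationship-matrix elements
#'
#' Summarizes the diagonal and the off-diagonal elements of K (each
#' unordered pair counted once, i.e. the upper triangle), including
#' \eqn{D = \mu(diag) - \mu(offdiag)} — the distribution parameter
#' governing the base-population genetic variance — and the fraction
#' of off-diagonal elements inside a band around zero. Standard
#' deviations are sample (n-1) standard deviations.
#'
#' @param K square \code{rel_matrix} or plain matrix.
#' @param band two-element interval for the off-diagonal
#'   concentration, default \code{c(-0.02, 0.02)} (open interval).
#' @return List of class \code{element_summary}: \code{mu_diag},
#'   \code{sd_diag}, \code{min_diag}, \code{max_diag},
#'   \code{mu_offdiag}, \code{sd_offdiag}, \code{min_offdiag},
#'   \code{max_offdiag}, \code{D}, \code{band_fraction}, \code{band}.
#' @export
element_summary <- function(K, band = c(-0.02, 0.02)) {
  V <- rm_values(K)
  if (nrow(V) != ncol(V)) stop("K must be square")
  d <- diag(V)
  off <- V[upper.tri(V)]
  sdv <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  out <- list(
    mu_diag = mean(d), sd_diag = sdv(d),
    min_diag = min(d), max_diag = max(d),
    mu_offdiag = if (length(off)) mean(off) else NA_real_,
    sd_offdiag = sdv(off),
    min_offdiag = if (length(off)) min(off) else NA_real_,
    max_offdiag = if (length(off)) max(off) else NA_real_,
    D = mean(d) - if (length(off)) mean(off) else 0,
    band_fraction = if (length(off))
      mean(off > band[1] & off < band[2]) else NA_real_,
    band = band
  )
  class(out) <- "element_summary"
  out
}

#' @export
print.element_summary <- function(x, ...) {
  cat(sprintf("diag:    %.4f +/- %.4f  [%.4f, %.4f]\n",
              x$mu_diag, x$sd_diag, x$min_diag, x$max_diag))
  cat(sprintf("offdiag: %.4f +/- %.4f  [%.4f, %.4f]\n",
              x$mu_offdiag, x$sd_offdiag, x$min_offdiag, x$max_offdiag))
  cat(sprintf("D = %.4f;  %.2f%% of offdiag in (%g, %g)\n",
              x$D, 100 * x$band_fraction, x$band[1], x$band[2]))
  invisible(x)
}

#' Compare two sets of breeding values
#'
#' Pearson correlation and the least-squares regression slope of the
#' comparison EBVs on the reference EBVs (slope > 1 means the
#' comparison set is more dispersed; slope below the correlation means
#' its variance shrank).
#'
#' @param reference baseline \code{ebv_result} or named numeric vector.
#' @param comparison \code{ebv_result} or named vector on the same ids.
#' @return List of class \code{ebv_comparison}: \code{pearson_r},
#'   \code{slope}, \code{mean_ref}, \code{sd_ref}, \code{mean_cmp},
#'   \code{sd_cmp}, \code{n}.
#' @export
ebv_compare <- function(reference, comparison) {
  r <- if (inherits(reference, "ebv_result")) reference$ebv else reference
  c_ <- if (inherits(comparison, "ebv_result")) comparison$ebv else comparison
  if (!is.null(names(r)) && !is.null(names(c_))) {
    if (!setequal(names(r), names(c_)))
      stop("EBV sets are not over the same ids")
    c_ <- c_[names(r)]
  } else if (length(r) != length(c_)) {
    stop("EBV sets differ in length and carry no names to align by")
  }
  vr <- stats::var(r)
  vc <- stats::var(c_)
  if (!is.finite(vr) || vr == 0 || !is.finite(vc) || vc == 0)
    stop("zero variance in an EBV set; correlation/slope undefined")
  structure(list(
    pearson_r = stats::cor(r, c_),
    slope = stats::cov(r, c_) / vr,
    mean_ref = mean(r), sd_ref = sqrt(vr),
    mean_cmp = mean(c_), sd_cmp = sqrt(vc),
    n = length(r)
  ), class = "ebv_comparison")
}

#' @export
print.ebv_comparison <- function(x, ...) {
  cat(sprintf("<ebv_comparison: r = %.4f, slope = %.4f, n = %d>\n",
              x$pearson_r, x$slope, x$n))
  invisible(x)
}

#' Discard rows/columns of K^-1 with extreme elements
#'
#' Removes, in a single pass over the original matrix, every
#' individual whose diagonal element exceeds \code{diag_gt} or that
#' participates in any off-diagonal element below \code{offdiag_lt},
#' together with its phenotype record.
#'
#' @param K_inv inverse relationship matrix.
#' @param phen optional phenotype data frame filtered alongside.
#' @param diag_gt diagonal threshold (default \code{Inf}: no removal).
#' @param offdiag_lt off-diagonal threshold (default \code{-Inf}).
#' @return List with \code{K_inv}, \code{phen}, and \code{removed}
#'   (character vector of discarded ids).
#' @export
discard_extreme <- function(K_inv, phen = NULL, diag_gt = Inf,
                            offdiag_lt = -Inf) {
  V <- rm_values(K_inv)
  ids <- rm_ids(K_inv)
  off <- V
  diag(off) <- NA
  hit_diag <- diag(V) > diag_gt
  hit_off <- apply(off < offdiag_lt, 1, any, na.rm = TRUE)
  drop_i <- hit_diag | hit_off
  if (all(drop_i))
    stop("thresholds remove every row/column of K^-1")
  removed <- ids[drop_i]
  keep <- ids[!drop_i]
  out_K <- rel_matrix(V[!drop_i, !drop_i, drop = FALSE], ids = keep,
                      kind = rm_kind(K_inv), check = FALSE)
  out_phen <- NULL
  if (!is.null(phen)) {
    phen <- as_phenotypes(phen)
    out_phen <- phen[phen$id %in% keep, , drop = FALSE]
  }
  list(K_inv = out_K, phen = out_phen, removed = removed)
}
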