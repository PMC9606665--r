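#' Default transformation grid
#'
#' The factorial grid w in \{0.9, 1, 1.1\}, alpha in \{-0.05, 0, 0.05\},
#' beta in \{-0.05, 0, 0.05\}. For a pedigree matrix A two regions are
#' marked excluded rather than run: alpha = -0.05 (negative
#' off-diagonals would result, A being a 1-tailed matrix with minimum
#' off-diagonal 0) and alpha = 0 with beta = -0.05 (diagonals would
#' drop below the minimum of 1).
#'
#' @param kind matrix kind; exclusions are applied when it is
#'   \code{"A"} (or \code{"A_inv"} when \code{exclude_A} is left NULL).
#' @param w,alpha,beta grid levels.
#' @param exclude_A force the A exclusions on or off (NULL = decide
#'   from \code{kind}).
#' @return data.frame with columns \code{w}, \code{alpha}, \code{beta},
#'   \code{excluded}.
#' @export
default_grid <- function(kind = "custom", w = c(0.9, 1, 1.1),
                         alpha = c(-0.05, 0, 0.05),
                         beta = c(-0.05, 0, 0.05),
                         exclude_A = NULL) {
  g <- expand.grid(w = w, alpha = alpha, beta = beta,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$w, g$alpha, g$beta), , drop = FALSE]
  rownames(g) <- NULL
  if (is.null(exclude_A)) exclude_A <- kind %in% c("A", "A_inv")
  g$excluded <- if (exclude_A)
    g$alpha == -0.05 | (g$alpha == 0 & g$beta == -0.05)
  else rep(FALSE, nrow(g))
  g
}

#' Transformation grid over K: element distributions and heritability
#'
#' For every non-excluded grid cell, forms K* = wK + alpha 11' + beta I,
#' checks its numerical condition, inverts it when positive definite,
#' summarizes the elements of (K*)^-1, and re-estimates the variance
#' components by REML with the transformed matrix. Singular or
#' non-positive-definite cells are reported as rows with condition
#' diagnostics, not errors; only a singular baseline (w = 1, alpha = 0,
#' beta = 0) is fatal.
#'
#' @param K relationship matrix.
#' @param phen phenotype data frame (\code{id}, \code{value}).
#' @param grid a [default_grid()]-style data.frame; defaults to the
#'   standard grid for \code{K}'s kind.
#' @param band off-diagonal concentration interval, default
#'   \code{c(-0.02, 0.02)}.
#' @param ... passed to [reml_estimate()].
#' @return data.frame, one row per grid cell: the spec, exclusion and
#'   positive-definiteness flags, smallest eigenvalue, the
#'   [element_summary()] fields of (K*)^-1, and \code{h2},
#'   \code{sigma2_g}, \code{sigma2_e}.
#' @export
run_K_grid <- function(K, phen, grid = NULL, band = c(-0.02, 0.02), ...) {
  if (is.null(grid)) grid <- default_grid(rm_kind(K))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    base_row <- data.frame(kind = rm_kind(K), w = row$w,
                           alpha = row$alpha, beta = row$beta,
                           excluded = row$excluded, pd = NA,
                           min_eigen = NA_real_,
                           mu_diag = NA_real_, sd_diag = NA_real_,
                           mu_offdiag = NA_real_, sd_offdiag = NA_real_,
                           D = NA_real_, band_fraction = NA_real_,
                           h2 = NA_real_, sigma2_g = NA_real_,
                           sigma2_e = NA_real_)
    if (row$excluded) return(base_row)
    Kstar <- transformK(K, transform_spec(row$w, row$alpha, row$beta))
    cond <- condition_report(Kstar)
    base_row$pd <- cond$positive_definite
    base_row$min_eigen <- cond$min_eigen
    is_baseline <- row$w == 1 && row$alpha == 0 && row$beta == 0
    if (!cond$positive_definite) {
      if (is_baseline) stop("baseline K is not positive definite")
      return(base_row)
    }
    Kinv <- invert_relmat(Kstar)
    s <- element_summary(Kinv, band)
    base_row[c("mu_diag", "sd_diag", "mu_offdiag", "sd_offdiag",
               "D", "band_fraction")] <-
      s[c("mu_diag", "sd_diag", "mu_offdiag", "sd_offdiag",
          "D", "band_fraction")]
    fit <- tryCatch(suppressWarnings(
      reml_estimate(K_inv = Kinv, phen = phen, ...)),
      error = function(e) NULL)
    if (is.null(fit) && is_baseline)
      stop("REML failed on the baseline K")
    if (!is.null(fit)) {
      base_row$h2 <- fit$h2
      base_row$sigma2_g <- fit$sigma2_g
      base_row$sigma2_e <- fit$sigma2_e
    }
    base_row
  })
  do.call(rbind, out)
}

#' Transformation grid over K^-1: heritability and EBV stability
#'
#' The baseline K^-1 is fitted by REML and its EBVs predicted. Every
#' non-excluded cell then transforms K^-1 itself, and two analyses are
#' run: (a) EBV prediction using the baseline heritability, compared
#' with the baseline EBVs by Pearson correlation and the regression
#' slope of the cell EBVs on the baseline ones; (b) a fresh REML fit
#' with the transformed matrix as the inverse-relationship input (its
#' own h2), whose EBVs are compared the same way — for a pure
#' reweighting (alpha = beta = 0) the own-h2 EBVs reproduce the
#' baseline exactly.
#'
#' @param K_inv baseline inverse relationship matrix (positive
#'   definite).
#' @param phen phenotype data frame.
#' @param grid as in [run_K_grid()]; defaults to the grid for the
#'   matrix kind.
#' @param ... passed to [reml_estimate()].
#' @return data.frame, one row per cell: spec columns, \code{h2_own},
#'   \code{sigma2_g_own}, \code{r}, \code{slope} (baseline-h2
#'   analysis), \code{r_own}, \code{slope_own}, plus the baseline
#'   \code{h2_baseline} replicated for reference.
#' @export
run_Kinv_grid <- function(K_inv, phen, grid = NULL, ...) {
  if (is.null(grid)) grid <- default_grid(rm_kind(K_inv))
  base_fit <- reml_estimate(K_inv = K_inv, phen = phen, ...)
  ebv0 <- predict_ebv(K_inv, phen, lambda = base_fit$lambda)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    res <- data.frame(kind = rm_kind(K_inv), w = row$w,
                      alpha = row$alpha, beta = row$beta,
                      excluded = row$excluded,
                      h2_baseline = base_fit$h2,
                      h2_own = NA_real_, sigma2_g_own = NA_real_,
                      r = NA_real_, slope = NA_real_,
                      r_own = NA_real_, slope_own = NA_real_)
    if (row$excluded) return(res)
    Kistar <- transformK(K_inv, transform_spec(row$w, row$alpha, row$beta))
    ebv_b <- tryCatch(
      predict_ebv(Kistar, phen, lambda = base_fit$lambda),
      error = function(e) NULL)
    if (!is.null(ebv_b)) {
      cmp <- ebv_compare(ebv0, ebv_b)
      res$r <- cmp$pearson_r
      res$slope <- cmp$slope
    }
    fit <- tryCatch(suppressWarnings(
      reml_estimate(K_inv = Kistar, phen = phen, ...)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$sigma2_g > 0) {
      res$h2_own <- fit$h2
      res$sigma2_g_own <- fit$sigma2_g
      ebv_o <- tryCatch(predict_ebv(Kistar, phen, lambda = fit$lambda),
                        error = function(e) NULL)
      if (!is.null(ebv_o)) {
        cmp_o <- ebv_compare(ebv0, ebv_o)
        res$r_own <- cmp_o$pearson_r
        res$slope_own <- cmp_o$slope
      }
    }
    res
  })
  do.call(rbind, out)
}

#' Pivot a grid table into the w-by-beta layout of the result tables
#'
#' @param tab output of [run_K_grid()] or [run_Kinv_grid()].
#' @param metric column to pivot (e.g. \code{"h2"}, \code{"r"},
#'   \code{"slope"}).
#' @return data.frame with rows (w, alpha) and one column per beta
#'   level.
#' @export
grid_pivot <- function(tab, metric = "h2") {
  if (!metric %in% names(tab)) stop("no column '", metric, "' in table")
  betas <- sort(unique(tab$beta))
  rows <- unique(tab[, c("w", "alpha")])
  rows <- rows[order(rows$w, rows$alpha), , drop = FALSE]
  out <- rows
  for (b in betas) {
    v <- vapply(seq_len(nrow(rows)), function(i) {
      hit <- tab$w == rows$w[i] & tab$alpha == rows$alpha[i] &
        tab$beta == b
      if (any(hit)) tab[[metric]][which(hit)[1]] else NA_real_
    }, numeric(1))
    out[[sprintf("beta=%g", b)]] <- v
  }
  rownames(out) <- NULL
  out
}
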