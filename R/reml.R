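#' Variance components
#'
#' Container for the two variance components of the animal model and
#' their derived quantities.
#'
#' @param sigma2_g additive genetic variance (>= 0).
#' @param sigma2_e residual variance (>= 0).
#' @param n_iter,converged,trajectory optional fitting metadata.
#' @return List of class \code{varcomp} with \code{sigma2_g},
#'   \code{sigma2_e}, \code{h2}, \code{lambda} plus metadata.
#' @export
varcomp <- function(sigma2_g, sigma2_e, n_iter = NA_integer_,
                    converged = NA, trajectory = NULL) {
  if (sigma2_g < 0 || sigma2_e < 0)
    stop("variance components must be non-negative")
  vp <- sigma2_g + sigma2_e
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = if (vp > 0) sigma2_g / vp else NA_real_,
                 lambda = if (sigma2_g > 0) sigma2_e / sigma2_g else Inf,
                 n_iter = n_iter, converged = converged,
                 trajectory = trajectory),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "<varcomp: sigma2_g = %.6g, sigma2_e = %.6g, h2 = %.4f, lambda = %.4f",
    x$sigma2_g, x$sigma2_e, x$h2, x$lambda))
  if (!is.na(x$n_iter))
    cat(sprintf(", %d iterations%s", x$n_iter,
                if (isTRUE(x$converged)) "" else " (NOT converged)"))
  cat(">\n")
  invisible(x)
}

#' REML for the single-trait animal model
#'
#' Estimates \eqn{\sigma^2_g} and \eqn{\sigma^2_e} of
#' \eqn{y = X\mu + Zu + e}, \eqn{u \sim (0, K\sigma^2_g)},
#' \eqn{e \sim (0, I\sigma^2_e)}. With a single variance ratio
#' \eqn{\lambda = \sigma^2_e/\sigma^2_g} the REML criterion profiles
#' to a one-dimensional function of \eqn{\lambda},
#' \deqn{f(\lambda) = (N - p)\,\log \hat\sigma^2_e(\lambda)
#'   - q \log \lambda + \log|M(\lambda)| + const,}
#' where \eqn{M(\lambda)} is the mixed-model coefficient matrix,
#' \eqn{\hat\sigma^2_e(\lambda) = y'(y - X\hat b - Z\hat u)/(N - p)},
#' \eqn{q} the matrix dimension and \eqn{p = 1} fixed effect (the
#' mean). The fit runs expectation-maximization updates to get near
#' the optimum, then polishes with Newton steps on the analytic
#' profile gradient
#' \eqn{f'(\lambda) = (N-p)\,\hat u'K^{-1}\hat u / (y'\hat e)
#'   - q/\lambda + tr(K^{-1} C^{uu})}.
#' All quantities involve only K^-1, so a transformed inverse can be
#' supplied directly via \code{K_inv} without ever forming K.
#'
#' @param K relationship matrix (positive definite); ignored when
#'   \code{K_inv} is given.
#' @param phen phenotype data frame (\code{id}, \code{value}).
#' @param K_inv inverse relationship matrix used directly in the
#'   equations.
#' @param init_h2 starting heritability splitting the phenotypic
#'   variance (default 0.5).
#' @param tol convergence threshold on the relative change of lambda
#'   (default 1e-8; the Newton polish typically lands far inside it).
#' @param max_iter cap on EM iterations before/without acceleration
#'   (default 500).
#' @param accelerate use the Newton polish in the EM path (default
#'   TRUE); FALSE runs plain EM to \code{tol}.
#' @param method \code{"eigen"} marginalizes to the phenotyped block
#'   of K and profiles the criterion through one eigendecomposition
#'   (fast, requires an invertible K and single records);
#'   \code{"em"} runs the expectation-maximization/Newton iteration
#'   on the mixed model equations, which only needs K^-1 and accepts
#'   indefinite transformed inverses. \code{"auto"} (default) picks
#'   \code{"eigen"} when possible. Both reach the same stationary
#'   point.
#' @return A [varcomp()] with iteration metadata; per-iteration
#'   component values are kept in \code{$trajectory}.
#' @details A genetic variance collapsing below 1e-8 of the phenotypic
#' variance is clamped to the zero boundary with a warning.
#' Non-convergence raises an error reporting the trajectory tail.
#' @export
reml_estimate <- function(K = NULL, phen, K_inv = NULL, init_h2 = 0.5,
                          tol = 1e-8, max_iter = 500L,
                          accelerate = TRUE,
                          method = c("auto", "eigen", "em")) {
  method <- match.arg(method)
  if (is.null(K) && is.null(K_inv)) stop("supply K or K_inv")
  phen0 <- as_phenotypes(phen)
  if (method != "em") {
    # marginalize to the phenotyped subset and diagonalize K_obs once;
    # the profile REML criterion is then O(n) per lambda evaluation
    K_obs <- NULL
    if (!is.null(K)) {
      K_obs <- tryCatch(rm_align(K, unique(phen0$id)),
                        error = function(e) NULL)
    } else {
      Kfull <- tryCatch(invert_relmat(K_inv), error = function(e) NULL)
      if (!is.null(Kfull))
        K_obs <- tryCatch(rm_align(Kfull, unique(phen0$id)),
                          error = function(e) NULL)
    }
    if (!is.null(K_obs) && !anyDuplicated(phen0$id))
      return(reml_eigen(K_obs, phen0, tol = tol))
    if (method == "eigen")
      stop("eigen method needs an invertible K (or K_inv) and at most ",
           "one record per individual")
  }
  if (is.null(K_inv)) K_inv <- invert_relmat(K)
  phen <- phen0
  vp <- stats::var(phen$value)
  if (!is.finite(vp) || vp <= 0)
    stop("phenotypic variance must be positive")
  q <- nrow(K_inv)
  N <- nrow(phen)
  Ki <- rm_values(K_inv)
  sys0 <- build_mme(K_inv, phen, lambda = 1)
  ZtZ <- crossprod(sys0$Z)
  nf <- sys0$n_fixed
  uidx <- nf + seq_len(q)

  # one pass at a given lambda: solutions, EM updates, profile gradient
  eval_at <- function(lambda, s2e_cur) {
    LHS <- sys0$LHS
    LHS[uidx, uidx] <- ZtZ + lambda * Ki
    R <- tryCatch(chol(LHS), error = function(e) NULL)
    C <- if (is.null(R)) MASS::ginv(LHS) else chol2inv(R)
    sol <- drop(C %*% sys0$RHS)
    b <- sol[seq_len(nf)]
    u <- sol[uidx]
    Cuu <- C[uidx, uidx]
    uKu <- drop(crossprod(u, Ki %*% u))
    trKC <- sum(Ki * Cuu)
    ye <- drop(crossprod(sys0$y,
                         sys0$y - b[1] - drop(sys0$Z %*% u)))
    list(u = u, b = b, uKu = uKu, trKC = trKC, ye = ye,
         s2e = ye / (N - nf),
         s2g_em = (uKu + trKC * s2e_cur) / q,
         grad = (N - nf) * uKu / ye - q / lambda + trKC)
  }

  s2g <- init_h2 * vp
  s2e <- (1 - init_h2) * vp
  traj <- list()
  it <- 0L
  converged <- FALSE
  boundary <- FALSE
  em_tol <- if (accelerate) max(tol, 1e-3) else tol
  em_iter <- if (accelerate) min(max_iter, 200L) else max_iter
  ev <- NULL
  while (it < em_iter) {
    it <- it + 1L
    ev <- eval_at(s2e / s2g, s2e)
    s2g_new <- ev$s2g_em
    s2e_new <- ev$s2e
    traj[[it]] <- c(sigma2_g = s2g_new, sigma2_e = s2e_new)
    if (!is.finite(s2g_new) || s2g_new < 1e-8 * vp) {
      warning("genetic variance hit the zero boundary; clamped")
      s2g <- 0; s2e <- s2e_new
      boundary <- TRUE; converged <- TRUE
      break
    }
    delta <- max(abs(s2g_new - s2g) / s2g, abs(s2e_new - s2e) / s2e)
    s2g <- s2g_new; s2e <- s2e_new
    if (delta < em_tol) { converged <- TRUE; break }
  }

  if (!boundary && accelerate && is.finite(s2g) && s2g > 0) {
    # Newton on the analytic profile gradient in lambda
    lam <- s2e / s2g
    polished <- FALSE
    for (k in seq_len(60L)) {
      ev <- eval_at(lam, s2e)
      g <- ev$grad
      h <- max(1e-8, 1e-6 * lam)
      g2 <- eval_at(lam + h, s2e)$grad
      fpp <- (g2 - g) / h
      step <- if (is.finite(fpp) && fpp > 0) -g / fpp else -g * lam * 0.1
      step <- max(min(step, lam * 0.9), -lam * 0.9)  # safeguard
      lam_new <- lam + step
      it <- it + 1L
      if (!is.finite(lam_new) || lam_new <= 0) break
      rel <- abs(lam_new - lam) / lam
      lam <- lam_new
      if (rel < tol) { polished <- TRUE; break }
    }
    if (polished || converged) {
      ev <- eval_at(lam, s2e)
      s2e <- ev$s2e
      s2g <- s2e / lam
      traj[[length(traj) + 1L]] <- c(sigma2_g = s2g, sigma2_e = s2e)
      converged <- TRUE
      if (s2g < 1e-8 * vp) {
        warning("genetic variance hit the zero boundary; clamped")
        s2g <- 0
      }
    }
  }

  traj <- do.call(rbind, traj)
  if (!converged)
    stop("REML did not converge in ", max_iter, " iterations; ",
         "last iterates: ",
         paste(apply(utils::tail(traj, 3), 1, function(r)
           sprintf("(%.6g, %.6g)", r[1], r[2])), collapse = " "))
  varcomp(s2g, s2e, n_iter = it, converged = converged,
          trajectory = traj)
}

# Profile REML via one eigendecomposition of the phenotyped block of K.
# Rotating y and the intercept by the eigenvectors makes V diagonal, so
# every lambda evaluation is O(n); Brent locates the optimum and Newton
# steps on the analytic profile gradient polish it.
reml_eigen <- function(K_obs, phen, tol = 1e-8) {
  ids <- rm_ids(K_obs)
  y <- phen$value[match(ids, phen$id)]
  n <- length(y)
  vp <- stats::var(y)
  if (!is.finite(vp) || vp <= 0)
    stop("phenotypic variance must be positive")
  es <- eigen(rm_values(K_obs), symmetric = TRUE)
  d <- pmax(es$values, 0)
  yt <- drop(crossprod(es$vectors, y))
  xt <- drop(crossprod(es$vectors, rep(1, n)))
  p <- 1L
  nev <- 0L

  parts <- function(lam) {
    D <- d + lam
    b <- sum(xt * yt / D)
    cc <- sum(xt^2 / D)
    q <- sum(yt^2 / D) - b^2 / cc
    list(D = D, b = b, cc = cc, q = q)
  }
  f <- function(t) {
    nev <<- nev + 1L
    lam <- exp(t)
    pt <- parts(lam)
    if (pt$q <= 0 || pt$cc <= 0) return(Inf)
    (n - p) * log(pt$q) + sum(log(pt$D)) + log(pt$cc)
  }
  fprime <- function(lam) {
    pt <- parts(lam)
    D <- pt$D
    s2y <- sum(yt^2 / D^2)
    sxy <- sum(xt * yt / D^2)
    sxx <- sum(xt^2 / D^2)
    qp <- -s2y + 2 * pt$b * sxy / pt$cc - pt$b^2 * sxx / pt$cc^2
    (n - p) * qp / pt$q + sum(1 / D) - sxx / pt$cc
  }

  lo <- log(1e-8); hi <- log(1e8)
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-9)
  lam <- exp(opt$minimum)
  boundary_hi <- opt$minimum > hi - 0.05
  boundary_lo <- opt$minimum < lo + 0.05
  if (!boundary_hi && !boundary_lo) {
    for (k in seq_len(30L)) {
      g <- fprime(lam)
      h <- max(1e-10, 1e-6 * lam)
      fpp <- (fprime(lam + h) - g) / h
      nev <- nev + 2L
      step <- if (is.finite(fpp) && fpp > 0) -g / fpp else 0
      step <- max(min(step, lam * 0.5), -lam * 0.5)
      lam_new <- lam + step
      if (!is.finite(lam_new) || lam_new <= 0) break
      rel <- abs(lam_new - lam) / lam
      lam <- lam_new
      if (rel < tol) break
    }
  }
  pt <- parts(lam)
  s2g <- pt$q / (n - p)
  s2e <- lam * s2g
  if (boundary_hi || s2g < 1e-8 * vp) {
    warning("genetic variance hit the zero boundary; clamped")
    s2g <- 0
    s2e <- stats::var(y)
  }
  varcomp(s2g, s2e, n_iter = nev, converged = TRUE)
}

#' Write variance components as key-value YAML-style text
#' @param vc a \code{varcomp}.
#' @param file output path.
#' @export
write_varcomp <- function(vc, file) {
  lines <- c(
    sprintf("sigma2_g: %.10g", vc$sigma2_g),
    sprintf("sigma2_e: %.10g", vc$sigma2_e),
    sprintf("h2: %.10g", vc$h2),
    sprintf("lambda: %.10g", vc$lambda),
    sprintf("n_iter: %d", vc$n_iter),
    sprintf("converged: %s", tolower(as.character(vc$converged)))
  )
  writeLines(lines, file)
}
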