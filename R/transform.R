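#' Transformation specification w, alpha, beta
#'
#' The study transformation of a relationship matrix (or of its
#' inverse): \deqn{K^* = w K + \alpha 11' + \beta I.} \code{w} rescales
#' the matrix (and with it the base-population genetic variance),
#' \code{alpha} re-bases every element, and \code{beta} re-bases the
#' diagonal only, so that
#' \eqn{\mu(diag) - \mu(offdiag)} changes by exactly
#' \eqn{w \cdot D + \beta}.
#'
#' @param w positive scale factor (default 1).
#' @param alpha shift added to every element (default 0).
#' @param beta shift added to the diagonal (default 0).
#' @return A list of class \code{transform_spec}.
#' @export
transform_spec <- function(w = 1, alpha = 0, beta = 0) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0)
    stop("w must be a single positive number")
  structure(list(w = w, alpha = alpha, beta = beta),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform: w=%g, alpha=%g, beta=%g>\n",
              x$w, x$alpha, x$beta))
  invisible(x)
}

#' Apply K* = wK + alpha 11' + beta I
#'
#' Never mutates its input; the result is tagged \code{"custom"} so
#' downstream code cannot assume A/G/H semantics for the transformed
#' matrix.
#'
#' @param K square symmetric \code{rel_matrix} (or plain matrix).
#' @param spec a [transform_spec()], or w/alpha/beta passed directly.
#' @param w,alpha,beta used when \code{spec} is missing.
#' @return Transformed \code{rel_matrix} of kind \code{"custom"}.
#' @export
transformK <- function(K, spec = NULL, w = 1, alpha = 0, beta = 0) {
  if (is.null(spec)) spec <- transform_spec(w, alpha, beta)
  V <- rm_values(K)
  out <- spec$w * V + spec$alpha
  diag(out) <- diag(out) + spec$beta
  rel_matrix(out, ids = rm_ids(K), kind = "custom", check = FALSE)
}

#' SQS decomposition of a covariance matrix
#'
#' Writes K = S Q S with S the diagonal matrix of standard deviations
#' (sqrt of diag(K)) and Q the correlation matrix. Adding
#' \eqn{\alpha 11' + \beta I} to K turns S^2 into
#' \eqn{S^2 + (\alpha+\beta) I} while distorting Q; positive alpha and
#' negative beta push correlations toward +/-1 and the matrix toward
#' singularity.
#'
#' @param K \code{rel_matrix} with strictly positive diagonal.
#' @return List of class \code{sqs} with \code{S} (named vector of
#'   standard deviations) and \code{Q} (correlation matrix).
#' @export
sqs_decompose <- function(K) {
  V <- rm_values(K)
  d <- diag(V)
  if (any(d <= 0))
    stop("SQS decomposition requires a strictly positive diagonal")
  S <- sqrt(d)
  Q <- V / tcrossprod(S)
  diag(Q) <- 1
  structure(list(S = stats::setNames(S, rm_ids(K)), Q = Q),
            class = "sqs")
}
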