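#' Assemble the mixed model equations
#'
#' For the single-trait animal model \eqn{y = X\mu + Zu + e} with the
#' overall mean as the only fixed effect, builds
#' \deqn{LHS = \begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + K^{-1}\lambda
#' \end{pmatrix}, \quad RHS = \begin{pmatrix} X'y \\ Z'y \end{pmatrix}}
#' where \eqn{\lambda = \sigma^2_e / \sigma^2_g = (1-h^2)/h^2}.
#' Individuals without phenotypes stay in the equations; their
#' solutions flow through K^-1.
#'
#' @param K_inv inverse relationship matrix (\code{rel_matrix}) over
#'   all individuals in the evaluation.
#' @param phen phenotype data frame with columns \code{id},
#'   \code{value}; every id must be indexed by \code{K_inv}.
#' @param lambda positive variance ratio.
#' @return List of class \code{mme_system}: \code{LHS}, \code{RHS},
#'   \code{ids}, \code{n_records}, \code{n_fixed}, \code{y}.
#' @export
build_mme <- function(K_inv, phen, lambda) {
  phen <- as_phenotypes(phen)
  if (nrow(phen) == 0) stop("no phenotype records")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a single positive number")
  ids <- rm_ids(K_inv)
  miss <- setdiff(phen$id, ids)
  if (length(miss) > 0)
    stop("phenotyped ids absent from K^-1: ",
         paste(utils::head(miss, 5), collapse = ", "))
  q <- length(ids)
  n <- nrow(phen)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), match(phen$id, ids))] <- 1
  y <- phen$value
  XtX <- matrix(n, 1, 1)
  XtZ <- matrix(colSums(Z), 1, q)
  ZtZ <- crossprod(Z)
  LHS <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + lambda * rm_values(K_inv)))
  RHS <- c(sum(y), crossprod(Z, y))
  structure(list(LHS = LHS, RHS = RHS, ids = ids, n_records = n,
                 n_fixed = 1L, y = y, Z = Z),
            class = "mme_system")
}

#' Solve the mixed model equations
#'
#' Direct dense solve of the assembled system; if the coefficient
#' matrix is numerically singular a generalized (Moore-Penrose)
#' solution is used as fallback and flagged.
#'
#' @param system an [build_mme()] system.
#' @return List of class \code{ebv_result}: \code{fixed} (estimate of
#'   the mean), \code{ebv} (named vector of breeding values),
#'   \code{relative_residual} of the linear solve, and
#'   \code{generalized} (logical).
#' @export
solve_mme <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  sol <- tryCatch(solve(system$LHS, system$RHS), error = function(e) NULL)
  generalized <- FALSE
  if (is.null(sol)) {
    sol <- drop(MASS::ginv(system$LHS) %*% system$RHS)
    generalized <- TRUE
  }
  res <- system$LHS %*% sol - system$RHS
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(system$RHS^2)), 1e-300)
  nf <- system$n_fixed
  ebv <- sol[-seq_len(nf)]
  names(ebv) <- system$ids
  structure(list(fixed = sol[seq_len(nf)], ebv = ebv,
                 relative_residual = rel, generalized = generalized),
            class = "ebv_result")
}

#' @export
print.ebv_result <- function(x, ...) {
  cat(sprintf("<ebv_result: mean = %.6g, %d breeding values, sd(EBV) = %.6g>\n",
              x$fixed[1], length(x$ebv), stats::sd(x$ebv)))
  invisible(x)
}

#' Predict breeding values for a given K^-1 and heritability
#'
#' Convenience wrapper assembling and solving the mixed model
#' equations with \eqn{\lambda = (1-h^2)/h^2}.
#'
#' @param K_inv inverse relationship matrix.
#' @param phen phenotype data frame (\code{id}, \code{value}).
#' @param h2 heritability in (0, 1); alternatively supply
#'   \code{lambda} directly.
#' @param lambda optional variance ratio overriding \code{h2}.
#' @return An \code{ebv_result}.
#' @export
predict_ebv <- function(K_inv, phen, h2 = NULL, lambda = NULL) {
  if (is.null(lambda)) {
    if (is.null(h2) || h2 <= 0 || h2 >= 1)
      stop("supply h2 in (0,1) or a positive lambda")
    lambda <- (1 - h2) / h2
  }
  solve_mme(build_mme(K_inv, phen, lambda))
}

as_phenotypes <- function(phen) {
  if (inherits(phen, "sim_population")) phen <- phen$phenotypes
  phen <- as.data.frame(phen)
  if (!all(c("id", "value") %in% names(phen))) {
    if (ncol(phen) >= 2) names(phen)[1:2] <- c("id", "value")
    else stop("phenotypes need columns id, value")
  }
  phen$id <- as.character(phen$id)
  phen$value <- as.numeric(phen$value)
  phen <- phen[!is.na(phen$value), c("id", "value")]
  phen
}

#' Read phenotypes from CSV (columns id, value; missing rows absent)
#' @param file path.
#' @return data.frame with columns \code{id}, \code{value}.
#' @export
read_phenotypes <- function(file) {
  df <- utils::read.csv(file, colClasses = c("character", "numeric"))
  as_phenotypes(df)
}

#' Write breeding values as a two-column TSV (id, ebv)
#' @param ebv an \code{ebv_result} or named numeric vector.
#' @param file output path.
#' @export
write_ebv <- function(ebv, file) {
  if (inherits(ebv, "ebv_result")) ebv <- ebv$ebv
  utils::write.table(data.frame(id = names(ebv), ebv = as.numeric(ebv)),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
}
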