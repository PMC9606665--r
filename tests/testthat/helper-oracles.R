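# Independent oracles and generators used across the test files.
# Everything here is deliberately written without reusing the package's
# own construction code paths.

# Recursive-kinship oracle: additive relationship a(i, j) evaluated by
# the classical recurrence, memoized in an environment.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  s <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  d <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  memo <- new.env(hash = TRUE)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      1 + 0.5 * a(s[i], d[i])
    } else {
      # j precedes i in a topological order
      0.5 * (a(s[i], j) + a(d[i], j))
    }
    memo[[key]] <- val
    val
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    M[i, j] <- M[j, i] <- a(i, j)
  }
  dimnames(M) <- list(ped$id, ped$id)
  M
}

# Random topologically ordered pedigree: nf founders, then individuals
# drawing parents (possibly unknown) among earlier ones of the right sex.
random_pedigree <- function(n, nf = max(4, round(n / 5)), seed = NULL,
                            p_unknown = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")  # guarantee both sexes among founders
  sire <- dam <- rep("0", n)
  for (i in (nf + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (length(males) > 0 && stats::runif(1) > p_unknown)
      sire[i] <- as.character(sample(males, 1))
    if (length(females) > 0 && stats::runif(1) > p_unknown)
      dam[i] <- as.character(sample(females, 1))
  }
  pedigree(id = as.character(1:n), sire = sire, dam = dam, sex = sex)
}

# Explicit H-matrix oracle: assemble the joint pedigree-genomic
# relationship matrix from its block formula, with genotyped ids last.
#   H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21
#   H12 = A12 A22^-1 G ; H22 = G
assemble_H_oracle <- function(A, G, genotyped_ids) {
  ids <- rownames(A)
  ng <- setdiff(ids, genotyped_ids)
  ord <- c(ng, genotyped_ids)
  A <- A[ord, ord]
  i1 <- seq_along(ng)
  i2 <- length(ng) + seq_along(genotyped_ids)
  A11 <- A[i1, i1, drop = FALSE]; A12 <- A[i1, i2, drop = FALSE]
  A22 <- A[i2, i2, drop = FALSE]
  G <- G[genotyped_ids, genotyped_ids]
  A22i <- solve(A22)
  H <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  H[i1, i1] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H[i1, i2] <- A12 %*% A22i %*% G
  H[i2, i1] <- t(H[i1, i2])
  H[i2, i2] <- G
  H
}

# Small synthetic data set reused by the model/pipeline tests:
# pedigree-based population with phenotypes, no markers.
small_population <- function(seed = 42, nm = 36, nf = 36, gens = 3) {
  simulate_population(
    sim_config(n_founder_males = nm, n_founder_females = nf,
               n_generations = gens, n_markers = 0,
               genotyped_generations = integer(0)),
    seed = seed)
}
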