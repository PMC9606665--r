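#' Simulation configuration
#'
#' Parameters of the discrete-generation breeding-scheme simulator.
#' Defaults describe the study population: 100 male and 100 female
#' founders, ten non-overlapping generations, litter size 4, a 1:1
#' mating ratio in which half of the females (selected on own
#' phenotype) are mated to a random half of the males, 5,000 unlinked
#' gene-dropped markers retained for generations 8-10, phenotypes
#' missing for all founders and for 25% of later males, and 10% of
#' sire / 5% of dam pedigree entries masked.
#'
#' The true variance components are simulation inputs: heritability
#' 0.30 on a phenotypic variance of 42 (phenotypic mean 48), giving
#' phenotypes of roughly 48 +/- 6.5.
#'
#' @param n_founder_males,n_founder_females founder counts.
#' @param n_generations generations after the founders (>= 0).
#' @param litter_size offspring per mating.
#' @param prop_dams_selected fraction of females selected as dams.
#' @param prop_sires_used fraction of males drawn as sires.
#' @param n_markers biallelic markers to gene-drop (0 = none).
#' @param genotyped_generations integer vector of generations whose
#'   genotypes are retained.
#' @param male_phenotype_missing_rate fraction of post-founder males
#'   without phenotype.
#' @param sire_mask_rate,dam_mask_rate per-entry masking rates for the
#'   released pedigree (generations >= 1).
#' @param h2 true heritability.
#' @param sigma2_p true phenotypic variance.
#' @param mu phenotypic mean.
#' @param seed optional RNG seed stored with the configuration.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_founder_males = 100, n_founder_females = 100,
                       n_generations = 10, litter_size = 4,
                       prop_dams_selected = 0.5, prop_sires_used = 0.5,
                       n_markers = 5000, genotyped_generations = 8:10,
                       male_phenotype_missing_rate = 0.25,
                       sire_mask_rate = 0.10, dam_mask_rate = 0.05,
                       h2 = 0.30, sigma2_p = 42, mu = 48,
                       seed = NULL) {
  cfg <- list(n_founder_males = n_founder_males,
              n_founder_females = n_founder_females,
              n_generations = n_generations, litter_size = litter_size,
              prop_dams_selected = prop_dams_selected,
              prop_sires_used = prop_sires_used,
              n_markers = n_markers,
              genotyped_generations = as.integer(genotyped_generations),
              male_phenotype_missing_rate = male_phenotype_missing_rate,
              sire_mask_rate = sire_mask_rate,
              dam_mask_rate = dam_mask_rate,
              h2 = h2, sigma2_p = sigma2_p, mu = mu, seed = seed)
  rates <- c(cfg$prop_dams_selected, cfg$prop_sires_used,
             cfg$male_phenotype_missing_rate, cfg$sire_mask_rate,
             cfg$dam_mask_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_generations < 0) stop("n_generations must be >= 0")
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("h2 must lie in [0, 1]")
  if (cfg$sigma2_p <= 0) stop("sigma2_p must be positive")
  if (cfg$litter_size < 1) stop("litter_size must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a breeding population
#'
#' Runs the discrete-generation scheme of [sim_config()]: founders are
#' unrelated and non-inbred; each later generation is produced by
#' mating the selected dams (top fraction of females on own phenotype;
#' founder dams at random, since founders carry no phenotypes) 1:1 to
#' randomly drawn sires, with a fixed litter size and equiprobable
#' offspring sex. True breeding values follow the pedigree recursion
#' \eqn{u_i = (u_s + u_d)/2 + m_i},
#' \eqn{m_i \sim N(0, 0.5 (1 - (F_s + F_d)/2) \sigma^2_g)}, phenotypes
#' are \eqn{y = \mu + u + e}, and marker genotypes are gene-dropped
#' independently per locus from founder alleles with per-locus founder
#' frequencies uniform on (0.05, 0.95).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; overrides \code{cfg$seed} when given.
#' @return List of class \code{sim_population}: \code{pedigree} (true
#'   pedigree with \code{sex} and \code{generation} columns),
#'   \code{masked_pedigree}, \code{genotypes} (a [geno_matrix()] over
#'   the genotyped generations, or NULL), \code{phenotypes}
#'   (\code{id}, \code{value}), \code{true_bv} (named vector),
#'   \code{config}, \code{seed}.
#' @export
simulate_population <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  s2g <- cfg$h2 * cfg$sigma2_p
  s2e <- (1 - cfg$h2) * cfg$sigma2_p
  L <- cfg$n_markers
  n0 <- cfg$n_founder_males + cfg$n_founder_females

  sex <- c(rep("M", cfg$n_founder_males), rep("F", cfg$n_founder_females))
  gen <- rep(0L, n0)
  sire <- rep(0L, n0)
  dam <- rep(0L, n0)
  A <- diag(n0)
  u <- stats::rnorm(n0, 0, sqrt(s2g))
  y <- rep(NA_real_, n0)  # founders carry no phenotypes

  drop_markers <- L > 0
  if (drop_markers) {
    p_founder <- stats::runif(L, 0.05, 0.95)
    a1 <- matrix(stats::rbinom(n0 * L, 1, rep(p_founder, each = n0)), n0, L)
    a2 <- matrix(stats::rbinom(n0 * L, 1, rep(p_founder, each = n0)), n0, L)
  }

  for (t in seq_len(cfg$n_generations)) {
    prev <- which(gen == t - 1L)
    fem <- prev[sex[prev] == "F"]
    mal <- prev[sex[prev] == "M"]
    n_dams <- round(cfg$prop_dams_selected * length(fem))
    n_sires <- round(cfg$prop_sires_used * length(mal))
    n_pairs <- min(n_dams, n_sires)
    if (n_pairs < 1)
      stop("selection leaves no mating pairs in generation ", t)
    if (all(is.na(y[fem]))) {
      dams <- sample(fem, n_dams)
    } else {
      scored <- fem[!is.na(y[fem])]
      dams <- scored[order(y[scored], decreasing = TRUE)][seq_len(
        min(n_dams, length(scored)))]
    }
    sires <- sample(mal, n_sires)
    dams <- sample(dams)[seq_len(n_pairs)]
    sires <- sires[seq_len(n_pairs)]

    m <- n_pairs * cfg$litter_size
    off_sire <- rep(sires, each = cfg$litter_size)
    off_dam <- rep(dams, each = cfg$litter_size)
    n_old <- length(gen)

    A_new <- matrix(0, n_old + m, n_old + m)
    A_new[seq_len(n_old), seq_len(n_old)] <- A
    A <- A_new
    for (k in seq_len(m)) {
      i <- n_old + k
      s <- off_sire[k]; d <- off_dam[k]
      j <- seq_len(i - 1L)
      row <- (A[s, j] + A[d, j]) / 2
      A[i, j] <- row
      A[j, i] <- row
      A[i, i] <- 1 + A[s, d] / 2
    }
    Fs <- (diag(A)[off_sire] - 1)
    Fd <- (diag(A)[off_dam] - 1)
    msv <- 0.5 * (1 - (Fs + Fd) / 2) * s2g
    u_off <- (u[off_sire] + u[off_dam]) / 2 +
      stats::rnorm(m, 0, sqrt(msv))
    sex_off <- sample(c("M", "F"), m, replace = TRUE)
    y_off <- cfg$mu + u_off + stats::rnorm(m, 0, sqrt(s2e))
    y_off[sex_off == "M" &
            stats::runif(m) < cfg$male_phenotype_missing_rate] <- NA

    if (drop_markers) {
      a1_off <- matrix(0L, m, L)
      a2_off <- matrix(0L, m, L)
      for (k in seq_len(m)) {
        s <- off_sire[k]; d <- off_dam[k]
        pick_s <- stats::runif(L) < 0.5
        pick_d <- stats::runif(L) < 0.5
        a1_off[k, ] <- ifelse(pick_s, a1[s, ], a2[s, ])
        a2_off[k, ] <- ifelse(pick_d, a1[d, ], a2[d, ])
      }
      a1 <- rbind(a1, a1_off)
      a2 <- rbind(a2, a2_off)
    }

    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, sex_off)
    gen <- c(gen, rep(t, m))
    u <- c(u, u_off)
    y <- c(y, y_off)
  }

  n <- length(gen)
  ids <- as.character(seq_len(n))
  ped <- pedigree(id = ids,
                  sire = ifelse(sire == 0L, "0", as.character(sire)),
                  dam = ifelse(dam == 0L, "0", as.character(dam)),
                  sex = sex, generation = gen)

  masked <- ped
  later <- masked$generation >= 1L
  mask_s <- later & stats::runif(n) < cfg$sire_mask_rate
  mask_d <- later & stats::runif(n) < cfg$dam_mask_rate
  masked$sire[mask_s] <- "0"
  masked$dam[mask_d] <- "0"

  genotypes <- NULL
  if (drop_markers) {
    keep <- which(gen %in% cfg$genotyped_generations)
    if (length(keep) > 0) {
      M <- (a1 + a2)[keep, , drop = FALSE]
      genotypes <- geno_matrix(M, coding = "dosage", ids = ids[keep],
                               markers = paste0("m", seq_len(L)))
    }
  }

  phen <- data.frame(id = ids[!is.na(y)], value = y[!is.na(y)],
                     stringsAsFactors = FALSE)
  structure(list(pedigree = ped, masked_pedigree = masked,
                 genotypes = genotypes, phenotypes = phen,
                 true_bv = stats::setNames(u, ids),
                 config = cfg, seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population: %d individuals, %d generations, %d phenotyped%s>\n",
    nrow(x$pedigree), max(x$pedigree$generation), nrow(x$phenotypes),
    if (!is.null(x$genotypes))
      sprintf(", %d genotyped x %d markers", length(x$genotypes$ids),
              length(x$genotypes$markers)) else ""))
  invisible(x)
}

#' Small deterministic fixtures for examples and tests
#'
#' @param name one of \code{"trio"} (two founders and their
#'   offspring), \code{"fullsib"} (a full-sib mating: founders 1-2,
#'   full sibs 3-4, inbred offspring 5), \code{"ped30"} (a fixed
#'   three-generation pedigree of 30 individuals with phenotypes), or
#'   \code{"toy_geno"} (a 2-individual, 2-marker genotype toy with
#'   fixed allele frequencies 0.5).
#' @return The fixture: a \code{ped} for the pedigrees (\code{ped30}
#'   additionally carries a \code{phenotypes} attribute), a
#'   \code{geno_matrix} for \code{"toy_geno"}.
#' @export
make_fixture <- function(name = c("trio", "fullsib", "ped30", "toy_geno")) {
  name <- match.arg(name)
  switch(name,
    trio = pedigree(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2)),
    fullsib = pedigree(id = 1:5, sire = c(0, 0, 1, 1, 3),
                       dam = c(0, 0, 2, 2, 4)),
    ped30 = {
      # 10 founders; 12 in generation 1; 8 in generation 2
      id <- 1:30
      sire <- c(rep(0, 10),
                c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 1),
                c(11, 11, 13, 13, 15, 17, 19, 21))
      dam <- c(rep(0, 10),
               c(6, 6, 7, 7, 8, 8, 9, 9, 10, 10, 6, 7),
               c(12, 14, 14, 16, 18, 18, 20, 22))
      ped <- pedigree(id = id, sire = sire, dam = dam)
      set.seed(3030)
      phen <- data.frame(id = as.character(11:30),
                         value = round(stats::rnorm(20, 50, 5), 2))
      attr(ped, "phenotypes") <- phen
      ped
    },
    toy_geno = geno_matrix(matrix(c(1, -1, 1, 1), nrow = 2, byrow = TRUE,
                                  dimnames = list(c("1", "2"),
                                                  c("m1", "m2"))),
                           coding = "centered",
                           allele_freqs = c(0.5, 0.5))
  )
}
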