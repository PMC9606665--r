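test_that("zero generations yields exactly the founders", {
  cfg <- sim_config(n_founder_males = 7, n_founder_females = 9,
                    n_generations = 0, n_markers = 10,
                    genotyped_generations = 0)
  pop <- simulate_population(cfg, seed = 1)
  expect_equal(nrow(pop$pedigree), 16)
  expect_true(all(pop$pedigree$sire == "0" & pop$pedigree$dam == "0"))
  expect_equal(nrow(pop$phenotypes), 0)  # founders carry no phenotypes
})

test_that("per-generation offspring counts follow the mating design", {
  cfg <- sim_config(n_founder_males = 20, n_founder_females = 20,
                    n_generations = 3, litter_size = 3, n_markers = 0,
                    genotyped_generations = integer(0))
  pop <- simulate_population(cfg, seed = 2)
  gen <- pop$pedigree$generation
  sex <- pop$pedigree$sex
  for (t in 1:3) {
    prev <- gen == t - 1
    n_pairs <- min(round(0.5 * sum(sex[prev] == "F")),
                   round(0.5 * sum(sex[prev] == "M")))
    expect_equal(sum(gen == t), n_pairs * 3)
  }
})

test_that("identical config and seed reproduce the population exactly", {
  cfg <- sim_config(n_founder_males = 8, n_founder_females = 8,
                    n_generations = 2, n_markers = 30,
                    genotyped_generations = 1:2)
  a <- simulate_population(cfg, seed = 77)
  b <- simulate_population(cfg, seed = 77)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$M, b$genotypes$M)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$true_bv, b$true_bv)
})

test_that("gene-dropped genotypes are Mendelian-consistent", {
  pop <- simulate_population(
    sim_config(n_founder_males = 6, n_founder_females = 6,
               n_generations = 2, n_markers = 40,
               genotyped_generations = 0:2),
    seed = 31)
  M <- pop$genotypes$M + 1  # back to 0/1/2 dosages
  ped <- pop$pedigree
  for (i in which(ped$sire != "0")) {
    id <- ped$id[i]
    s <- ped$sire[i]; d <- ped$dam[i]
    lo <- (M[s, ] == 2) + (M[d, ] == 2)
    hi <- (M[s, ] >= 1) + (M[d, ] >= 1)
    expect_true(all(M[id, ] >= lo & M[id, ] <= hi),
                label = paste("offspring", id, "attainable from parents"))
  }
})

test_that("founder breeding values realize the input genetic variance", {
  cfg <- sim_config(n_founder_males = 300, n_founder_females = 300,
                    n_generations = 0, n_markers = 0,
                    genotyped_generations = integer(0))
  pop <- simulate_population(cfg, seed = 8)
  s2g <- cfg$h2 * cfg$sigma2_p
  v <- var(pop$true_bv)
  se <- s2g * sqrt(2 / (length(pop$true_bv) - 1))
  expect_lt(abs(v - s2g), 4 * se)
})

test_that("masking only blanks parent slots and sparsifies A-inverse", {
  pop <- simulate_population(
    sim_config(n_founder_males = 25, n_founder_females = 25,
               n_generations = 4, n_markers = 0,
               genotyped_generations = integer(0),
               sire_mask_rate = 0.2, dam_mask_rate = 0.1),
    seed = 12)
  truth <- pop$pedigree
  masked <- pop$masked_pedigree
  expect_identical(truth$id, masked$id)
  changed_s <- truth$sire != masked$sire
  changed_d <- truth$dam != masked$dam
  expect_true(all(masked$sire[changed_s] == "0"))
  expect_true(all(masked$dam[changed_d] == "0"))
  expect_gt(sum(changed_s) + sum(changed_d), 0)

  nnz <- function(K) sum(abs(rm_values(K)) > 1e-12)
  expect_lt(nnz(makeAinv(masked)), nnz(makeAinv(truth)))
})

test_that("fixture catalog rejects unknown names", {
  expect_error(make_fixture("nope"))
  expect_s3_class(make_fixture("trio"), "ped")
  expect_s3_class(make_fixture("toy_geno"), "geno_matrix")
  ped30 <- make_fixture("ped30")
  expect_equal(nrow(ped30), 30)
  expect_equal(nrow(attr(ped30, "phenotypes")), 20)
})
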