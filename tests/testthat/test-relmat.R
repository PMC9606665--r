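test_that("inbreeding coefficients match hand-derived pedigrees", {
  two <- pedigree(id = 1:2, sire = c(0, 0), dam = c(0, 0))
  expect_equal(unname(inbreeding(two)), c(0, 0))

  # 4 = sire 1 x dam 3, where 3 = (1, 2): a(1,3) = 0.5, F4 = 0.25
  ped <- pedigree(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3))
  expect_equal(unname(inbreeding(ped)), c(0, 0, 0, 0.25))

  # full-sib mating: parents 3 and 4 share both parents, a(3,4) = 0.5
  fs <- make_fixture("fullsib")
  expect_equal(unname(inbreeding(fs)), c(0, 0, 0, 0, 0.25))
  expect_true(all(inbreeding(fs) >= 0 & inbreeding(fs) < 1))
})

test_that("pedigree validation rejects malformed input", {
  expect_error(pedigree(id = c(1, 1), sire = c(0, 0), dam = c(0, 0)),
               "unique")
  expect_error(pedigree(id = 1:2, sire = c(2, 0), dam = c(0, 0)),
               "ordered")
  expect_error(pedigree(id = 1:2, sire = c(0, 2), dam = c(0, 0)),
               "own parent")
  expect_error(pedigree(id = 1:3, sire = c(0, 0, 9), dam = c(0, 0, 0)),
               "do not appear")
})

test_that("makeA reproduces the tabular method", {
  two <- pedigree(id = 1:2, sire = c(0, 0), dam = c(0, 0))
  expect_equal(rm_values(makeA(two)), diag(2), ignore_attr = TRUE)

  trio <- make_fixture("trio")
  expect_equal(rm_values(makeA(trio)),
               matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3, 3),
               ignore_attr = TRUE)

  fs <- make_fixture("fullsib")
  A <- rm_values(makeA(fs))
  expect_equal(A[5, 5], 1.25)
  expect_equal(A[3, 4], 0.5)
})

test_that("makeA agrees with an independent recursive-kinship oracle", {
  for (seed in c(11, 23)) {
    ped <- random_pedigree(30, seed = seed)
    A <- rm_values(makeA(ped))
    expect_equal(A, kinship_oracle(ped), tolerance = 1e-12)
    expect_equal(diag(A), 1 + unname(inbreeding(ped)),
                 ignore_attr = TRUE)
    expect_true(all(diag(A) >= 1))
    expect_true(all(A[upper.tri(A)] >= 0))
  }
})

test_that("makeAinv follows Henderson's rules and inverts A", {
  founders <- pedigree(id = 1:4, sire = rep(0, 4), dam = rep(0, 4))
  expect_equal(rm_values(makeAinv(founders)), diag(4),
               ignore_attr = TRUE)

  trio <- make_fixture("trio")
  expect_equal(rm_values(makeAinv(trio)),
               matrix(c(1.5, .5, -1, .5, 1.5, -1, -1, -1, 2), 3, 3),
               ignore_attr = TRUE)

  for (n in c(30, 200)) {
    ped <- random_pedigree(n, seed = n)
    prod <- rm_values(makeAinv(ped)) %*% rm_values(makeA(ped))
    expect_lt(max(abs(prod - diag(n))), 1e-8)
  }
})

test_that("ignoring inbreeding in A-inverse matters only when inbred", {
  noninbred <- make_fixture("trio")
  expect_equal(rm_values(makeAinv(noninbred, use_inbreeding = FALSE)),
               rm_values(makeAinv(noninbred)))
  # the rules diverge once an inbred individual (5, F = 0.25) has progeny
  inbred <- pedigree(id = 1:6, sire = c(0, 0, 1, 1, 3, 5),
                     dam = c(0, 0, 2, 2, 4, 2))
  with_f <- rm_values(makeAinv(inbred))
  without_f <- rm_values(makeAinv(inbred, use_inbreeding = FALSE))
  expect_gt(max(abs(with_f - without_f)), 0.05)
  # only the inbreeding-aware version inverts A exactly
  A <- rm_values(makeA(inbred))
  expect_lt(max(abs(with_f %*% A - diag(6))), 1e-10)
  expect_gt(max(abs(without_f %*% A - diag(6))), 1e-3)
})

test_that("makeG evaluates the VanRaden method 1 formulas", {
  toy <- make_fixture("toy_geno")
  G <- rm_values(makeG(toy))
  # codings (1,-1) and (1,1), p = 0.5: denominator 1, G = [[2,0],[0,2]]
  expect_equal(G, 2 * diag(2), ignore_attr = TRUE)

  # a fully heterozygous individual at p = 0.5 has diagonal 0
  het <- geno_matrix(matrix(0, 1, 4), coding = "centered",
                     allele_freqs = rep(0.5, 4))
  expect_equal(rm_values(makeG(het))[1, 1], 0)

  # monomorphic markers leave a zero denominator
  mono <- geno_matrix(matrix(1, 3, 2), coding = "centered")
  expect_error(makeG(mono), "monomorphic")
})

test_that("makeG is symmetric, permutation-equivariant and matches WW'", {
  set.seed(5)
  M <- matrix(sample(c(-1, 0, 1), 8 * 30, replace = TRUE), 8, 30)
  geno <- geno_matrix(M, coding = "centered",
                      ids = paste0("i", 1:8))
  G <- rm_values(makeG(geno))
  expect_equal(G, t(G))
  p <- geno$p
  W <- sweep(M, 2, 2 * p - 1)
  expect_equal(G, tcrossprod(W) / (2 * sum(p * (1 - p))),
               ignore_attr = TRUE, tolerance = 1e-12)
  # permuting individuals permutes rows and columns identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  Gp <- rm_values(makeG(geno_matrix(M[perm, ], coding = "centered",
                                    ids = paste0("i", 1:8)[perm],
                                    allele_freqs = p)))
  expect_equal(Gp, G[perm, perm], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("genomic matrix estimates pedigree expectations on gene drops", {
  pop <- simulate_population(
    sim_config(n_founder_males = 15, n_founder_females = 15,
               n_generations = 3, n_markers = 2000,
               genotyped_generations = 0:3),
    seed = 99)
  A <- rm_values(makeA(pop$pedigree))
  # reference G to the base population: founder allele frequencies
  founders <- pop$pedigree$id[pop$pedigree$generation == 0]
  p0 <- colMeans(pop$genotypes$M[founders, ] + 1) / 2
  geno0 <- geno_matrix(pop$genotypes$M, coding = "centered",
                       ids = pop$genotypes$ids, allele_freqs = p0)
  G <- rm_values(makeG(geno0))
  ids <- pop$genotypes$ids
  expect_identical(rownames(G), ids)
  expect_lt(mean(abs(G - A[ids, ids])), 0.05)
})

test_that("blendGA weights G against A22", {
  ids <- paste0("g", 1:3)
  G <- rel_matrix(2 * diag(3), ids = ids, kind = "G")
  A <- rel_matrix(diag(3), ids = ids, kind = "A")
  expect_equal(rm_values(blendGA(G, A, weight = 1)), rm_values(G))
  expect_equal(rm_values(blendGA(G, A, weight = 0)), rm_values(A))
  expect_equal(rm_values(blendGA(G, A, weight = 0.95)), 1.95 * diag(3),
               ignore_attr = TRUE)
  A_bad <- rel_matrix(diag(3), ids = paste0("x", 1:3), kind = "A")
  expect_error(blendGA(G, A_bad), "ids")
})

test_that("makeHinv degenerates correctly and matches the assembled H", {
  ped <- random_pedigree(20, seed = 77)
  A <- makeA(ped)
  Ainv <- makeAinv(ped)

  # empty genotyped set: H^-1 is A^-1
  empty <- makeHinv(Ainv, rel_matrix(matrix(0, 0, 0), ids = character(0)),
                    rel_matrix(matrix(0, 0, 0), ids = character(0)),
                    genotyped_ids = character(0))
  expect_equal(rm_values(empty), rm_values(Ainv))
  expect_identical(attr(empty, "kind"), "H_inv")

  # all individuals genotyped: H^-1 = G_blend^-1
  set.seed(1)
  Mfull <- matrix(sample(0:2, 20 * 400, replace = TRUE), 20, 400)
  Gfull <- makeG(geno_matrix(Mfull, ids = rm_ids(A)))
  Gb_full <- blendGA(Gfull, A)
  H_all <- makeHinv(Ainv, Gb_full, A, genotyped_ids = rm_ids(A))
  expect_equal(rm_values(H_all), rm_values(invert_relmat(Gb_full)),
               tolerance = 1e-8)

  # 8 genotyped of 20: equals the dense inverse of the assembled H
  gids <- ped$id[13:20]
  A22 <- subset_relmat(A, gids)
  G <- rel_matrix(rm_values(A22) + 0.05 * diag(8), ids = gids, kind = "G")
  Gb <- blendGA(G, A22)
  Hinv <- makeHinv(Ainv, Gb, A22)
  H_explicit <- assemble_H_oracle(rm_values(A), rm_values(Gb), gids)
  ids <- rm_ids(Hinv)
  expect_lt(max(abs(rm_values(Hinv) - solve(H_explicit)[ids, ids])), 1e-8)
})

test_that("invert_relmat inverts SPD matrices and flags singular ones", {
  I3 <- rel_matrix(diag(3), kind = "G")
  expect_equal(rm_values(invert_relmat(I3)), diag(3), ignore_attr = TRUE)
  expect_identical(attr(invert_relmat(I3), "kind"), "G_inv")
  expect_equal(rm_values(invert_relmat(rel_matrix(2 * diag(3)))),
               0.5 * diag(3), ignore_attr = TRUE)
  ones <- rel_matrix(matrix(1, 3, 3) + 1e-12 * diag(3))
  expect_error(invert_relmat(ones), "singular|positive definite")
})
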