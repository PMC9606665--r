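test_that("build_mme assembles the Henderson system", {
  K1 <- rel_matrix(matrix(1), ids = "1", kind = "custom")
  phen <- data.frame(id = "1", value = 3.2)
  sys <- build_mme(K1, phen, lambda = 1)
  expect_equal(sys$LHS, matrix(c(1, 1, 1, 2), 2, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(sys$RHS), c(3.2, 3.2))
  expect_error(build_mme(K1, data.frame(id = character(0),
                                        value = numeric(0)), 1),
               "no phenotype")
  expect_error(build_mme(K1, data.frame(id = "9", value = 1), 1),
               "absent")
})

test_that("build_mme matches hand-assembled blocks with partial records", {
  trio <- make_fixture("trio")
  Ainv <- makeAinv(trio)
  phen <- data.frame(id = c("1", "3"), value = c(1.0, 2.0))
  lambda <- 2
  sys <- build_mme(Ainv, phen, lambda)
  X <- matrix(1, 2, 1)
  Z <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X),
                     crossprod(Z) + lambda * rm_values(Ainv)))
  expect_equal(sys$LHS, LHS, ignore_attr = TRUE)
  expect_equal(as.numeric(sys$RHS),
               c(sum(phen$value), crossprod(Z, phen$value)))
})

test_that("solve_mme solves directly and agrees with a pseudo-inverse", {
  trio <- make_fixture("trio")
  Ainv <- makeAinv(trio)
  phen <- data.frame(id = c("1", "2", "3"), value = c(4.1, 5.7, 5.0))
  sys <- build_mme(Ainv, phen, lambda = 1.5)
  sol <- solve_mme(sys)
  expect_lt(sol$relative_residual, 1e-8)
  oracle <- drop(MASS::ginv(sys$LHS) %*% sys$RHS)
  expect_equal(unname(c(sol$fixed, sol$ebv)), oracle, tolerance = 1e-8)
})

test_that("extreme shrinkage drives all EBVs to zero", {
  pop <- small_population(seed = 5, nm = 10, nf = 10, gens = 2)
  Ainv <- makeAinv(pop$pedigree)
  big <- predict_ebv(Ainv, pop$phenotypes, lambda = 1e6)
  expect_lt(max(abs(big$ebv)), 1e-3)
  mild <- predict_ebv(Ainv, pop$phenotypes, lambda = 1)
  expect_gt(max(abs(mild$ebv)), 0.1)
})

test_that("REML obeys the w-scaling identities on both K and K-inverse", {
  pop <- small_population(seed = 42)
  A <- makeA(pop$pedigree)
  fit0 <- reml_estimate(K = A, phen = pop$phenotypes)
  expect_true(fit0$converged)
  Ainv <- invert_relmat(A)
  for (w in c(0.9, 1.1)) {
    fw <- reml_estimate(K = transformK(A, w = w), phen = pop$phenotypes)
    expect_equal(fw$sigma2_g, fit0$sigma2_g / w, tolerance = 1e-6)
    expect_equal(fw$sigma2_e, fit0$sigma2_e, tolerance = 1e-6)
    expect_equal(fw$h2, 1 / (1 + w * fit0$lambda), tolerance = 1e-6)
    fiw <- reml_estimate(K_inv = transformK(Ainv, w = w),
                         phen = pop$phenotypes)
    expect_equal(fiw$sigma2_g, w * fit0$sigma2_g, tolerance = 1e-6)
  }
})

test_that("REML recovers the simulated heritability at small scale", {
  h2_hat <- vapply(1:6, function(i) {
    pop <- small_population(seed = 100 + i, nm = 30, nf = 30, gens = 3)
    reml_estimate(K = makeA(pop$pedigree), phen = pop$phenotypes)$h2
  }, numeric(1))
  se <- sd(h2_hat) / sqrt(length(h2_hat))
  expect_lt(abs(mean(h2_hat) - 0.30), 4 * se + 0.02)
})

test_that("REML errors cleanly on degenerate inputs", {
  K1 <- rel_matrix(diag(2), ids = c("1", "2"))
  expect_error(reml_estimate(phen = data.frame(id = "1", value = 1)),
               "supply K or K_inv")
  expect_error(
    reml_estimate(K = K1, phen = data.frame(id = c("1", "2"),
                                            value = c(1, 1))),
    "phenotypic variance")
})
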