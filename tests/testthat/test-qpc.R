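make_kin <- function(n = 40, seed = 4, n_pops = 3, n_snps = 400) {
  g <- simulate_genotypes(small_cfg(n_accessions = n, n_pops = n_pops,
                                    n_snps = n_snps, seed = seed))
  kinship_centered(g$genotypes)
}

test_that("conditional eigensystem is orthonormal and matches a brute-force
           decomposition", {
  kin <- make_kin(5, n_snps = 60)
  ce <- conditional_eigen(kin)
  expect_equal(crossprod(ce$vectors), diag(4), tolerance = 1e-8)
  ## spectral identity: retained eigenvalues sum to the trace of the
  ## mean-centered kinship (the dropped null eigenvalue is zero)
  C <- diag(5) - matrix(1 / 5, 5, 5)
  Kc <- C %*% kin$K %*% C
  expect_equal(sum(ce$values), sum(diag(Kc)), tolerance = 1e-10)
  ## dense solver oracle
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  expect_equal(ce$values, e$values[1:4], tolerance = 1e-10)
  expect_equal(abs(ce$vectors), abs(e$vectors[, 1:4]), tolerance = 1e-6)

  ## drop-one variant: matches the dense decomposition of L K L'
  ce2 <- conditional_eigen(kin, centering = "dropone")
  L <- cbind(diag(4), 0) - matrix(1 / 5, 4, 5)
  e2 <- eigen(L %*% kin$K %*% t(L), symmetric = TRUE)
  expect_equal(ce2$values, e2$values, tolerance = 1e-10)
})

test_that("qpc test is invariant to trait location/scale and to joint
           reordering", {
  kin <- make_kin(40)
  set.seed(20)
  z <- simulate_neutral_phenotype(kin, Va = 1)
  q1 <- qpc_test(z, kin, n_tested = 5)
  q2 <- qpc_test(3.2 * z - 7, kin, n_tested = 5)
  expect_equal(q1$stats$F, q2$stats$F, tolerance = 1e-10)
  expect_equal(q1$stats$p, q2$stats$p, tolerance = 1e-10)

  perm <- sample(length(z))
  Kp <- kin$K[perm, perm]
  rownames(Kp) <- colnames(Kp) <- kin$ids[perm]
  q3 <- qpc_test(z[perm], Kp, n_tested = 5)
  expect_equal(q1$stats$F, q3$stats$F, tolerance = 1e-6)
  expect_equal(q1$stats$p, q3$stats$p, tolerance = 1e-6)
})

test_that("a trait with zero tail projections is rejected as degenerate", {
  kin <- make_kin(30)
  ce <- conditional_eigen(kin)
  ## a trait lying entirely along PC1 has zero tail projections
  z <- ce$vectors[, 1] * sqrt(ce$values[1])
  names(z) <- kin$ids
  expect_error(qpc_test(z, kin, n_tested = 5), "degenerate")
})

test_that("neutral draws give F statistics with the F-distribution mean and
           an unbiased tail variance estimate", {
  kin <- make_kin(60, seed = 6, n_snps = 600)
  set.seed(21)
  nsim <- 400
  F1 <- numeric(nsim)
  Va_hat <- numeric(nsim)
  for (i in seq_len(nsim)) {
    z <- simulate_neutral_phenotype(kin, Va = 2)
    q <- qpc_test(z, kin, n_tested = 10)
    F1[i] <- q$stats$F[1]
    Va_hat[i] <- q$Va_tail
  }
  tail_df <- 60 - 1 - 10
  expect_equal(mean(F1), tail_df / (tail_df - 2), tolerance = 0.25)
  ## Va_tail unbiased (relative bias < 5%)
  expect_equal(mean(Va_hat), 2, tolerance = 0.05)
})

test_that("neutral envelope has the stated geometry and coverage", {
  kin <- make_kin(40)
  set.seed(22)
  z <- simulate_neutral_phenotype(kin, Va = 1)
  q <- qpc_test(z, kin, n_tested = 5)

  env0 <- neutral_envelope(q, pc = 1, confidence = 0)
  expect_equal(env0$lower, env0$upper, tolerance = 1e-12)

  env <- neutral_envelope(q, pc = 2, confidence = 0.9)
  lam <- q$stats$lambda[2]
  expect_equal(env$upper,
               qnorm(0.95) * sqrt(q$Va_tail * lam) * abs(env$pc_score),
               tolerance = 1e-10)
  ## width monotone in lambda at matched score
  env1 <- neutral_envelope(q, pc = 1, confidence = 0.9)
  expect_gt(max(env1$upper) / max(abs(env1$pc_score)),
            max(env$upper) / max(abs(env$pc_score)) *
              sqrt(q$stats$lambda[1] / lam) - 1e-8)

  ## coverage: the observed through-origin slope falls inside the band
  ## when F <= qnorm(0.95)^2; empirical rate over neutral draws ~ 90%
  set.seed(23)
  inside <- vapply(1:300, function(i) {
    zz <- simulate_neutral_phenotype(kin, Va = 1)
    qq <- qpc_test(zz, kin, n_tested = 5)
    qq$stats$F[1] <= qnorm(0.95)^2
  }, logical(1))
  expect_equal(mean(inside), 0.90, tolerance = 0.05 / 0.90)
})

test_that("screening reports duplicated and affine traits identically and
           validates subsets", {
  kin <- make_kin(40)
  set.seed(24)
  z <- simulate_neutral_phenotype(kin, Va = 1)
  d <- tibble::tibble(accession = kin$ids, t1 = z, t2 = z,
                      t3 = -2 * z + 5)
  scr <- qpc_screen(d, kin, n_tested = 5)
  s <- scr$summary
  expect_equal(s$F[s$trait == "t1"], s$F[s$trait == "t2"])
  expect_equal(s$F[s$trait == "t1"], s$F[s$trait == "t3"], tolerance = 1e-10)
  expect_error(qpc_screen(d, kin, n_tested = 5, subset = kin$ids[1:8]),
               "subset")
})

test_that("selection along a PC is detected with the expected power", {
  ## closed-form oracle: F(1, tail; ncp = s^2) with shift s*sqrt(Va*lambda)
  kin <- make_kin(60, seed = 6, n_snps = 600)
  ce <- conditional_eigen(kin)
  n_tested <- 10
  tail_df <- 60 - 1 - n_tested
  shift_sd <- 3   # in units of sqrt(Va * lambda_5)
  power_theory <- 1 - pf(qf(0.95, 1, tail_df), 1, tail_df, ncp = shift_sd^2)
  expect_gt(power_theory, 0.8)

  Va <- 1
  delta <- shift_sd * sqrt(Va * ce$values[5])
  vshift <- ce$vectors[, 5] * delta
  set.seed(25)
  rej <- vapply(1:300, function(i) {
    z <- simulate_neutral_phenotype(kin, Va = Va) + vshift
    qpc_test(z, kin, n_tested = n_tested)$stats$p[5] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})
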