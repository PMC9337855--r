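test_that("MAF filter uses a strict threshold on non-missing calls", {
  G <- cbind(rare = c(rep(0, 9), 1),          # f = 0.10 exactly: removed
             common = rep(c(0, 1), 5),        # f = 0.50: kept
             ok = c(rep(0, 8), 1, 1))         # f = 0.20: kept
  out <- maf_filter(G, threshold = 0.10)
  expect_identical(colnames(out$genotypes), c("common", "ok"))
  expect_false(out$report$kept[out$report$id == "rare"])
  expect_equal(out$report$maf, c(0.1, 0.5, 0.2))

  ## missingness: frequencies computed on observed calls; >20% missing drops
  Gna <- cbind(a = c(rep(NA, 3), rep(0, 4), rep(1, 3)),
               b = c(NA, rep(0, 6), rep(1, 3)))
  out2 <- maf_filter(Gna)
  expect_identical(colnames(out2$genotypes), "b")
  expect_error(maf_filter(G[, 1, drop = FALSE]), "no SNPs")
})

test_that("with K = I the mixed-model scan equals per-SNP OLS", {
  set.seed(30)
  n <- 60
  kin <- identity_kinship(n)
  G <- matrix(rbinom(n * 100, 1, 0.4), n,
              dimnames = list(kin$ids, sprintf("s%03d", 1:100)))
  y <- setNames(rnorm(n), kin$ids)
  scan <- lmm_scan(y, G, kin, maf_threshold = 0.1)
  ols <- vapply(scan$id, function(s) {
    sm <- summary(lm(y ~ G[, s]))$coefficients
    c(sm[2, 1], sm[2, 4])
  }, numeric(2))
  expect_equal(scan$beta, unname(ols[1, ]), tolerance = 1e-6)
  expect_equal(scan$p, unname(ols[2, ]), tolerance = 1e-6)
})

test_that("allele-label flips change the sign of beta but not the p-value", {
  set.seed(31)
  g <- simulate_genotypes(small_cfg(n_accessions = 50, n_snps = 150))
  kin <- kinship_centered(g$genotypes)
  y <- setNames(simulate_neutral_phenotype(kin, Va = 1) + rnorm(50, 0, 0.5),
                kin$ids)
  s1 <- lmm_scan(y, g$genotypes, kin)
  s2 <- lmm_scan(y, 1L - g$genotypes, kin)
  expect_equal(s1$beta, -s2$beta, tolerance = 1e-10)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
  expect_error(lmm_scan(setNames(rep(1, 50), kin$ids), g$genotypes, kin),
               "constant")
})

test_that("scan p-values are calibrated under a purely polygenic trait", {
  set.seed(32)
  g <- simulate_genotypes(small_cfg(n_accessions = 80, n_pops = 3,
                                    fst = 0.25, n_snps = 500))
  kin <- kinship_centered(g$genotypes)
  z <- simulate_neutral_phenotype(kin, Va = 1) +
    rnorm(80, 0, 0.3)  # keep residual variance identifiable
  scan <- lmm_scan(setNames(z, kin$ids), g$genotypes, kin)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(attr(scan, "lambda_hat"), 0)
})

test_that("fixed-ratio and exact per-SNP fits agree closely", {
  set.seed(33)
  g <- simulate_genotypes(small_cfg(n_accessions = 60, n_pops = 3,
                                    fst = 0.2, n_snps = 150))
  kin <- kinship_centered(g$genotypes)
  z <- simulate_neutral_phenotype(kin, Va = 0.5) + rnorm(60)
  y <- setNames(z, kin$ids)
  fast <- lmm_scan(y, g$genotypes, kin)
  slow <- lmm_scan(y, g$genotypes, kin, exact = TRUE)
  dlog <- abs(-log10(fast$p) + log10(slow$p))
  expect_lt(unname(quantile(dlog, 0.99)), 0.05)
})

test_that("a planted causal SNP rises above the genome background", {
  ## median over replicates: the causal SNP's -log10 p exceeds the 95th
  ## percentile of the genome background
  set.seed(34)
  g <- simulate_genotypes(small_cfg(n_accessions = 100, n_pops = 3,
                                    n_snps = 300))
  kin <- kinship_centered(g$genotypes)
  causal <- colnames(g$genotypes)[42]
  excess <- vapply(1:7, function(i) {
    z <- simulate_neutral_phenotype(kin, Va = 1) + rnorm(100, 0, 0.4)
    z <- z + 0.5 * sd(z) * g$genotypes[, causal]
    scan <- lmm_scan(setNames(z, kin$ids), g$genotypes, kin)
    lp <- -log10(scan$p)
    lp[scan$id == causal] - unname(quantile(lp[scan$id != causal], 0.95))
  }, numeric(1))
  expect_gt(median(excess), 0)
})

test_that("Bonferroni threshold and QQ quantiles follow their definitions", {
  expect_equal(bonferroni_threshold(1), -log10(0.05))
  expect_equal(bonferroni_threshold(1e6), 7.30103)
  ns <- c(10, 100, 1e4, 1e6)
  expect_true(all(diff(bonferroni_threshold(ns)) > 0))

  n <- 99
  p_exact <- (1:n) / (n + 1)
  qd <- qq_data(p_exact)
  expect_equal(qd$observed, qd$expected, tolerance = 1e-12)

  qd1 <- qq_data(rep(1, 20))
  expect_true(all(qd1$observed == 0))
  expect_error(qq_data(c(0.5, 0, rep(0.2, 10))), "0, 1")

  set.seed(35)
  u <- runif(2000)
  qu <- qq_data(u)
  inside <- mean(qu$observed >= qu$lower & qu$observed <= qu$upper)
  expect_gt(inside, 0.9)
})
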