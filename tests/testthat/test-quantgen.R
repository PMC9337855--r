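test_that("Pearson correlation table covers the expected cases", {
  x <- rnorm(50)
  pheno <- tibble::tibble(accession = sprintf("a%02d", 1:50), t1 = x)
  climate <- tibble::tibble(accession = pheno$accession, clim = x,
                            flat = rep(1, 50))
  out <- pearson_correlations(pheno, climate)
  expect_equal(out$r[out$variable == "clim"], 1, tolerance = 1e-12)
  expect_true(is.na(out$r[out$variable == "flat"]))

  set.seed(8)
  big <- tibble::tibble(accession = as.character(1:10000),
                        t1 = rnorm(10000))
  bigc <- tibble::tibble(accession = big$accession, clim = rnorm(10000))
  out2 <- pearson_correlations(big, bigc)
  expect_lt(abs(out2$r), 0.05)
})

test_that("kinship correction reduces to the Pearson correlation when K = I", {
  set.seed(11)
  n <- 80
  kin <- identity_kinship(n)
  d <- tibble::tibble(accession = kin$ids, x = rnorm(n))
  d$y <- 0.4 * zstd(d$x) + rnorm(n, 0, 0.9)
  out <- kinship_corrected_correlation(d, "y", "x", kin)
  expect_equal(out$r_corrected, out$r, tolerance = 1e-6)
})

test_that("kinship correction attenuates structure-driven correlations", {
  set.seed(12)
  g <- simulate_genotypes(small_cfg(n_accessions = 80, n_pops = 2,
                                    fst = 0.3, n_snps = 500))
  kin <- kinship_centered(g$genotypes)
  pc1 <- kin$vectors[, 1]
  d <- tibble::tibble(accession = kin$ids,
                      x = pc1 + rnorm(80, 0, 0.2 * sd(pc1)),
                      y = pc1)
  out <- kinship_corrected_correlation(d, "y", "x", kin)
  expect_lt(abs(out$r_corrected), abs(out$r))
})

test_that("kinship-corrected test holds its type-I error under structure", {
  set.seed(13)
  g <- simulate_genotypes(small_cfg(n_accessions = 60, n_pops = 3,
                                    fst = 0.25, n_snps = 400))
  kin <- kinship_centered(g$genotypes)
  pc1 <- kin$vectors[, 1]
  nsim <- 300
  rej <- vapply(seq_len(nsim), function(i) {
    d <- tibble::tibble(
      accession = kin$ids,
      x = pc1 + rnorm(60, 0, 0.5 * sd(pc1)),           # structured covariate
      y = simulate_neutral_phenotype(kin, Va = 1))     # neutral trait
    kinship_corrected_correlation(d, "y", "x", kin)$p_corrected < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.04 / 0.05)
})

test_that("heritability behaves at the boundaries and under permutation", {
  d <- tibble::tibble(accession = rep(sprintf("a%d", 1:10), each = 5),
                      experiment = "exp1",
                      M0 = rep(rnorm(10, 10), each = 5))
  out <- suppressWarnings(heritability(d, "M0"))
  expect_gt(out$H2, 0.99)

  set.seed(14)
  d2 <- d
  d2$M0 <- d2$M0 + rnorm(50, 0, 1)
  d2$accession <- sample(d2$accession)
  out2 <- suppressWarnings(heritability(d2, "M0"))
  expect_lt(out2$H2, 0.15)
})

test_that("heritability is invariant to affine trait transforms", {
  set.seed(15)
  d <- tibble::tibble(accession = rep(sprintf("a%d", 1:20), each = 4),
                      experiment = rep(c("e1", "e2"), 40),
                      y = rep(rnorm(20), each = 4) + rnorm(80, 0, 0.8))
  h1 <- heritability(d, "y")
  d$y <- 3.7 * d$y - 12
  h2 <- heritability(d, "y")
  expect_equal(h1$H2, h2$H2, tolerance = 1e-6)
})

test_that("heritability recovers the generator target from plant truth", {
  cfg <- small_cfg(n_accessions = 80, n_snps = 100, n_reps = 3,
                   n_experiments = 2, timepoints = c(0, 1, 2, 3),
                   target_h2 = c(M0 = 0.41, r16 = 0.5, r6 = 0.32),
                   seed = 16)
  study <- simulate_study(cfg)
  h <- heritability(study$plant_params, "r", temperature = 16)
  expect_equal(h$H2, 0.5, tolerance = 0.1 / 0.5)
})

test_that("variance partition decomposes orthogonal predictors into R^2", {
  set.seed(17)
  n <- 400
  x1 <- zstd(rnorm(n))
  x2 <- zstd(resid(lm(rnorm(n) ~ x1)))
  y <- 0.6 * x1 + 0.3 * x2 + rnorm(n, 0, sqrt(1 - 0.36 - 0.09))
  d <- tibble::tibble(M0 = y, winter_temp = x1, seed_size = x2)
  vp <- variance_partition(d)
  r2 <- summary(lm(zstd(y) ~ x1 + x2))$r.squared
  expect_equal(sum(vp$var_fraction), r2, tolerance = 1e-6)
  expect_lt(abs(vp$var_fraction[1] - 0.36), 0.12)
  expect_false(is.na(vp$p_corrected[1]))

  ## independent covariate contributes (almost) nothing
  d2 <- tibble::tibble(M0 = x1 + rnorm(n, 0, 0.5), winter_temp = x1,
                       seed_size = rnorm(n))
  vp2 <- variance_partition(d2)
  expect_lt(vp2$var_fraction[2], 0.02)

  d3 <- tibble::tibble(M0 = y, winter_temp = x1,
                       seed_size = x1 + rnorm(n, 0, 1e-4))
  expect_error(variance_partition(d3), "collinear")
})

test_that("standardization is idempotent and p-values are valid", {
  x <- rnorm(30, 5, 3)
  expect_equal(zstd(zstd(x)), zstd(x), tolerance = 1e-12)
  g <- simulate_genotypes(small_cfg(n_accessions = 30, n_snps = 100))
  kin <- kinship_centered(g$genotypes)
  d <- tibble::tibble(accession = kin$ids, x = rnorm(30), y = rnorm(30))
  out <- kinship_corrected_correlation(d, "y", "x", kin)
  expect_true(out$p > 0 && out$p <= 1)
  expect_true(out$p_corrected > 0 && out$p_corrected <= 1)
})
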