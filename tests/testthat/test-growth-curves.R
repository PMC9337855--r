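test_that("closed-form growth curves match hand arithmetic", {
  expect_equal(exponential_size(0, M0 = 7, r = 0.3), 7)
  expect_equal(exponential_size(7, M0 = 10, r = 0.5), 10 * exp(3.5))
  expect_equal(exponential_size(3:5, M0 = 2, r = 0), rep(2, 3))
  expect_equal(powerlaw_size(0, M0 = 11, r = 0.2, beta = 0.7), 11)
  expect_equal(powerlaw_size(7, M0 = 10, r = 0.5, beta = 0.9),
               (10^0.1 + 0.35)^10)
  expect_error(exponential_size(1, M0 = -1, r = 0.1), "positive")
})

test_that("power-law curve approaches the exponential limit as beta -> 1", {
  tt <- seq(0, 21, length.out = 50)
  pl <- powerlaw_size(tt, M0 = 10, r = 0.2, beta = 1 - 1e-7)
  ex <- exponential_size(tt, M0 = 10, r = 0.2)
  expect_lt(max(abs(pl - ex) / ex), 1e-5)
  ## exact dispatch at beta = 1
  expect_identical(powerlaw_size(tt, 10, 0.2, 1), exponential_size(tt, 10, 0.2))
})

test_that("power-law curve is monotone in t and continuous in beta", {
  tt <- seq(0, 21, by = 0.5)
  for (b in c(0.3, 0.7, 0.95)) {
    expect_true(all(diff(powerlaw_size(tt, 5, 0.4, b)) > 0))
  }
  ## continuity in beta across the exponential dispatch boundary: step
  ## changes stay proportional to the grid spacing, with no jump at beta = 1
  betas <- c(seq(0.8, 0.999999, length.out = 400), 1)
  at_t10 <- vapply(betas, function(b) powerlaw_size(10, 10, 0.2, b), 1)
  expect_true(all(abs(diff(at_t10)) < 1))
})

test_that("domain errors name the offending time", {
  ## negative rate drives the base non-positive at large t
  expect_error(powerlaw_size(c(1, 50), M0 = 2, r = -0.5, beta = 0.5),
               "t = 50")
})

test_that("self-start recovers parameters from noiseless data", {
  tt <- seq(0, 21, by = 1)
  exp_dat <- exponential_size(tt, M0 = 8, r = 0.15)
  ss <- growth_selfstart(tt, exp_dat, "exponential")
  expect_equal(ss$M0, 8, tolerance = 1e-8)
  expect_equal(ss$r, 0.15, tolerance = 1e-8)

  pl_dat <- powerlaw_size(tt, M0 = 8, r = 0.3, beta = 0.8)
  ss2 <- growth_selfstart(tt, pl_dat, "powerlaw")
  expect_lt(abs(ss2$beta - 0.8), 0.021)  # within grid resolution

  expect_warning(ss3 <- growth_selfstart(tt, rep(5, length(tt))), "constant")
  expect_equal(ss3$r, 0)
  expect_equal(ss3$M0, 5)
})

test_that("clean_series implements the running-maximum discard rule", {
  d <- tibble::tibble(plant_id = "p1", time_dap = 1:4, area = c(5, 6, 4, 7))
  expect_equal(clean_series(d)$area, c(5, 6, 7))

  ties <- tibble::tibble(plant_id = "p1", time_dap = 1:3, area = c(5, 5, 5))
  expect_equal(clean_series(ties)$area, c(5, 5, 5))

  mono <- tibble::tibble(plant_id = "p1", time_dap = 1:4, area = 5:8)
  expect_equal(clean_series(mono)$area, 5:8)

  expect_error(clean_series(mono[0, ]), "empty")
})

test_that("clean_series is idempotent, non-decreasing, and flags short series", {
  set.seed(5)
  d <- tibble::tibble(
    plant_id = rep(sprintf("p%d", 1:30), each = 12),
    time_dap = rep(1:12, 30),
    area = as.vector(replicate(30, cumsum(abs(rnorm(12))) + rnorm(12, 0, 2))))
  d$area <- pmax(d$area, 0.01)
  once <- clean_series(d)
  twice <- clean_series(once)
  expect_equal(once$area, twice$area)
  nondec <- tapply(once$area, once$plant_id, function(x) all(diff(x) >= 0))
  expect_true(all(nondec))

  short <- tibble::tibble(plant_id = "p1", time_dap = 1:4,
                          area = c(10, 1, 1, 1))
  expect_false(any(clean_series(short)$usable))
})

test_that("temperature response is the rate contrast, matching the
           ordered-factor slope up to the sqrt(2) contrast scaling", {
  expect_equal(temperature_response(r6 = 0.2, r16 = 0.2), 0)
  expect_equal(temperature_response(r6 = 0.1, r16 = 0.4), 0.3)
  ## oracle: linear regression on an ordered two-level factor
  r6 <- c(0.10, 0.05); r16 <- c(0.40, 0.20)
  for (i in 1:2) {
    temp <- factor(c("6C", "16C"), levels = c("6C", "16C"), ordered = TRUE)
    fit <- lm(c(r6[i], r16[i]) ~ temp)
    slope <- coef(fit)[["temp.L"]]
    resp <- temperature_response(r6[i], r16[i])
    expect_equal(resp, slope * sqrt(2), tolerance = 1e-10)
    expect_equal(sign(resp), sign(slope))
  }
  expect_error(temperature_response(NA_real_, 1), "finite")
})
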