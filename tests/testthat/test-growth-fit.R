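sim_stage2_small <- function(seed = 21, ...) {
  cfg <- small_cfg(n_accessions = 8, n_snps = 80, n_reps = 2,
                   timepoints = sort(rep(seq(0, 20, by = 2.5), each = 2) +
                                       c(0, 0.42)),
                   seed = seed, ...)
  simulate_study(cfg)
}

test_that("fit records satisfy the AIC/BIC identities and reproduce the
           published model-comparison arithmetic", {
  rec <- model_fit_record("powerlaw", loglik = 435312.5, k = 10,
                          n_obs = 291000)
  expect_equal(rec$aic, 2 * 10 - 2 * 435312.5)
  expect_equal(rec$aic, -870605.0)
  rec_exp <- model_fit_record("exponential", loglik = 334281.8, k = 6,
                              n_obs = 291000)
  expect_equal(rec_exp$aic, -668551.6)

  cmp <- compare_models(rec_exp, rec)
  expect_equal(cmp$AIC, c(-668551.6, -870605.0))
  expect_equal(cmp$L.ratio[2], 2 * (435312.5 - 334281.8))
  expect_equal(cmp$df, c(6, 10))

  same <- compare_models(model_fit_record("exponential", 100, 6, 50),
                         model_fit_record("powerlaw", 100, 10, 50))
  expect_equal(same$L.ratio[2], 0)
  expect_equal(same$p_value[2], 1)

  expect_error(compare_models(rec, rec_exp), "nested")
})

test_that("stage-1 parameter counts follow the fixed + RE-cov + residual
           convention (6 exponential, 10 power-law)", {
  study <- sim_stage2_small()
  d <- study$phenotypes[study$phenotypes$temperature_C == 16, ]
  fits <- fit_growth_models(d)
  expect_equal(fits$exponential$k, 6)
  expect_equal(fits$powerlaw$k, 10)
  ## nesting: power-law likelihood not below exponential (optimizer tol)
  expect_gte(fits$powerlaw$loglik, fits$exponential$loglik - 1e-3)
  expect_equal(fits$comparison$df, c(6, 10))
})

test_that("stage-2 accession estimates reconstruct the fixed-effect coding", {
  study <- sim_stage2_small()
  fit <- fit_stage2(clean_series(study$phenotypes))
  fe <- fit$fixed_effects
  ae <- accession_estimates(fit)
  acc <- fit$levels$accession

  ## reference accession at the warm treatment: intercepts only
  expect_equal(ae$M0[ae$accession == acc[1]],
               exp(unname(fe[["lM0.(Intercept)"]])))
  expect_equal(ae$r16[ae$accession == acc[1]], unname(fe[["r.(Intercept)"]]))
  ## non-reference accession at the cold treatment: all four terms
  a <- acc[3]
  expect_equal(
    ae$r6[ae$accession == a],
    unname(fe[["r.(Intercept)"]] + fe[[paste0("r.accession", a)]] +
             fe[["r.temperature6C"]] +
             fe[[paste0("r.accession", a, ":temperature6C")]]))
  expect_equal(ae$response, ae$r16 - ae$r6)
  expect_error(accession_estimates(fit, "nonexistent"), "not in fit")
})

test_that("swapping temperature labels swaps the rate estimates", {
  study <- sim_stage2_small()
  ph <- clean_series(study$phenotypes)
  fit <- fit_stage2(ph)
  swapped <- dplyr::mutate(ph,
    temperature_C = ifelse(.data$temperature_C == 16, 6, 16))
  fit_sw <- fit_stage2(swapped)
  ae <- accession_estimates(fit)
  ae_sw <- accession_estimates(fit_sw)
  expect_equal(ae$r16, ae_sw$r6, tolerance = 1e-4)
  expect_equal(ae$r6, ae_sw$r16, tolerance = 1e-4)
})

test_that("plant estimates shrink toward (and average to) accession values", {
  study <- sim_stage2_small(seed = 33)
  fit <- fit_stage2(clean_series(study$phenotypes))
  pp <- plant_estimates(fit)
  ae <- accession_estimates(fit)
  ## BLUP centering: within-accession mean of plant rates tracks the
  ## accession fixed-effect rate
  m16 <- pp |>
    dplyr::filter(.data$temperature_C == 16) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop") |>
    dplyr::left_join(ae, by = "accession")
  expect_gt(cor(m16$r, m16$r16), 0.95)
  expect_lt(mean(abs(m16$r - m16$r16)), 0.02)

  ## plant-level estimates recover plant truth better than accession means
  truth <- study$plant_params
  j <- dplyr::inner_join(pp, truth, by = "plant_id", suffix = c("", ".t")) |>
    dplyr::left_join(ae, by = "accession")
  j16 <- j[j$temperature_C == 16, ]
  expect_gt(cor(j16$r, j16$r.t), cor(j16$r16, j16$r.t) - 0.02)
})

test_that("with vanishing noise the fixed effects reproduce the generating
           parameters", {
  cfg <- small_cfg(n_accessions = 6, n_snps = 60, n_reps = 2,
                   sigma_meas = 1e-6, artifact_rate = 0,
                   target_h2 = c(M0 = 1 - 1e-9, r16 = 1 - 1e-9, r6 = 1 - 1e-9),
                   experiment_sd = c(lM0 = 0, r = 0),
                   timepoints = sort(rep(seq(0, 20, by = 2.5), each = 2) +
                                       c(0, 0.42)),
                   seed = 77)
  study <- simulate_study(cfg)
  fit <- suppressWarnings(fit_stage2(study$phenotypes, car1 = FALSE))
  ae <- dplyr::left_join(accession_estimates(fit), study$truth$accessions,
                         by = "accession", suffix = c("", ".t"))
  expect_lt(max(abs(ae$M0 - ae$M0.t) / ae$M0.t), 1e-3)
  expect_lt(max(abs(ae$r16 - ae$r16.t) / abs(ae$r16.t)), 1e-3)
  expect_equal(unname(fit$fixed_effects[["b"]]), cfg$beta_true,
               tolerance = 1e-3)
})

test_that("single-temperature input fits with a warning and no temperature
           terms", {
  study <- sim_stage2_small()
  d16 <- study$phenotypes[study$phenotypes$temperature_C == 16, ]
  expect_warning(fit <- fit_stage2(d16), "single temperature")
  ae <- accession_estimates(fit)
  expect_true("r16" %in% names(ae))
  expect_false("r6" %in% names(ae))
})
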