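#' Simulate climate, seed size and heritable accession-level growth parameters
#'
#' Builds the accession-level layer of the synthetic study on top of
#' simulated genotypes: a winter-temperature variable structured by
#' population of origin, a polygenic score from the simulated SNPs, a seed
#' size correlated with winter temperature, and the three accession-level
#' growth parameters (log initial size `lM0`, growth rates `r16` and `r6`).
#'
#' Each trait is constructed as
#' `trait = mean + scale * (r_clim * climate + sqrt(1 - r_clim^2) * residual)`
#' where the residual mixes the (climate-orthogonalized) polygenic score and
#' independent noise in proportion `genetic_share`. Orthogonalization makes
#' the realized trait-climate correlation match the target essentially
#' exactly in the generated panel. Plant-level SDs are derived from the
#' broad-sense heritability targets: since accessions are inbred lines, all
#' accession-level variance is genetic, so
#' `sd_plant = scale * sqrt((1 - H2) / H2)` gives
#' `H2 = Vg / (Vg + Ve)` exactly in the generating distribution.
#'
#' @param cfg a [sim_config()].
#' @param genotypes,pop_labels output of [simulate_genotypes()] (the whole
#'   list can also be passed as `genotypes`).
#' @return an object of class `synthetic_truth`: a list with `accessions`
#'   (tibble: accession, pop, winter_temp, seed_size, genetic_value, lM0,
#'   M0, r16, r6), `plant_sd` (named SDs of plant-level deviations),
#'   `genotypes`, `pop_labels`, `map`, and `config`.
#' @export
simulate_climate_and_traits <- function(cfg, genotypes, pop_labels = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(genotypes) && !is.null(genotypes$genotypes)) {
    pop_labels <- genotypes$pop_labels
    map <- genotypes$map
    genotypes <- genotypes$genotypes
  } else {
    map <- NULL
  }
  if (is.null(pop_labels)) rlang::abort("pop_labels are required")
  n <- nrow(genotypes)
  if (n != cfg$n_accessions) {
    rlang::abort("genotypes do not match cfg$n_accessions")
  }
  r_tgt <- cfg$target_climate_r
  if (any(abs(r_tgt) > 0.95)) {
    rlang::abort("infeasible target_climate_r: |r| > 0.95 leaves no genetic/noise variance")
  }
  set.seed(cfg$seed + 1L)

  ## climate: population means along the winter-temperature gradient + jitter
  pop_means <- seq(cfg$winter_temp_range[1], cfg$winter_temp_range[2],
                   length.out = cfg$n_pops)
  winter_temp <- pop_means[as.integer(pop_labels)] +
    rnorm(n, 0, cfg$climate_jitter_sd)
  clim_std <- standardize(winter_temp)

  ## polygenic score from all SNPs, then orthogonalized against climate
  w <- rnorm(ncol(genotypes))
  score <- as.vector(scale(genotypes, center = TRUE, scale = FALSE) %*% w)
  g_std <- standardize(score)
  g_perp <- residualize_std(g_std, clim_std)

  ## seed size: exact target correlation with winter temperature
  rho <- cfg$seed_size_climate_r
  u <- residualize_std(rnorm(n), clim_std)
  seed_std <- rho * clim_std + sqrt(1 - rho^2) * u
  seed_size <- cfg$seed_size_mean + cfg$seed_size_sd * seed_std

  gs <- cfg$genetic_share
  make_trait <- function(target_r) {
    e <- residualize_std(rnorm(n), cbind(clim_std, g_perp))
    target_r * clim_std +
      sqrt(1 - target_r^2) * (sqrt(gs) * g_perp + sqrt(1 - gs) * e)
  }
  lM0_std <- make_trait(r_tgt[["M0"]])
  r16_std <- make_trait(r_tgt[["r16"]])
  r6_std  <- make_trait(r_tgt[["r6"]])

  mu <- cfg$trait_means
  sc <- cfg$trait_scales
  accessions <- tibble::tibble(
    accession = rownames(genotypes),
    pop = as.character(pop_labels),
    winter_temp = winter_temp,
    seed_size = seed_size,
    genetic_value = g_std,
    lM0 = mu[["lM0"]] + sc[["lM0"]] * lM0_std,
    r16 = mu[["r16"]] + sc[["r16"]] * r16_std,
    r6  = mu[["r6"]]  + sc[["r6"]]  * r6_std
  )
  accessions$M0 <- exp(accessions$lM0)

  h2 <- cfg$target_h2
  plant_sd <- c(
    lM0 = sc[["lM0"]] * sqrt((1 - h2[["M0"]]) / h2[["M0"]]),
    r16 = sc[["r16"]] * sqrt((1 - h2[["r16"]]) / h2[["r16"]]),
    r6  = sc[["r6"]]  * sqrt((1 - h2[["r6"]])  / h2[["r6"]])
  )

  structure(list(accessions = accessions, plant_sd = plant_sd,
                 genotypes = genotypes, pop_labels = pop_labels,
                 map = map, config = cfg),
            class = c("synthetic_truth", "list"))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat(sprintf("  %d accessions, %d SNPs, %d populations\n",
              nrow(x$accessions), ncol(x$genotypes),
              length(unique(x$pop_labels))))
  print(utils::head(x$accessions, 4))
  invisible(x)
}
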