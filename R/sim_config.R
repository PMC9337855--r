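#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the design of a multi-experiment growth-phenotyping study of naturally
#' inbred *Arabidopsis thaliana* accessions: 249 accessions drawn from a
#' handful of admixture groups spread along a winter-temperature gradient,
#' five replicate plants per accession per experiment, three replicate
#' experiments, two temperature treatments (16 and 6 degrees C) and rosette
#' areas imaged twice a day over a 21-day treatment window.
#'
#' Treatment time is measured in days since the start of the temperature
#' treatment (which begins 14 days after stratification); the generated
#' phenotype table reports `time_dap` = days after stratification.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_pops number of source populations (admixture groups).
#' @param fst divergence of population allele frequencies, in `[0, 1)`.
#' @param n_snps number of biallelic SNPs to simulate.
#' @param winter_temp_range range (degrees C) of the population means of the
#'   winter-temperature variable (mean temperature of the coldest quarter).
#' @param target_h2 named fractions in `(0, 1)`: broad-sense heritability
#'   targets for `M0`, `r16`, `r6`.
#' @param target_climate_r named correlations in `(-1, 1)`: target Pearson
#'   correlation of each accession-level trait with winter temperature.
#' @param beta_true power-law scaling exponent used to generate growth, in
#'   `(0, 1]` (`1` generates exponential growth).
#' @param phi_true continuous-AR1 residual correlation per day, in `[0, 1)`.
#' @param sigma_meas measurement noise SD, in rosette-area units. The
#'   default (0.3, about 3% of the initial rosette area) keeps noise-driven
#'   area decreases rare, so the negative-growth filter removes
#'   approximately the artifact fraction, as intended.
#' @param n_reps replicate plants per accession per experiment per treatment.
#' @param n_experiments number of replicate experiments.
#' @param n_temps number of temperature treatments (fixed design: 2).
#' @param timepoints strictly increasing measurement times in treatment days.
#'   The default is two measurements per day (0.42 d apart, approximating the
#'   9-h photoperiod imaging schedule) on each of 21 treatment days.
#' @param artifact_rate fraction of observations shrunk multiplicatively to
#'   mimic imaging segmentation dropouts (source of negative-growth records).
#' @param seed integer RNG seed; fixes all generator output exactly.
#' @param genetic_share fraction of the climate-independent accession-level
#'   trait variance driven by the genome-wide polygenic score.
#' @param seed_size_climate_r correlation between seed size and winter
#'   temperature.
#' @param trait_means,trait_scales accession-level means and SDs of
#'   `lM0` (log initial area), `r16`, `r6`.
#' @param experiment_sd SDs of experiment-level shifts of `lM0` and `r`.
#' @param climate_jitter_sd within-population SD of winter temperature (C).
#' @param seed_size_mean,seed_size_sd seed size distribution (mm^2).
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_study()], [simulate_genotypes()],
#'   [simulate_climate_and_traits()], [simulate_plant_series()]
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 20, n_snps = 100, seed = 7)
#' cfg$n_accessions
sim_config <- function(n_accessions = 249,
                       n_pops = 4,
                       fst = 0.15,
                       n_snps = 2000,
                       winter_temp_range = c(-12, 4),
                       target_h2 = c(M0 = 0.41, r16 = 0.57, r6 = 0.32),
                       target_climate_r = c(M0 = -0.39, r16 = 0.33, r6 = 0.28),
                       beta_true = 0.9,
                       phi_true = 0.6,
                       sigma_meas = 0.3,
                       n_reps = 5,
                       n_experiments = 3,
                       n_temps = 2,
                       timepoints = sort(rep(0:20, each = 2) + c(0, 0.42)),
                       artifact_rate = 0.02,
                       seed = 1L,
                       genetic_share = 0.6,
                       seed_size_climate_r = -0.75,
                       trait_means = c(lM0 = log(10), r16 = 0.22, r6 = 0.10),
                       trait_scales = c(lM0 = 0.15, r16 = 0.03, r6 = 0.02),
                       experiment_sd = c(lM0 = 0.05, r = 0.005),
                       climate_jitter_sd = 1,
                       seed_size_mean = 0.12,
                       seed_size_sd = 0.015) {
  stopifnot(n_accessions >= 2, n_pops >= 1, n_snps >= 1,
            n_reps >= 1, n_experiments >= 1, n_temps %in% c(1L, 2L))
  assert_fraction(fst, "fst", 0, 1, hi_open = TRUE)
  assert_fraction(target_h2, "target_h2", 0, 1, lo_open = TRUE, hi_open = TRUE)
  assert_fraction(abs(target_climate_r), "abs(target_climate_r)", 0, 1,
                  hi_open = TRUE)
  assert_fraction(beta_true, "beta_true", 0, 1, lo_open = TRUE)
  assert_fraction(phi_true, "phi_true", 0, 1, hi_open = TRUE)
  assert_fraction(artifact_rate, "artifact_rate", 0, 1, hi_open = TRUE)
  assert_fraction(genetic_share, "genetic_share")
  trait_names <- c("M0", "r16", "r6")
  if (!all(trait_names %in% names(target_h2)) ||
      !all(trait_names %in% names(target_climate_r))) {
    rlang::abort("target_h2 and target_climate_r must be named with M0, r16, r6")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    rlang::abort("timepoints must be strictly increasing")
  }
  if (sigma_meas < 0) rlang::abort("sigma_meas must be >= 0")
  stopifnot(length(winter_temp_range) == 2,
            winter_temp_range[1] < winter_temp_range[2])
  cfg <- list(
    n_accessions = as.integer(n_accessions), n_pops = as.integer(n_pops),
    fst = fst, n_snps = as.integer(n_snps),
    winter_temp_range = winter_temp_range,
    target_h2 = target_h2[trait_names],
    target_climate_r = target_climate_r[trait_names],
    beta_true = beta_true, phi_true = phi_true, sigma_meas = sigma_meas,
    n_reps = as.integer(n_reps), n_experiments = as.integer(n_experiments),
    n_temps = as.integer(n_temps), timepoints = timepoints,
    artifact_rate = artifact_rate, seed = as.integer(seed),
    genetic_share = genetic_share,
    seed_size_climate_r = seed_size_climate_r,
    trait_means = trait_means, trait_scales = trait_scales,
    experiment_sd = experiment_sd, climate_jitter_sd = climate_jitter_sd,
    seed_size_mean = seed_size_mean, seed_size_sd = seed_size_sd
  )
  structure(cfg, class = c("sim_config", "list"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d accessions in %d populations, Fst = %g, %d SNPs\n",
              x$n_accessions, x$n_pops, x$fst, x$n_snps))
  cat(sprintf("  %d reps x %d experiments x %d temperatures, %d timepoints\n",
              x$n_reps, x$n_experiments, x$n_temps, length(x$timepoints)))
  cat(sprintf("  beta = %g, phi = %g, sigma_meas = %g, artifact rate = %g, seed = %d\n",
              x$beta_true, x$phi_true, x$sigma_meas, x$artifact_rate, x$seed))
  invisible(x)
}
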