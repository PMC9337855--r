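#' Simulate plant-level rosette-area time series
#'
#' Generates the long-format phenotype table: for every accession,
#' experiment, temperature treatment and replicate plant, a rosette-area
#' trajectory following the power-law growth curve with plant-level random
#' deviations of (log M0, r), additive measurement noise with
#' continuous-AR1 correlation `corr(e_i, e_j) = phi^|t_i - t_j|`, and a
#' small fraction of observations shrunk multiplicatively (imaging
#' artifacts that create negative-growth records).
#'
#' Times in the output are days after stratification (`time_dap`); the
#' treatment clock starts 14 days after stratification, so
#' `time_dap = treatment_day + 14`.
#'
#' @param truth a `synthetic_truth` from [simulate_climate_and_traits()].
#' @param cfg a [sim_config()] (defaults to the one stored in `truth`).
#' @return a tibble with columns `plant_id`, `accession`, `experiment`,
#'   `temperature_C`, `time_dap`, `area`. The per-plant generating
#'   parameters are attached as `attr(, "plant_params")` (tibble with
#'   `plant_id`, `accession`, `experiment`, `temperature_C`, `M0`, `r`,
#'   `beta`).
#' @export
simulate_plant_series <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "sim_config"))
  acc <- truth$accessions
  if (any(acc$M0 <= 0)) rlang::abort("accession M0 must be positive")
  set.seed(cfg$seed + 2L)

  temps <- c(16, 6)[seq_len(cfg$n_temps)]
  tt <- cfg$timepoints
  nt <- length(tt)
  cholC <- car1_chol(tt, cfg$phi_true)

  exp_lM0 <- rnorm(cfg$n_experiments, 0, cfg$experiment_sd[["lM0"]])
  exp_r   <- rnorm(cfg$n_experiments, 0, cfg$experiment_sd[["r"]])

  design <- expand.grid(rep = seq_len(cfg$n_reps), temp = temps,
                        exper = seq_len(cfg$n_experiments),
                        acc_i = seq_len(nrow(acc)), KEEP.OUT.ATTRS = FALSE)
  np <- nrow(design)
  lM0_p <- acc$lM0[design$acc_i] + exp_lM0[design$exper] +
    rnorm(np, 0, truth$plant_sd[["lM0"]])
  r_a <- ifelse(design$temp == 16, acc$r16[design$acc_i], acc$r6[design$acc_i])
  sd_r <- ifelse(design$temp == 16, truth$plant_sd[["r16"]], truth$plant_sd[["r6"]])
  r_p <- r_a + exp_r[design$exper] + rnorm(np, 0, sd_r)

  plant_id <- sprintf("%s_e%d_%dC_r%d", acc$accession[design$acc_i],
                      design$exper, design$temp, design$rep)

  ## expected trajectories: np x nt
  b <- cfg$beta_true
  M <- vapply(seq_len(np), function(i) {
    powerlaw_size(tt, M0 = exp(lM0_p[i]), r = r_p[i], beta = b)
  }, numeric(nt))
  M <- t(M)

  if (cfg$sigma_meas > 0) {
    E <- matrix(rnorm(np * nt), np, nt) %*% cholC * cfg$sigma_meas
    M <- M + E
  }
  if (cfg$artifact_rate > 0) {
    hit <- runif(np * nt) < cfg$artifact_rate
    M[hit] <- M[hit] * runif(sum(hit), 0.5, 0.95)
  }
  M <- pmax(M, 1e-3)

  out <- tibble::tibble(
    plant_id = rep(plant_id, each = nt),
    accession = rep(acc$accession[design$acc_i], each = nt),
    experiment = rep(sprintf("exp%d", design$exper), each = nt),
    temperature_C = rep(design$temp, each = nt),
    time_dap = rep(tt, times = np) + 14,
    area = as.vector(t(M))
  )
  attr(out, "plant_params") <- tibble::tibble(
    plant_id = plant_id,
    accession = acc$accession[design$acc_i],
    experiment = sprintf("exp%d", design$exper),
    temperature_C = design$temp,
    M0 = exp(lM0_p), r = r_p, beta = b
  )
  out
}

#' Draw neutral phenotypes from the kinship model
#'
#' Samples trait vectors `z ~ MVN(mu * 1, Va * K)`, the neutral model under
#' which trait differentiation along kinship principal components is purely
#' drift. Used to calibrate the type-I error of [qpc_test()] and the
#' coverage of [neutral_envelope()].
#'
#' @param kinship a [kinship_centered()] object or a PSD matrix.
#' @param Va additive genetic variance (>= 0).
#' @param n_draws number of independent draws.
#' @param mu common mean.
#' @return a numeric vector (one draw) or an n x `n_draws` matrix, with
#'   accession ids as (row) names.
#' @export
simulate_neutral_phenotype <- function(kinship, Va, n_draws = 1, mu = 0) {
  if (Va < 0) rlang::abort("Va must be >= 0")
  if (inherits(kinship, "kinship_matrix")) {
    values <- kinship$values; vectors <- kinship$vectors; ids <- kinship$ids
  } else {
    e <- eigen(kinship, symmetric = TRUE)
    values <- e$values; vectors <- e$vectors
    ids <- rownames(kinship) %||% as.character(seq_len(nrow(kinship)))
  }
  Z <- rmvn_eigen(n_draws, mu, Va * values, vectors)
  rownames(Z) <- ids
  if (n_draws == 1) stats::setNames(Z[, 1], ids) else Z
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_climate_and_traits()] and [simulate_plant_series()].
#'
#' @param cfg a [sim_config()].
#' @return a list with `config`, `truth` (see
#'   [simulate_climate_and_traits()]), `phenotypes` (long tibble) and
#'   `plant_params` (per-plant generating parameters).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_accessions = 8, n_snps = 60,
#'                                    n_reps = 1, n_experiments = 1,
#'                                    timepoints = 0:6, seed = 3))
#' head(study$phenotypes)
simulate_study <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  truth <- simulate_climate_and_traits(cfg, geno)
  pheno <- simulate_plant_series(truth, cfg)
  list(config = cfg, truth = truth, phenotypes = pheno,
       plant_params = attr(pheno, "plant_params"))
}
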