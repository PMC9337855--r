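# small, fast study configurations used across the suite

small_cfg <- function(...) {
  defaults <- list(
    n_accessions = 12, n_pops = 3, n_snps = 120,
    n_reps = 2, n_experiments = 1,
    timepoints = sort(rep(seq(0, 20, by = 5), each = 2) + c(0, 0.42)),
    sigma_meas = 0.3, artifact_rate = 0, seed = 42
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# the generator configuration used for parameter-recovery checks:
# 50 accessions, 3 replicate plants, 2 treatments, 20 timepoints spanning
# the 21-day treatment (10 imaging days x 2/day)
recovery_cfg <- function(seed, ...) {
  defaults <- list(
    n_accessions = 50, n_pops = 3, n_snps = 200,
    n_reps = 3, n_experiments = 1,
    timepoints = sort(rep(round(seq(0, 20, length.out = 10)), each = 2) +
                        c(0, 0.42)),
    beta_true = 0.9, phi_true = 0.6, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# identity "kinship" (no structure) for reduction checks
identity_kinship <- function(n, ids = sprintf("acc%03d", seq_len(n))) {
  structure(list(K = diag(n), ids = ids, values = rep(1, n),
                 vectors = diag(n)),
            class = "kinship_matrix")
}

# plain standardization used by test oracles
zstd <- function(x) (x - mean(x)) / stats::sd(x)
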