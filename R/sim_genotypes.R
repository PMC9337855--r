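#' Simulate structured inbred genotypes (Balding-Nichols model)
#'
#' Draws biallelic SNP genotypes for a panel of naturally inbred accessions
#' from `n_pops` diverged populations. Ancestral allele frequencies are
#' uniform on (0.1, 0.9); population frequencies follow the Balding-Nichols
#' Beta distribution with divergence parameter `fst`; each accession, being
#' fully inbred (selfing), carries a single allele coded `{0, 1}`.
#' Columns that come out monomorphic across the panel are re-drawn, so the
#' returned matrix is polymorphic throughout. SNPs are assigned positions on
#' five chromosomes to support Manhattan-style outputs.
#'
#' @param cfg a [sim_config()].
#' @return a list with `genotypes` (accessions x SNPs matrix of 0/1 with
#'   dimnames), `pop_labels` (factor, one per accession) and `map` (tibble
#'   with `id`, `chr`, `pos`).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_accessions = 12, n_snps = 50, seed = 1))
#' dim(g$genotypes)
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions
  p <- cfg$n_snps
  k <- cfg$n_pops
  fst <- cfg$fst
  panmictic <- fst < 1e-12
  if (panmictic && k > 1) {
    rlang::warn("fst = 0 with more than one population: collapsing to panmixia")
  }
  pop <- factor(sprintf("pop%d", rep_len(seq_len(k), n)),
                levels = sprintf("pop%d", seq_len(k)))
  ids <- sprintf("acc%03d", seq_len(n))

  draw_cols <- function(m) {
    p_anc <- runif(m, 0.1, 0.9)
    G <- matrix(0L, n, m)
    for (j in seq_len(k)) {
      idx <- which(as.integer(pop) == j)
      fj <- if (panmictic) p_anc else
        stats::rbeta(m, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
      G[idx, ] <- stats::rbinom(length(idx) * m, 1L, rep(fj, each = length(idx)))
    }
    G
  }

  G <- draw_cols(p)
  for (round in 1:100) {
    mono <- which(colSums(G) %in% c(0L, n))
    if (!length(mono)) break
    G[, mono] <- draw_cols(length(mono))
  }
  mono <- which(colSums(G) %in% c(0L, n))
  if (length(mono)) {
    rlang::abort("could not obtain polymorphic SNPs; increase n_accessions or fst < 1")
  }

  chr <- rep_len(1:5, p)[order(rep_len(1:5, p))]  # contiguous blocks
  chr <- sort(rep_len(1:5, p))
  pos <- unlist(lapply(split(seq_len(p), chr), function(ix) {
    sort(sample.int(3e7, length(ix)))
  }), use.names = FALSE)
  snp_ids <- sprintf("chr%d_%d", chr, pos)
  dimnames(G) <- list(ids, snp_ids)
  list(genotypes = G,
       pop_labels = stats::setNames(pop, ids),
       map = tibble::tibble(id = snp_ids, chr = chr, pos = pos))
}
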