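# linear-mixed-model association scan with relatedness correction

#' Filter SNPs by minor-allele frequency
#'
#' Keeps a SNP iff its minor-allele frequency, computed on non-missing calls,
#' strictly exceeds `threshold` (a SNP at exactly the threshold is removed).
#' SNPs with more than `max_missing` missing calls are dropped as well.
#'
#' @param G accession x SNP matrix of allele counts (0/1, `NA` allowed).
#' @param threshold MAF threshold (default 0.10, strict `>`).
#' @param max_missing maximum tolerated missing fraction per SNP.
#' @return a list with `genotypes` (filtered matrix) and `report` (tibble:
#'   `id`, `maf`, `missing`, `kept`).
#' @export
#' @examples
#' G <- matrix(c(rep(0, 9), 1, rep(c(0, 1), 5)), ncol = 2,
#'             dimnames = list(NULL, c("rare", "common")))
#' maf_filter(G)$report
maf_filter <- function(G, threshold = 0.10, max_missing = 0.2) {
  stopifnot(is.matrix(G))
  assert_fraction(threshold, "threshold", 0, 0.5, hi_open = TRUE)
  f <- colMeans(G, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  missing <- colMeans(is.na(G))
  kept <- maf > threshold & missing <= max_missing
  if (!any(kept)) rlang::abort("no SNPs pass the MAF filter")
  ids <- colnames(G) %||% as.character(seq_len(ncol(G)))
  list(genotypes = G[, kept, drop = FALSE],
       report = tibble::tibble(id = ids, maf = unname(maf),
                               missing = unname(missing), kept = unname(kept)))
}

#' Linear-mixed-model association scan
#'
#' Single-trait genome scan with the model
#' `y = mu + x_s * beta_s + g + e`, `g ~ N(0, sg2 * K)`,
#' `e ~ N(0, se2 * I)` for each SNP `s`. The null variance ratio
#' `gamma = sg2 / se2` is estimated once by REML on the rotated kinship
#' spectrum and then held fixed while each SNP is tested by a GLS Wald test
#' in rotated coordinates (the usual fixed-ratio approximation for
#' genome-wide scans); `exact = TRUE` re-optimizes the ratio per SNP.
#' With `K = I` every SNP test reduces exactly to per-SNP OLS.
#'
#' @param y named trait vector (names = accession ids).
#' @param G accession x SNP genotype matrix (0/1; `NA` mean-imputed after
#'   the missingness filter).
#' @param kinship a [kinship_centered()] object (or PSD matrix).
#' @param map optional tibble (`id`, `chr`, `pos`) merged into the result.
#' @param maf_threshold MAF filter applied before testing (strict `>`).
#' @param exact per-SNP variance-ratio optimization (slower).
#' @return a tibble of class `gwas_scan`: `id`, `chr`, `pos`, `maf`,
#'   `beta`, `se`, `p`, with the null variance ratio in
#'   `attr(, "lambda_hat")` and the test count in `attr(, "n_tests")`.
#' @export
lmm_scan <- function(y, G, kinship, map = NULL, maf_threshold = 0.10,
                     exact = FALSE) {
  stopifnot(is.matrix(G))
  if (stats::sd(y) == 0) rlang::abort("constant trait vector")
  if (inherits(kinship, "kinship_matrix")) {
    ids <- kinship$ids; values <- kinship$values; vectors <- kinship$vectors
  } else {
    ids <- rownames(kinship) %||% rownames(G)
    e <- eigen(kinship, symmetric = TRUE)
    values <- e$values; vectors <- e$vectors
  }
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) rlang::abort("trait is missing accessions")
    y <- y[ids]
  }
  if (!is.null(rownames(G))) G <- G[ids, , drop = FALSE]
  n <- length(y)

  flt <- maf_filter(G, threshold = maf_threshold)
  G <- flt$genotypes
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  p_snps <- ncol(G)

  ## null model REML fit for the variance ratio
  null_fit <- lmm_eigen_fit(y, matrix(1, n, 1), values, vectors, reml = TRUE)
  gamma <- null_fit$gamma
  lam <- pmax(values, 0)
  w <- 1 / (gamma * lam + 1)
  yt <- drop(crossprod(vectors, y))
  x0 <- drop(crossprod(vectors, rep(1, n)))
  Gt <- crossprod(vectors, G)

  if (!exact) {
    ## vectorized 2-parameter weighted regressions across SNPs
    a11 <- sum(w * x0^2)
    b1 <- sum(w * x0 * yt)
    syy <- sum(w * yt^2)
    a12 <- colSums((w * x0) * Gt)
    a22 <- colSums(w * Gt^2)
    b2 <- colSums((w * yt) * Gt)
    det <- a11 * a22 - a12^2
    degenerate <- det <= 1e-12 * a11 * pmax(a22, 1e-300)
    beta <- (a11 * b2 - a12 * b1) / det
    beta0 <- (a22 * b1 - a12 * b2) / det
    rss <- syy - (beta0 * b1 + beta * b2)
    sigma2 <- pmax(rss, 0) / (n - 2)
    se <- sqrt(sigma2 * a11 / det)
    tval <- beta / se
    pval <- pmax(2 * stats::pt(-abs(tval), n - 2), 1e-300)
    beta[degenerate] <- NA_real_
    se[degenerate] <- NA_real_
    pval[degenerate] <- 1
  } else {
    fits <- purrr::map(seq_len(p_snps), function(j) {
      lmm_eigen_fit(y, cbind(1, G[, j]), values, vectors, reml = TRUE)
    })
    beta <- purrr::map_dbl(fits, ~ .x$beta[2])
    se <- purrr::map_dbl(fits, ~ .x$se[2])
    pval <- pmax(purrr::map_dbl(fits, ~ .x$p[2]), 1e-300)
  }

  f <- colMeans(G)
  out <- tibble::tibble(id = colnames(G) %||% as.character(seq_len(p_snps)),
                        maf = unname(pmin(f, 1 - f)),
                        beta = unname(beta), se = unname(se),
                        p = unname(pval))
  if (!is.null(map)) {
    out <- dplyr::left_join(out, map[, c("id", "chr", "pos")], by = "id") |>
      dplyr::select("id", "chr", "pos", "maf", "beta", "se", "p")
  }
  attr(out, "lambda_hat") <- gamma
  attr(out, "n_tests") <- p_snps
  class(out) <- c("gwas_scan", class(out))
  out
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' @param n_tests number of tests.
#' @param alpha family-wise error rate.
#' @return the threshold on the `-log10(p)` scale: `-log10(alpha / n_tests)`.
#' @export
#' @examples
#' bonferroni_threshold(1e6)  # 7.30103
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  assert_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  -log10(alpha / n_tests)
}

#' Observed-vs-expected p-value quantiles for a QQ plot
#'
#' Sorted observed `-log10(p)` against the uniform expectation `i / (n+1)`,
#' with a pointwise 95% null band from the beta distribution of uniform
#' order statistics.
#'
#' @param p p-values in (0, 1].
#' @param band pointwise band coverage.
#' @return a tibble with `expected`, `observed`, `lower`, `upper` (all on
#'   the `-log10` scale).
#' @export
qq_data <- function(p, band = 0.95) {
  if (length(p) < 10) rlang::abort("need at least 10 p-values")
  if (any(p <= 0 | p > 1 | !is.finite(p))) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  n <- length(p)
  i <- seq_len(n)
  a <- (1 - band) / 2
  tibble::tibble(
    expected = -log10(i / (n + 1)),
    observed = -log10(sort(p)),
    lower = -log10(stats::qbeta(1 - a, i, n + 1 - i)),
    upper = -log10(stats::qbeta(a, i, n + 1 - i))
  )
}
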