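# test for polygenic adaptive differentiation along kinship PCs

#' Conditional eigensystem of a kinship matrix
#'
#' Principal components for the adaptive-differentiation test come from the
#' kinship matrix conditioned on the panel mean. Two constructions are
#' offered. The default, `"projection"`, centers the matrix
#' (`K_c = C K C` with `C = I - 11'/n`, a no-op for an already-centered
#' kinship) and eigendecomposes it, dropping the null direction along the
#' 1-vector; this matches taking genetic PCs from the eigendecomposition of
#' the (centered) kinship matrix and is exactly invariant to accession
#' reordering. The alternative, `"dropone"`, uses the conditional-MVN
#' transform `L = [I_{n-1} | 0] - (1/n) 11'` (drop the final accession);
#' it yields the same null distribution but statistics that depend on which
#' accession is dropped. Under the neutral model `z ~ MVN(mu 1, Va K)` the
#' projections of the mean-centered trait onto the retained eigenvectors,
#' scaled by the root eigenvalues, are iid `N(0, Va)` in either
#' construction - the property the variance-ratio test relies on.
#'
#' @param kinship a [kinship_centered()] object or PSD matrix.
#' @param centering `"projection"` (default) or `"dropone"`.
#' @return a list with `values` (n-1 eigenvalues, decreasing), `vectors`
#'   (orthonormal columns; length-n rows for `"projection"`), `transform`
#'   (function mapping a trait vector to the conditioned space) and `ids`.
#' @export
conditional_eigen <- function(kinship,
                              centering = c("projection", "dropone")) {
  centering <- match.arg(centering)
  if (inherits(kinship, "kinship_matrix")) {
    K <- kinship$K; ids <- kinship$ids
  } else {
    K <- kinship
    ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  }
  n <- nrow(K)
  if (n < 3) rlang::abort("need at least 3 accessions")
  if (centering == "projection") {
    C <- diag(n) - matrix(1 / n, n, n)
    Kc <- C %*% K %*% C
    Kc <- (Kc + t(Kc)) / 2
    e <- eigen(Kc, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values))) {
      rlang::abort("kinship matrix is not positive semi-definite beyond tolerance")
    }
    ## drop the null direction along the 1-vector (last eigenpair)
    keep <- seq_len(n - 1)
    list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE],
         transform = function(z) z - mean(z), ids = ids,
         centering = centering)
  } else {
    L <- cbind(diag(n - 1), 0) - matrix(1 / n, n - 1, n)
    Kc <- L %*% K %*% t(L)
    Kc <- (Kc + t(Kc)) / 2
    e <- eigen(Kc, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values))) {
      rlang::abort("kinship matrix is not positive semi-definite beyond tolerance")
    }
    list(values = e$values, vectors = e$vectors,
         transform = function(z) drop(L %*% z), ids = ids,
         centering = centering)
  }
}

#' Test a trait for adaptive differentiation along kinship PCs
#'
#' Compares the trait variance along each of the leading kinship principal
#' components to the neutral variance estimated from the tail of the
#' spectrum. With the conditional eigensystem (see [conditional_eigen()]),
#' the standardized projections `c_m = u_m' L z / sqrt(lambda_m)` are iid
#' `N(0, Va)` under neutrality; `Va` is estimated as the mean of `c_m^2`
#' over the tail PCs (`n_tested + 1 ... n - 1`) and each tested PC yields
#' `F_m = c_m^2 / Va_tail ~ F(1, n_tail)` under the null. Excess variance
#' along a leading PC (large `F_m`) indicates adaptive differentiation of
#' the trait along that axis of genetic structure.
#'
#' @param z named trait vector (names = accession ids) aligned with the
#'   kinship matrix.
#' @param kinship a [kinship_centered()] object or PSD matrix.
#' @param n_tested number of leading PCs tested (must be < (n-1)/2).
#' @param trait optional trait label carried into outputs.
#' @param centering conditioning construction, see [conditional_eigen()].
#' @return an object of class `qpc_result`; see [tidy.qpc_result()],
#'   [neutral_envelope()] and [autoplot.qpc_result()].
#' @export
qpc_test <- function(z, kinship, n_tested = 10, trait = "trait",
                     centering = c("projection", "dropone")) {
  ce <- conditional_eigen(kinship, centering)
  n <- length(ce$ids)
  if (n_tested >= (n - 1) / 2) {
    rlang::abort("n_tested must be smaller than (n - 1) / 2")
  }
  if (!is.null(names(z))) {
    if (!all(ce$ids %in% names(z))) {
      rlang::abort("trait vector is missing accessions present in the kinship matrix")
    }
    z <- z[ce$ids]
  } else if (length(z) != n) {
    rlang::abort("unnamed trait vector must match the kinship dimension")
  }
  zt <- ce$transform(z)
  lam <- pmax(ce$values, 0)
  if (any(lam <= 1e-12 * max(lam))) {
    rlang::warn("near-zero conditional eigenvalues present; projections there are unstable")
  }
  cm <- drop(crossprod(ce$vectors, zt)) / sqrt(lam)
  tested <- seq_len(n_tested)
  tail_idx <- (n_tested + 1):(n - 1)
  Va <- mean(cm[tail_idx]^2)
  if (Va <= 1e-12 * stats::var(z)) {
    rlang::abort("degenerate trait: neutral tail variance is zero")
  }
  Fm <- cm[tested]^2 / Va
  pm <- stats::pf(Fm, 1, length(tail_idx), lower.tail = FALSE)
  structure(list(
    trait = trait,
    stats = tibble::tibble(pc = tested, lambda = lam[tested],
                           c_score = cm[tested], F = Fm, p = pm),
    Va_tail = Va, n_tested = n_tested, tail_df = length(tail_idx),
    tail_range = range(tail_idx),
    values = lam, vectors = ce$vectors, z_tilde = zt, ids = ce$ids
  ), class = "qpc_result")
}

#' @export
print.qpc_result <- function(x, ...) {
  cat(sprintf("<qpc_result: %s>\n", x$trait))
  cat(sprintf("  tested PCs 1-%d against tail %d-%d; Va_tail = %.4g\n",
              x$n_tested, x$tail_range[1], x$tail_range[2], x$Va_tail))
  print(x$stats, n = x$n_tested)
  invisible(x)
}

#' Tidy an adaptive-differentiation test
#'
#' @param x a `qpc_result`.
#' @param ... unused.
#' @return a tibble with `trait`, `pc`, `lambda`, `c_score`, `F`, `p`.
#' @method tidy qpc_result
#' @export
tidy.qpc_result <- function(x, ...) {
  dplyr::mutate(x$stats, trait = x$trait, .before = 1)
}

#' Neutral envelope for a trait-vs-PC plot
#'
#' The expected trait-PC relationship under neutrality is a line through the
#' origin whose slope has SD `sqrt(Va_tail * lambda_m)`; the band at PC
#' score `s` is `+/- z_{(1+conf)/2} * sqrt(Va_tail * lambda_m) * |s|`.
#' `fitted` is the observed through-origin regression line.
#'
#' @param qpc a `qpc_result`.
#' @param pc which tested PC.
#' @param confidence band coverage (default 0.90).
#' @param n_grid number of grid points along the observed score range.
#' @return a tibble with `pc_score`, `fitted`, `lower`, `upper`.
#' @export
neutral_envelope <- function(qpc, pc = 1, confidence = 0.90, n_grid = 51) {
  stopifnot(inherits(qpc, "qpc_result"), pc %in% qpc$stats$pc)
  assert_fraction(confidence, "confidence", 0, 1)
  lam <- qpc$stats$lambda[qpc$stats$pc == pc]
  slope_obs <- qpc$stats$c_score[qpc$stats$pc == pc] * sqrt(lam)
  scores <- qpc$vectors[, pc]
  smax <- max(abs(scores))
  grid <- seq(-smax, smax, length.out = n_grid)
  half <- stats::qnorm((1 + confidence) / 2) * sqrt(qpc$Va_tail * lam) * abs(grid)
  tibble::tibble(pc_score = grid, fitted = slope_obs * grid,
                 lower = -half, upper = half)
}

#' Screen several traits (and optional accession subsets) for adaptive
#' differentiation
#'
#' Runs [qpc_test()] for each trait column and returns a flat summary; an
#' optional accession subset supports robustness re-analyses that exclude a
#' geographic group.
#'
#' @param data tibble with `accession` and trait columns.
#' @param kinship a [kinship_centered()] object.
#' @param traits trait column names (default: all numeric columns).
#' @param n_tested leading PCs to test.
#' @param subset optional accession ids to retain (kinship is subset and
#'   re-decomposed); must contain more than `2 * n_tested` accessions.
#' @param alpha significance level for the `significant` flag.
#' @param centering conditioning construction, see [conditional_eigen()].
#' @return a list with `results` (named list of `qpc_result`) and `summary`
#'   (tibble: trait, pc, lambda, F, p, significant).
#' @export
qpc_screen <- function(data, kinship, traits = NULL, n_tested = 10,
                       subset = NULL, alpha = 0.05,
                       centering = c("projection", "dropone")) {
  centering <- match.arg(centering)
  stopifnot(inherits(kinship, "kinship_matrix"))
  require_columns(data, "accession", "data")
  traits <- traits %||%
    names(data)[vapply(data, is.numeric, TRUE)]
  if (!length(traits)) rlang::abort("no traits to screen")
  kin <- kinship
  d <- data
  if (!is.null(subset)) {
    if (length(subset) <= 2 * n_tested) {
      rlang::abort("subset must contain more than 2 * n_tested accessions")
    }
    keep <- kinship$ids %in% subset
    K <- kinship$K[keep, keep]
    rownames(K) <- colnames(K) <- kinship$ids[keep]
    e <- eigen(K, symmetric = TRUE)
    kin <- structure(list(K = K, ids = kinship$ids[keep],
                          values = e$values, vectors = e$vectors),
                     class = "kinship_matrix")
    d <- d[d$accession %in% subset, ]
  }
  results <- purrr::map(traits, function(tr) {
    z <- stats::setNames(d[[tr]], d$accession)
    qpc_test(z, kin, n_tested = n_tested, trait = tr,
             centering = centering)
  })
  names(results) <- traits
  summary <- purrr::map(results, tidy) |> dplyr::bind_rows() |>
    dplyr::mutate(significant = .data$p < alpha)
  list(results = results, summary = summary)
}
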