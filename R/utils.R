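# internal helpers shared across modules

# standardize to mean 0, sd 1 (idempotent up to floating point)
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    rlang::abort("cannot standardize a zero-variance vector")
  }
  (x - mean(x, na.rm = TRUE)) / s
}

# residualize y on columns of X (with intercept), return standardized residual
residualize_std <- function(y, X) {
  r <- stats::lm.fit(cbind(1, X), y)$residuals
  standardize(r)
}

# draw n_draws vectors from MVN(mu, V) given an eigendecomposition of V;
# negative eigenvalues within tolerance are clamped to zero
rmvn_eigen <- function(n_draws, mu, values, vectors, tol = 1e-8) {
  lam <- values
  if (min(lam) < -tol * max(abs(lam), 1)) {
    rlang::abort("covariance matrix is not positive semi-definite beyond tolerance")
  }
  lam <- pmax(lam, 0)
  n <- length(lam)
  E <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  sweep(vectors %*% (sqrt(lam) * E), 1, -mu)  # mu + U sqrt(L) E
}

# Cholesky factor of a CAR1 correlation matrix over timepoints tt
car1_chol <- function(tt, phi) {
  if (phi <= 0) return(diag(length(tt)))
  chol(phi^abs(outer(tt, tt, "-")))
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (lo_open) x > lo else x >= lo) &
    (if (hi_open) x < hi else x <= hi)
  if (!all(ok)) {
    rlang::abort(sprintf("`%s` must lie in %s%g, %g%s", name,
                         if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]"))
  }
  invisible(x)
}

require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# temperature treatment label ("16C"/"6C") from numeric or character input,
# reference level = warmer treatment
temperature_factor <- function(x) {
  lab <- ifelse(grepl("C$", as.character(x)), as.character(x),
                paste0(as.character(x), "C"))
  num <- as.numeric(sub("C$", "", lab))
  levs <- paste0(sort(unique(num), decreasing = TRUE), "C")
  factor(lab, levels = levs)
}
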