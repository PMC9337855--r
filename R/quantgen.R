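# heritability, climate correlations, variance partitioning

# ---- shared mixed-model engine -------------------------------------------
# ML/REML fit of y = X beta + g + e with g ~ N(0, sg2 * K), e ~ N(0, se2 * I),
# via eigen-rotation of K and 1-D optimization over the variance ratio
# gamma = sg2 / se2. Returns GLS coefficients at the optimum.
lmm_eigen_fit <- function(y, X, values, vectors, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  yt <- crossprod(vectors, y)
  Xt <- crossprod(vectors, X)
  lam <- pmax(values, 0)

  profile <- function(log_gamma) {
    gamma <- exp(log_gamma)
    w <- 1 / (gamma * lam + 1)           # up to se2 scale
    XtW <- Xt * w
    A <- crossprod(XtW, Xt)
    b <- crossprod(XtW, yt)
    beta <- solve(A, b)
    res <- yt - Xt %*% beta
    rss <- sum(w * res^2)
    if (reml) {
      se2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * se2) - sum(log(w)) +
                      determinant(A, logarithm = TRUE)$modulus + (n - p))
    } else {
      se2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * se2) - sum(log(w)) + n)
    }
    list(ll = as.numeric(ll), beta = beta, se2 = se2, A = A, w = w)
  }
  opt <- stats::optimize(function(lg) -profile(lg)$ll, c(-12, 12), tol = 1e-8)
  ## compare against the no-genetic-variance boundary
  at_opt <- profile(opt$minimum)
  at_zero <- profile(-25)
  use <- if (at_zero$ll > at_opt$ll) list(sol = at_zero, gamma = 0) else
    list(sol = at_opt, gamma = exp(opt$minimum))
  sol <- use$sol
  cov_beta <- sol$se2 * solve(sol$A)
  se <- sqrt(diag(cov_beta))
  tval <- as.vector(sol$beta) / se
  list(beta = as.vector(sol$beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), n - p),
       gamma = use$gamma, sigma2_e = sol$se2,
       sigma2_g = use$gamma * sol$se2, loglik = sol$ll, df = n - p)
}

#' Pairwise Pearson correlations between traits and climate variables
#'
#' Pairwise-complete Pearson correlation and two-sided t-test for every
#' (trait, variable) pair; zero-variance pairs are reported as missing.
#'
#' @param pheno tibble with `accession` and trait columns.
#' @param climate tibble with `accession` and climate variable columns.
#' @param traits,variables optional column subsets (defaults: all numeric).
#' @return a tibble with `trait`, `variable`, `n`, `r`, `p`.
#' @export
pearson_correlations <- function(pheno, climate, traits = NULL,
                                 variables = NULL) {
  require_columns(pheno, "accession", "pheno")
  require_columns(climate, "accession", "climate")
  d <- dplyr::left_join(pheno, climate, by = "accession",
                        suffix = c("", ".clim"))
  num <- function(tb) names(tb)[vapply(tb, is.numeric, TRUE)]
  traits <- traits %||% intersect(num(pheno), names(pheno))
  variables <- variables %||% intersect(num(climate), names(climate))
  grid <- expand.grid(trait = traits, variable = variables,
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(trait, variable) {
    x <- d[[trait]]
    yv <- if (variable %in% names(d)) d[[variable]] else d[[paste0(variable, ".clim")]]
    ok <- stats::complete.cases(x, yv)
    n_ok <- sum(ok)
    if (n_ok < 3 || stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      return(tibble::tibble(trait = trait, variable = variable,
                            n = n_ok, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], yv[ok])
    tibble::tibble(trait = trait, variable = variable, n = n_ok,
                   r = unname(ct$estimate), p = ct$p.value)
  }) |> dplyr::bind_rows()
}

#' Kinship-corrected trait-climate correlation
#'
#' Population structure confounds trait-climate correlations. This fits the
#' mixed model `y = beta * x + g + e` with `g ~ N(0, sg2 * K)` by ML via
#' eigen-rotation of the kinship matrix; both variables are standardized
#' internally so the coefficient `beta` is comparable to a Pearson
#' correlation. With `K = I` (no structure) the corrected coefficient
#' equals the Pearson correlation exactly.
#'
#' @param data tibble with `accession`, the trait and the climate variable.
#' @param trait,variable column names.
#' @param kinship a [kinship_centered()] object (ids must cover the data).
#' @return a one-row tibble: `trait`, `variable`, `n`, `r`, `p`,
#'   `r_corrected` (standardized mixed-model coefficient), `p_corrected`,
#'   and the fitted variance ratio `gamma` (genetic / residual).
#' @export
kinship_corrected_correlation <- function(data, trait, variable, kinship) {
  stopifnot(inherits(kinship, "kinship_matrix"))
  require_columns(data, c("accession", trait, variable), "data")
  d <- data[stats::complete.cases(data[[trait]], data[[variable]]), ]
  idx <- match(d$accession, kinship$ids)
  if (anyNA(idx)) {
    rlang::abort("accession(s) in data are missing from the kinship matrix")
  }
  y <- standardize(d[[trait]])
  x <- standardize(d[[variable]])
  Ksub <- kinship$K[idx, idx]
  e <- if (length(idx) == length(kinship$ids) && all(idx == seq_along(idx))) {
    list(values = kinship$values, vectors = kinship$vectors)
  } else eigen(Ksub, symmetric = TRUE)
  fit <- lmm_eigen_fit(y, cbind(1, x), e$values, e$vectors)
  ct <- stats::cor.test(d[[trait]], d[[variable]])
  tibble::tibble(trait = trait, variable = variable, n = length(y),
                 r = unname(ct$estimate), p = ct$p.value,
                 r_corrected = fit$beta[2], p_corrected = fit$p[2],
                 gamma = fit$gamma)
}

#' Broad-sense heritability from replicate plants of inbred accessions
#'
#' Fits the linear mixed model `trait ~ experiment + (1 | accession)` by
#' REML on per-plant parameter estimates and returns
#' `H2 = Vg / (Vg + Ve)` where `Vg` is the accession variance component and
#' `Ve` the residual variance. The experiment fixed effect removes
#' between-experiment variance (dropped automatically when only one
#' experiment is present). Growth-rate heritabilities are computed within
#' one temperature at a time by passing `temperature`.
#'
#' @param plant_params tibble of per-plant estimates (see
#'   [plant_estimates()]), with `accession`, optionally `experiment` and
#'   `temperature_C`, and the trait column.
#' @param trait trait column name (e.g. `"M0"` or `"r"`).
#' @param temperature optional numeric treatment (e.g. 16) to subset on.
#' @return a one-row tibble: `trait`, `temperature`, `Vg`, `Ve`, `H2`,
#'   `n_plants`, `n_accessions`.
#' @export
heritability <- function(plant_params, trait, temperature = NULL) {
  require_columns(plant_params, c("accession", trait), "plant_params")
  d <- plant_params
  if (!is.null(temperature)) {
    require_columns(d, "temperature_C", "plant_params")
    d <- d[d$temperature_C == temperature, ]
  }
  d <- d[stats::complete.cases(d[[trait]]), ]
  if (length(unique(d$accession)) < 2) {
    rlang::abort("need plants from at least 2 accessions")
  }
  d$.y <- d[[trait]]
  use_exp <- "experiment" %in% names(d) && length(unique(d$experiment)) > 1
  form <- if (use_exp) .y ~ experiment + (1 | accession) else .y ~ (1 | accession)
  fit <- lme4::lmer(form, data = d,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  Vg <- vc$vcov[vc$grp == "accession"]
  Ve <- vc$vcov[vc$grp == "Residual"]
  if (Vg <= 1e-12) {
    rlang::warn("accession variance estimated at the boundary: H2 = 0")
    Vg <- 0
  }
  tibble::tibble(trait = trait,
                 temperature = temperature %||% NA_real_,
                 Vg = Vg, Ve = Ve, H2 = Vg / (Vg + Ve),
                 n_plants = nrow(d),
                 n_accessions = length(unique(d$accession)))
}

#' Partition initial-size variance between winter temperature and seed size
#'
#' Joint linear model of the response on both (standardized) predictors;
#' the variance fraction attributed to predictor `j` is
#' `var(beta_j * x_j) / var(y)` (for orthogonal predictors the fractions sum
#' to the R-squared of the joint fit). The focal-predictor association is
#' additionally re-tested with the covariate absorbed as a one-column
#' random effect (a rank-1 variance component), mirroring a
#' covariate-as-random-effect correction.
#'
#' @param data tibble containing the response and both predictors.
#' @param response response column name (initial size).
#' @param focal focal predictor (winter temperature).
#' @param covariate covariate predictor (seed size).
#' @return a tibble with one row per predictor: `term`, `beta_std`
#'   (standardized joint-model coefficient), `var_fraction`, `p_joint`, and
#'   for the focal predictor `p_corrected` (covariate as random effect).
#' @export
variance_partition <- function(data, response = "M0", focal = "winter_temp",
                               covariate = "seed_size") {
  require_columns(data, c(response, focal, covariate), "data")
  d <- data[stats::complete.cases(data[[response]], data[[focal]],
                                  data[[covariate]]), ]
  y <- standardize(d[[response]])
  x1 <- standardize(d[[focal]])
  x2 <- standardize(d[[covariate]])
  if (abs(stats::cor(x1, x2)) > 0.99) {
    rlang::abort("predictors are collinear (|r| > 0.99)")
  }
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)$coefficients
  beta <- coef(fit)[c("x1", "x2")]
  frac <- c(stats::var(beta[1] * x1), stats::var(beta[2] * x2)) / stats::var(y)

  ## focal association with the covariate as a rank-1 random effect
  Kcov <- tcrossprod(x2)
  e <- eigen(Kcov, symmetric = TRUE)
  corr <- lmm_eigen_fit(y, cbind(1, x1), e$values, e$vectors)

  tibble::tibble(
    term = c(focal, covariate),
    beta_std = unname(beta),
    var_fraction = unname(frac),
    p_joint = unname(sm[c("x1", "x2"), "Pr(>|t|)"]),
    p_corrected = c(corr$p[2], NA_real_)
  )
}
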