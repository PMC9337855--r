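# hierarchical growth-model fitting (nonlinear mixed models via nlme)

#' Growth-curve model functions with analytic gradients
#'
#' Closed-form exponential and power-law curves parameterized with
#' `lM0 = log(M0)` (keeping the initial size positive), carrying analytic
#' gradient attributes for the nonlinear mixed-model fitter. Exported
#' because [nlme::nlme()] resolves the model function at evaluation time.
#'
#' @param lM0,r,b curve parameters (log initial size, rate, scaling
#'   exponent).
#' @param time treatment days.
#' @return fitted sizes with a `gradient` attribute.
#' @keywords internal
#' @export
.grad_exp <- stats::deriv(~ exp(lM0 + r * time), c("lM0", "r"),
                          function(lM0, r, time) {})

#' @rdname dot-grad_exp
#' @keywords internal
#' @export
.grad_pl <- stats::deriv(~ (exp(lM0 * (1 - b)) + r * time * (1 - b))^(1 / (1 - b)),
                         c("lM0", "r", "b"), function(lM0, r, b, time) {})

default_growth_control <- function() {
  nlme::nlmeControl(maxIter = 100, pnlsMaxIter = 10, msMaxIter = 200,
                    tolerance = 1e-5, returnObject = TRUE)
}

# normalize a phenotype table for fitting: treatment-day clock, factors
prepare_growth_data <- function(data) {
  require_columns(data, c("plant_id", "area"), "phenotype table")
  tcol <- if ("time_dap" %in% names(data)) "time_dap" else "time"
  require_columns(data, tcol, "phenotype table")
  d <- as.data.frame(data)
  d$time <- if (tcol == "time_dap") d$time_dap - 14 else d$time
  if ("usable" %in% names(d)) d <- d[d$usable, , drop = FALSE]
  if (any(d$area <= 0)) rlang::abort("areas must be positive; run clean_series() first")
  d$plant_id <- factor(d$plant_id)
  if ("accession" %in% names(d)) d$accession <- factor(d$accession)
  if ("temperature_C" %in% names(d)) {
    d$temperature <- temperature_factor(d$temperature_C)
  }
  if ("experiment" %in% names(d)) d$experiment <- factor(d$experiment)
  d[order(d$plant_id, d$time), , drop = FALSE]
}

new_model_fit <- function(model_kind, loglik, k, n_obs, fixed_effects = NULL,
                          re_cov = NULL, sigma2 = NA_real_, phi = NA_real_,
                          object = NULL, data = NULL, levels = NULL) {
  aic <- 2 * k - 2 * loglik
  bic <- k * log(n_obs) - 2 * loglik
  fit <- structure(list(
    model_kind = model_kind, loglik = loglik, k = as.integer(k),
    n_obs = as.integer(n_obs), aic = aic, bic = bic,
    fixed_effects = fixed_effects, re_cov = re_cov, sigma2 = sigma2,
    phi = phi, object = object, levels = levels, data = data
  ), class = "growth_fit")
  stopifnot(abs(fit$aic - (2 * fit$k - 2 * fit$loglik)) < 1e-8,
            abs(fit$bic - (fit$k * log(fit$n_obs) - 2 * fit$loglik)) < 1e-8)
  fit
}

#' Construct a growth-model fit record from summary quantities
#'
#' Builds a lightweight `growth_fit` record from a log-likelihood, a
#' parameter count and a sample size, computing AIC and BIC from their
#' defining identities (`AIC = 2k - 2 logLik`,
#' `BIC = k log(n) - 2 logLik`). Useful for model-comparison arithmetic on
#' published fit summaries.
#'
#' @param model_kind `"exponential"` or `"powerlaw"`.
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects + unique
#'   random-effect covariance entries + residual variance, + 1 when a CAR1
#'   parameter is estimated).
#' @param n_obs number of observations.
#' @return a `growth_fit` object.
#' @export
#' @examples
#' model_fit_record("powerlaw", loglik = 435312.5, k = 10, n_obs = 291000)$aic
model_fit_record <- function(model_kind = c("exponential", "powerlaw"),
                             loglik, k, n_obs) {
  model_kind <- match.arg(model_kind)
  new_model_fit(model_kind, loglik, k, n_obs)
}

# gross-outlier pass standing in for visual inspection of growth profiles:
# per-plant self-start curve, drop observations whose residual
# exceeds z robust-SD units (a no-op on artifact-free data)
trim_gross_outliers <- function(d, model_kind = "powerlaw", z = 5) {
  if (!is.finite(z)) return(d)
  res <- numeric(nrow(d))
  for (ix in split(seq_len(nrow(d)), d$plant_id)) {
    g <- d[ix, ]
    if (nrow(g) < 4) next
    ss <- suppressWarnings(growth_selfstart(g$time, g$area, model_kind))
    pred <- try(powerlaw_size(g$time, ss$M0, ss$r, ss$beta), silent = TRUE)
    if (inherits(pred, "try-error")) next
    res[ix] <- g$area - pred
  }
  scale <- stats::mad(res[res != 0])
  if (!is.finite(scale) || scale <= 0) return(d)
  keep <- abs(res) <= z * scale
  if (all(keep)) return(d)
  d <- d[keep, , drop = FALSE]
  d[stats::ave(seq_len(nrow(d)), d$plant_id, FUN = length) >= 4, , drop = FALSE]
}

# try a fit, jittering starting values on failure
fit_with_restarts <- function(fitter, start, n_restarts = 3) {
  last_err <- NULL
  for (i in 0:n_restarts) {
    st <- if (i == 0) start else
      start * (1 + stats::rnorm(length(start), 0, 0.05)) +
        stats::rnorm(length(start), 0, 0.01)
    out <- try(fitter(st), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    last_err <- attr(out, "condition")$message
  }
  rlang::abort(sprintf("growth model did not converge after %d restarts: %s",
                       n_restarts, last_err))
}

#' Fit the first-stage hierarchical growth model
#'
#' Fits a nonlinear mixed model with a common (fixed) parameter vector and
#' per-plant random effects on every curve parameter with unstructured
#' covariance: `(log M0, r)` for the exponential model, `(log M0, r, beta)`
#' for the power-law model. Residuals are iid Gaussian at this stage (no
#' CAR1). The parameter count follows the convention
#' fixed effects + unique random-effect covariance entries + residual
#' variance, giving `k = 6` (exponential) and `k = 10` (power-law). See
#' [fit_growth_models()] to fit and compare both models with the nesting
#' safeguard.
#'
#' @param data cleaned long phenotype table (see [clean_series()]), with
#'   `plant_id`, `time_dap` (or `time`, treatment days) and `area`.
#' @param model_kind `"powerlaw"` or `"exponential"`.
#' @param method `"ML"` (default, valid for likelihood-ratio comparison) or
#'   `"REML"`.
#' @param start optional starting values (`c(lM0, r)` or `c(lM0, r, beta)`);
#'   derived from [growth_selfstart()] when omitted.
#' @param control an [nlme::nlmeControl()] list.
#' @param trim_z robust-residual threshold for the pre-fit gross-outlier
#'   pass (per-plant self-start residuals; `Inf` disables). Emulates the
#'   visual-inspection discard of corrupted datapoints that the
#'   running-maximum filter cannot catch.
#' @return a `growth_fit` object; see [glance.growth_fit()].
#' @export
fit_stage1 <- function(data, model_kind = c("powerlaw", "exponential"),
                       method = "ML", start = NULL,
                       control = default_growth_control(), trim_z = 5) {
  model_kind <- match.arg(model_kind)
  d <- prepare_growth_data(data)
  d <- trim_gross_outliers(d, model_kind, trim_z)
  d$plant_id <- droplevels(d$plant_id)
  if (nlevels(d$plant_id) < 2) rlang::abort("need at least 2 plants")

  if (is.null(start)) {
    pls <- levels(d$plant_id)
    if (length(pls) > 40) pls <- pls[round(seq(1, length(pls), length.out = 40))]
    ss <- purrr::map(pls, function(p) {
      g <- d[d$plant_id == p, ]
      growth_selfstart(g$time, g$area, model_kind)
    }) |> dplyr::bind_rows()
    start <- c(log(median(ss$M0)), median(ss$r))
    if (model_kind == "powerlaw") start <- c(start, median(ss$beta))
  }

  fitter <- function(st) {
    if (model_kind == "exponential") {
      nlme::nlme(area ~ .grad_exp(lM0, r, time),
                 fixed = lM0 + r ~ 1, random = lM0 + r ~ 1 | plant_id,
                 data = d, start = st, method = method, control = control)
    } else {
      nlme::nlme(area ~ .grad_pl(lM0, r, b, time),
                 fixed = lM0 + r + b ~ 1, random = lM0 + r + b ~ 1 | plant_id,
                 data = d, start = st, method = method, control = control)
    }
  }
  obj <- fit_with_restarts(fitter, start)
  as_growth_fit(obj, model_kind, d)
}

#' Fit and compare both stage-1 growth models
#'
#' Fits the exponential and power-law stage-1 models on the same data and
#' compares them by likelihood ratio. The gross-outlier pass is applied
#' once (with the power-law self-start) before either fit, so both
#' likelihoods are computed on identical observations — a requirement for
#' the LRT. Because the exponential model is nested in the power-law model,
#' the power-law likelihood cannot genuinely fall below the exponential
#' one; if the optimizer converges below it, the power-law fit is restarted
#' from the exponential solution (`beta` near 1).
#'
#' @inheritParams fit_stage1
#' @return a list with `exponential`, `powerlaw` (both `growth_fit`) and
#'   `comparison` (see [compare_models()]).
#' @export
fit_growth_models <- function(data, method = "ML",
                              control = default_growth_control(),
                              trim_z = 5) {
  d <- prepare_growth_data(data)
  d <- trim_gross_outliers(d, "powerlaw", trim_z)
  fe <- fit_stage1(d, "exponential", method = method, control = control,
                   trim_z = Inf)
  fp <- fit_stage1(d, "powerlaw", method = method, control = control,
                   trim_z = Inf)
  if (fp$loglik < fe$loglik) {
    st <- c(fe$fixed_effects[["lM0"]], fe$fixed_effects[["r"]], 0.98)
    fp2 <- try(fit_stage1(d, "powerlaw", method = method, start = st,
                          control = control, trim_z = Inf), silent = TRUE)
    if (!inherits(fp2, "try-error") && fp2$loglik > fp$loglik) fp <- fp2
  }
  list(exponential = fe, powerlaw = fp, comparison = compare_models(fe, fp))
}

# wrap an nlme object into a growth_fit
as_growth_fit <- function(obj, model_kind, d, levels = NULL) {
  ll <- logLik(obj)
  re_cov <- try(nlme::getVarCov(obj), silent = TRUE)
  if (inherits(re_cov, "try-error")) {
    re_cov <- lapply(obj$modelStruct$reStruct, function(x)
      as.matrix(nlme::pdMatrix(x)) * obj$sigma^2)
  }
  phi <- NA_real_
  if (!is.null(obj$modelStruct$corStruct)) {
    phi <- as.numeric(coef(obj$modelStruct$corStruct, unconstrained = FALSE))
  }
  new_model_fit(model_kind, as.numeric(ll), attr(ll, "df"), obj$dims$N,
                fixed_effects = nlme::fixef(obj), re_cov = re_cov,
                sigma2 = obj$sigma^2, phi = phi, object = obj,
                data = d, levels = levels)
}

#' Compare nested exponential and power-law growth-model fits
#'
#' Likelihood-ratio comparison of the stage-1 fits (the exponential model is
#' the power-law model with `beta` fixed at 1 and its random effect
#' removed). Returns a table with one row per model mirroring the usual
#' ANOVA layout: parameter count, AIC, BIC, log-likelihood, the LRT
#' statistic `2 * (logLik_pl - logLik_exp)` and its chi-squared p-value.
#'
#' @param fit_exp,fit_pl `growth_fit` objects for the exponential and
#'   power-law models on the same data.
#' @return a tibble with columns `model`, `df`, `AIC`, `BIC`, `logLik`,
#'   `test`, `L.ratio`, `p_value`.
#' @export
compare_models <- function(fit_exp, fit_pl) {
  stopifnot(inherits(fit_exp, "growth_fit"), inherits(fit_pl, "growth_fit"))
  if (fit_pl$k <= fit_exp$k) {
    rlang::abort("models are not nested as expected: k_powerlaw must exceed k_exponential")
  }
  lr <- 2 * (fit_pl$loglik - fit_exp$loglik)
  df_diff <- fit_pl$k - fit_exp$k
  p <- stats::pchisq(lr, df_diff, lower.tail = FALSE)
  tibble::tibble(
    model = c("exponential", "powerlaw"),
    df = c(fit_exp$k, fit_pl$k),
    AIC = c(fit_exp$aic, fit_pl$aic),
    BIC = c(fit_exp$bic, fit_pl$bic),
    logLik = c(fit_exp$loglik, fit_pl$loglik),
    test = c(NA_character_, "1 vs 2"),
    L.ratio = c(NA_real_, lr),
    p_value = c(NA_real_, p)
  )
}

#' Fit the second-stage power-law growth model with design fixed effects
#'
#' The full hierarchical model used to derive accession-level phenotypes:
#' a power-law nonlinear mixed model in which log initial size has accession
#' fixed effects (initial size precedes the treatment, so no temperature
#' term), the growth rate has accession, temperature and interaction fixed
#' effects, and the scaling exponent `beta` is a single shared parameter.
#' Every curve parameter carries random effects for individual plants
#' (nested within experiment when several experiments are present; diagonal
#' covariance), and within-plant residuals follow a continuous-AR1
#' correlation `phi^|t_i - t_j|` (in days) when `car1 = TRUE`.
#'
#' @param data cleaned long phenotype table with `plant_id`, `accession`,
#'   `experiment`, `temperature_C`, `time_dap` (or `time`) and `area`.
#' @param car1 include the continuous-AR1 residual correlation.
#' @param method `"ML"` or `"REML"`.
#' @param beta_start optional starting value for `beta`; profiled from
#'   per-plant self-starts when omitted.
#' @param control an [nlme::nlmeControl()] list.
#' @param trim_z robust-residual threshold for the pre-fit gross-outlier
#'   pass (see [fit_stage1()]; `Inf` disables).
#' @return a `growth_fit`; pass to [accession_estimates()] and
#'   [plant_estimates()].
#' @export
fit_stage2 <- function(data, car1 = TRUE, method = "ML", beta_start = NULL,
                       control = default_growth_control(), trim_z = 5) {
  d <- prepare_growth_data(data)
  require_columns(d, c("accession", "temperature"), "phenotype table")
  d <- trim_gross_outliers(d, "powerlaw", trim_z)
  for (col in c("plant_id", "accession", "experiment"))
    if (col %in% names(d)) d[[col]] <- droplevels(d[[col]])
  if (nlevels(d$accession) < 2) rlang::abort("need at least 2 accessions")
  two_temps <- nlevels(droplevels(d$temperature)) >= 2
  if (!two_temps) {
    rlang::warn("single temperature treatment: fitting without temperature terms")
    d$temperature <- droplevels(d$temperature)
  }
  multi_exp <- "experiment" %in% names(d) && nlevels(d$experiment) > 1

  ## beta start: median of per-plant power-law self-starts
  if (is.null(beta_start)) {
    pls <- levels(d$plant_id)
    if (length(pls) > 30) pls <- pls[round(seq(1, length(pls), length.out = 30))]
    b0s <- purrr::map_dbl(pls, function(p) {
      g <- d[d$plant_id == p, ]
      growth_selfstart(g$time, g$area, "powerlaw")$beta
    })
    beta_start <- stats::median(b0s)
  }
  start <- stage2_starts(d, beta_start, two_temps)

  fixed <- if (two_temps) {
    list(lM0 ~ accession, r ~ accession * temperature, b ~ 1)
  } else {
    list(lM0 ~ accession, r ~ accession, b ~ 1)
  }
  fitter <- function(st) {
    args <- list(
      model = area ~ .grad_pl(lM0, r, b, time),
      fixed = fixed, data = d, start = st, method = method, control = control)
    if (multi_exp) {
      args$random <- list(experiment = nlme::pdDiag(lM0 + r + b ~ 1),
                          plant_id = nlme::pdDiag(lM0 + r + b ~ 1))
      if (car1) args$correlation <-
          nlme::corCAR1(0.3, form = ~ time | experiment / plant_id)
    } else {
      args$random <- nlme::pdDiag(lM0 + r + b ~ 1)
      args$groups <- ~plant_id
      if (car1) args$correlation <- nlme::corCAR1(0.3, form = ~ time | plant_id)
    }
    do.call(nlme::nlme, args)
  }
  obj <- fit_with_restarts(fitter, start)
  as_growth_fit(obj, "powerlaw", d,
                levels = list(accession = levels(d$accession),
                              temperature = levels(droplevels(d$temperature))))
}

# linearized per-accession starting values for the stage-2 fixed effects
stage2_starts <- function(d, b0, two_temps) {
  om <- 1 - b0
  grp <- interaction(d$accession, d$temperature, drop = FALSE)
  cf <- vapply(split(d, grp), function(g) {
    if (nrow(g) < 2) return(c(NA_real_, NA_real_))
    stats::lm.fit(cbind(1, g$time), g$area^om)$coefficients
  }, numeric(2))
  key <- strsplit(colnames(cf), "\\.")
  accs <- vapply(key, `[`, "", 1)
  temps <- vapply(key, `[`, "", 2)
  M0g <- pmax(cf[1, ], 1e-6)^(1 / om)
  rg <- cf[2, ] / om
  acc_levels <- levels(d$accession)
  lM0s <- tapply(log(M0g), accs, mean, na.rm = TRUE)[acc_levels]
  lM0s[is.na(lM0s)] <- mean(lM0s, na.rm = TRUE)
  temp_levels <- levels(droplevels(d$temperature))
  rmat <- vapply(temp_levels, function(tl) {
    v <- tapply(ifelse(temps == tl, rg, NA), accs, mean, na.rm = TRUE)[acc_levels]
    v[is.na(v) | is.nan(v)] <- mean(v, na.rm = TRUE)
    v
  }, numeric(length(acc_levels)))
  r1 <- rmat[, 1]
  st <- c(lM0s[1], lM0s[-1] - lM0s[1], r1[1], r1[-1] - r1[1])
  if (two_temps) {
    r2 <- rmat[, 2]
    st <- c(st, r2[1] - r1[1], (r2[-1] - r1[-1]) - (r2[1] - r1[1]))
  }
  unname(c(st, b0))
}

#' Accession-level growth phenotypes from a stage-2 fit
#'
#' Reconstructs, from the fixed effects only (random effects excluded), each
#' accession's initial size `M0`, growth rate in the warm and cold
#' treatments (`r16`, `r6`) and the temperature response `r16 - r6`.
#'
#' @param fit a `growth_fit` from [fit_stage2()].
#' @param accessions optional subset of accession ids; an id absent from the
#'   fit is an error.
#' @return a tibble with one row per accession: `accession`, `M0`, `r16`,
#'   `r6`, `response` (single-temperature fits return the available rate
#'   column only).
#' @export
accession_estimates <- function(fit, accessions = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(fit$levels)) rlang::abort("fit has no design levels; use fit_stage2()")
  fe <- fit$fixed_effects
  acc <- fit$levels$accession
  temps <- fit$levels$temperature
  if (!is.null(accessions)) {
    bad <- setdiff(accessions, acc)
    if (length(bad)) {
      rlang::abort(sprintf("accession(s) not in fit: %s",
                           paste(bad, collapse = ", ")))
    }
    acc_out <- accessions
  } else acc_out <- acc

  fe_get <- function(nm) ifelse(nm %in% names(fe), fe[nm], 0)
  acc_term <- function(prefix, a) {
    ifelse(a == acc[1], 0, fe_get(paste0(prefix, "accession", a)))
  }
  lM0 <- fe[["lM0.(Intercept)"]] + acc_term("lM0.", acc_out)
  r1 <- fe[["r.(Intercept)"]] + acc_term("r.", acc_out)
  out <- tibble::tibble(accession = acc_out, M0 = unname(exp(lM0)))
  rate_name <- function(tl) paste0("r", sub("C$", "", tl))
  out[[rate_name(temps[1])]] <- unname(r1)
  if (length(temps) >= 2) {
    main2 <- fe_get(paste0("r.temperature", temps[2]))
    int2 <- ifelse(acc_out == acc[1], 0,
                   fe_get(paste0("r.accession", acc_out, ":temperature", temps[2])))
    out[[rate_name(temps[2])]] <- unname(r1 + main2 + int2)
    if (all(c("r16", "r6") %in% names(out))) {
      out$response <- temperature_response(out$r6, out$r16)
    }
  }
  out
}

#' Plant-level growth parameters from a stage-2 fit
#'
#' Per-plant parameter estimates combining the fixed effects with each
#' plant's conditional random-effect modes (BLUPs). These are the inputs to
#' the broad-sense heritability calculation, where the within-accession
#' spread of plant estimates provides the environmental variance.
#'
#' @param fit a `growth_fit` from [fit_stage2()].
#' @return a tibble with `plant_id`, `accession`, `experiment`,
#'   `temperature_C`, `M0`, `r`, `beta` (each plant's rate is for its own
#'   treatment).
#' @export
plant_estimates <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(fit$object)) rlang::abort("fit carries no model object")
  cf <- coef(fit$object)
  plant <- sub(".*/", "", rownames(cf))
  d <- fit$data
  design <- unique(d[, intersect(c("plant_id", "accession", "experiment",
                                   "temperature", "temperature_C"), names(d))])
  design <- design[match(plant, as.character(design$plant_id)), ]
  acc <- as.character(design$accession)
  temps <- fit$levels$temperature
  tl <- as.character(design$temperature)
  ref_acc <- fit$levels$accession[1]

  col <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  pick <- function(prefix, key, zero_key) {
    vapply(seq_along(key), function(i) {
      if (key[i] == zero_key) 0 else {
        nm <- paste0(prefix, key[i])
        if (nm %in% names(cf)) cf[i, nm] else 0
      }
    }, numeric(1))
  }
  lM0 <- cf[["lM0.(Intercept)"]] + pick("lM0.accession", acc, ref_acc)
  r <- cf[["r.(Intercept)"]] + pick("r.accession", acc, ref_acc)
  if (length(temps) >= 2) {
    is2 <- tl == temps[2]
    main2 <- if (paste0("r.temperature", temps[2]) %in% names(cf))
      cf[[paste0("r.temperature", temps[2])]] else rep(0, nrow(cf))
    r <- r + ifelse(is2, main2, 0)
    intnames <- paste0("r.accession", acc, ":temperature", temps[2])
    intval <- vapply(seq_along(acc), function(i) {
      if (is2[i] && acc[i] != ref_acc && intnames[i] %in% names(cf))
        cf[i, intnames[i]] else 0
    }, numeric(1))
    r <- r + intval
  }
  tibble::tibble(
    plant_id = plant,
    accession = acc,
    experiment = if ("experiment" %in% names(design))
      as.character(design$experiment) else NA_character_,
    temperature_C = as.numeric(sub("C$", "", tl)),
    M0 = exp(lM0), r = r, beta = cf[["b"]]
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: %s>\n", x$model_kind))
  cat(sprintf("  logLik %.2f, k = %d, AIC %.2f, BIC %.2f, n = %d\n",
              x$loglik, x$k, x$aic, x$bic, x$n_obs))
  if (!is.na(x$phi)) cat(sprintf("  CAR1 phi = %.3f\n", x$phi))
  if (!is.na(x$sigma2)) cat(sprintf("  residual SD = %.4f\n", sqrt(x$sigma2)))
  invisible(x)
}

#' Glance at a growth-model fit
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return a one-row tibble with `model_kind`, `logLik`, `df`, `AIC`, `BIC`,
#'   `sigma`, `phi`, `n_obs`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, logLik = x$loglik, df = x$k,
                 AIC = x$aic, BIC = x$bic,
                 sigma = sqrt(x$sigma2), phi = x$phi, n_obs = x$n_obs)
}

#' Tidy the fixed effects of a growth-model fit
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return a tibble with `term` and `estimate`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  if (is.null(x$fixed_effects)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$fixed_effects),
                 estimate = unname(x$fixed_effects))
}
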