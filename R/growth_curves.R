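#' Exponential and power-law growth curves
#'
#' Closed-form solutions of the growth ODE `dM/dt = r * M^beta`. With
#' `beta = 1` growth is exponential, `M(t) = M0 * exp(r * t)`; with
#' `beta < 1` the relative growth rate declines with size and
#' `M(t) = (M0^(1 - beta) + r * t * (1 - beta))^(1 / (1 - beta))`.
#' `powerlaw_size()` dispatches to the exponential branch when
#' `|1 - beta| < 1e-8` (the analytic limit).
#'
#' @param t time(s) since treatment start, days; vectorized.
#' @param M0 initial size at `t = 0`, area units (> 0).
#' @param r growth rate (area-units^(1 - beta) per day; per day when
#'   `beta = 1`).
#' @param beta unitless scaling exponent in `(0, 1]`.
#' @return size(s) at `t`, same length as `t`.
#' @export
#' @examples
#' exponential_size(7, M0 = 10, r = 0.5)      # 10 * exp(3.5)
#' powerlaw_size(7, M0 = 10, r = 0.5, beta = 0.9)
exponential_size <- function(t, M0, r) {
  if (any(M0 <= 0)) rlang::abort("M0 must be positive")
  M0 * exp(r * t)
}

#' @rdname exponential_size
#' @export
powerlaw_size <- function(t, M0, r, beta) {
  if (any(M0 <= 0)) rlang::abort("M0 must be positive")
  if (abs(1 - beta) < 1e-8) return(exponential_size(t, M0, r))
  om <- 1 - beta
  base <- M0^om + r * t * om
  if (any(base <= 0)) {
    bad <- t[base <= 0]
    rlang::abort(sprintf(
      "power-law curve undefined (non-positive base) at t = %s",
      paste(signif(utils::head(bad, 3), 4), collapse = ", ")))
  }
  base^(1 / om)
}

#' Self-start parameter estimates for a single growth series
#'
#' Cheap deterministic initial estimates used to start the nonlinear
#' mixed-model fits. For the exponential model, OLS of `log(area)` on time
#' gives `(log M0, r)`. For the power-law model a 1-D grid profile over
#' `beta` is used: for each candidate `beta` the transformed model
#' `area^(1 - beta) = M0^(1 - beta) + r * (1 - beta) * t` is linear in `t`
#' and fitted by OLS; the triple minimizing the sum of squared errors on the
#' original area scale is returned.
#'
#' @param times,areas numeric vectors (same length >= 2), treatment days and
#'   rosette areas.
#' @param model_kind `"powerlaw"` or `"exponential"`.
#' @param beta_grid candidate scaling exponents profiled over.
#' @return one-row tibble with `M0`, `r`, `beta` (`beta = 1` for the
#'   exponential model).
#' @export
growth_selfstart <- function(times, areas,
                             model_kind = c("powerlaw", "exponential"),
                             beta_grid = seq(0.05, 0.99, by = 0.02)) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(times) == length(areas), length(times) >= 2)
  if (any(areas <= 0)) rlang::abort("areas must be positive")
  if (stats::sd(areas) == 0) {
    rlang::warn("constant series: returning r = 0")
    return(tibble::tibble(M0 = mean(areas), r = 0,
                          beta = if (model_kind == "powerlaw") 1 else 1))
  }
  if (model_kind == "exponential") {
    cf <- stats::lm.fit(cbind(1, times), log(areas))$coefficients
    return(tibble::tibble(M0 = exp(cf[[1]]), r = cf[[2]], beta = 1))
  }
  best <- NULL
  best_sse <- Inf
  for (b in beta_grid) {
    om <- 1 - b
    cf <- stats::lm.fit(cbind(1, times), areas^om)$coefficients
    M0 <- max(cf[[1]], 1e-6)^(1 / om)
    r <- cf[[2]] / om
    pred <- try(powerlaw_size(times, M0, r, b), silent = TRUE)
    if (inherits(pred, "try-error")) next
    sse <- sum((pred - areas)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(M0, r, b)
    }
  }
  if (is.null(best)) rlang::abort("self-start failed for all beta candidates")
  tibble::tibble(M0 = best[1], r = best[2], beta = best[3])
}

#' Remove negative-growth observations (running-maximum filter)
#'
#' Imaging artifacts occasionally shrink the measured rosette area;
#' observations with smaller area than an earlier (kept) time point are
#' discarded. Within each plant, an observation is kept iff its area is at
#' least the maximum of all previously kept areas (ties kept). Plants
#' retaining fewer than `min_points` observations are flagged unusable. The
#' filter is idempotent and its output is non-decreasing within plant.
#'
#' @param data long phenotype table with at least `plant_id`, `time_dap`
#'   (or `time`) and `area` columns.
#' @param min_points minimum surviving observations for a plant to be usable.
#' @return the filtered tibble, with a logical `usable` column; rows are
#'   ordered by plant and time.
#' @export
#' @examples
#' d <- tibble::tibble(plant_id = "p1", time_dap = 1:4, area = c(5, 6, 4, 7))
#' clean_series(d)$area   # 5 6 7
clean_series <- function(data, min_points = 4) {
  if (nrow(data) == 0) rlang::abort("empty phenotype table")
  require_columns(data, c("plant_id", "area"), "phenotype table")
  tcol <- if ("time_dap" %in% names(data)) "time_dap" else "time"
  require_columns(data, tcol, "phenotype table")
  data |>
    dplyr::arrange(.data$plant_id, .data[[tcol]]) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::filter(.data$area >= dplyr::lag(cummax(as.numeric(.data$area)),
                                           default = -Inf)) |>
    dplyr::mutate(usable = dplyr::n() >= min_points) |>
    dplyr::ungroup()
}

#' Temperature response of the growth rate
#'
#' The contrast of an accession's growth rate between the warm (16 C) and
#' cold (6 C) treatments, defined as the plain difference `r16 - r6`. The
#' slope from a regression on an ordered two-level temperature factor
#' (polynomial contrast) equals this difference divided by `sqrt(2)` - a
#' monotone rescaling that leaves signs, ranks and all downstream
#' correlations unchanged.
#'
#' @param r6,r16 growth rates at 6 C and 16 C (vectorized).
#' @return `r16 - r6`.
#' @export
#' @examples
#' temperature_response(r6 = 0.1, r16 = 0.4)  # 0.3
temperature_response <- function(r6, r16) {
  stopifnot(is.numeric(r6), is.numeric(r16))
  if (any(!is.finite(r6)) || any(!is.finite(r16))) {
    rlang::abort("growth rates must be finite")
  }
  r16 - r6
}
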