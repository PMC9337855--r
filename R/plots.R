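# figure-ready ggplot2 output for scan and differentiation results

#' Manhattan plot of an association scan
#'
#' @param object a `gwas_scan` from [lmm_scan()].
#' @param alpha family-wise error rate for the Bonferroni line.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gwas_scan
#' @export
autoplot.gwas_scan <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  if (!all(c("chr", "pos") %in% names(d)) || all(is.na(d$chr))) {
    d$chr <- 1L
    d$pos <- seq_len(nrow(d))
  }
  d <- dplyr::arrange(d, .data$chr, .data$pos)
  offsets <- d |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  d <- dplyr::left_join(d, offsets, by = "chr") |>
    dplyr::mutate(x = .data$pos + .data$offset,
                  chr_parity = factor(.data$chr %% 2))
  thr <- bonferroni_threshold(attr(object, "n_tests") %||% nrow(d), alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                  colour = .data$chr_parity)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of scan p-values
#'
#' @param p p-values, or a tibble from [qq_data()].
#' @param band pointwise null band coverage.
#' @return a ggplot object.
#' @export
plot_qq <- function(p, band = 0.95) {
  d <- if (is.data.frame(p)) p else qq_data(p, band)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red",
                        size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Trait-vs-PC plot with the neutral envelope
#'
#' Mean-centered trait values against the scores on a kinship PC, with the
#' observed through-origin regression line and the neutral band within which
#' the relationship is expected to fall under drift alone.
#'
#' @param object a `qpc_result`.
#' @param pc which tested PC to display.
#' @param confidence envelope coverage.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qpc_result
#' @export
autoplot.qpc_result <- function(object, pc = 1, confidence = 0.90, ...) {
  env <- neutral_envelope(object, pc = pc, confidence = confidence)
  pts <- tibble::tibble(score = object$vectors[, pc], z = object$z_tilde)
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = env,
                         ggplot2::aes(x = .data$pc_score, ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(data = env,
                       ggplot2::aes(x = .data$pc_score, y = .data$fitted),
                       colour = "blue") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$score, y = .data$z),
                        size = 1) +
    ggplot2::labs(x = sprintf("PC%d score", pc),
                  y = sprintf("%s (centered)", object$trait)) +
    ggplot2::theme_minimal()
}
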