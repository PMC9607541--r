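#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot sv_fit
#' @export
autoplot.sv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$Ksv,
                         linetype = 2) +
    ggplot2::labs(
      x = "[Q] (mol/L)", y = expression(F[0] / F),
      title = sprintf("Stern-Volmer plot (%g K)", object$temperature_K),
      subtitle = sprintf("Ksv = %.3g L/mol, R² = %.3f",
                         object$Ksv, object$r_squared)
    )
}

#' @method autoplot dlog_fit
#' @export
autoplot.dlog_fit <- function(object, ...) {
  b <- stats::coef(object$lm)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$log_conc, .data$log_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = b[1], slope = b[2], linetype = 2) +
    ggplot2::labs(
      x = expression(log[10] * "[Q]"),
      y = expression(log[10] * ((F[0] - F) / F)),
      title = sprintf("Double-logarithmic binding plot (%g K)",
                      object$temperature_K),
      subtitle = sprintf("Ka = %.3g L/mol, n = %.2f", object$Ka, object$n)
    )
}

#' @method autoplot vant_hoff
#' @export
autoplot.vant_hoff <- function(object, ...) {
  dat <- object$table |>
    dplyr::mutate(inv_T = 1 / .data$temperature_K, ln_ka = log(.data$Ka))
  b <- stats::coef(object$lm)
  ggplot2::ggplot(dat, ggplot2::aes(.data$inv_T, .data$ln_ka)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = b[1], slope = b[2], linetype = 2) +
    ggplot2::labs(
      x = "1 / T (1/K)", y = expression(ln ~ K[a]),
      title = "van't Hoff plot",
      subtitle = sprintf("dH = %.1f kJ/mol, dS = %.1f J/(mol K)",
                         object$dH, object$dS)
    )
}

#' @method autoplot shift_result
#' @export
autoplot.shift_result <- function(object, ...) {
  ggplot2::ggplot(object$peaks,
                  ggplot2::aes(.data$conc, .data$peak_wavelength)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "[Q] (mol/L)", y = "band maximum (nm)",
      title = sprintf("Synchronous band shift (delta-lambda = %g nm, %s)",
                      object$delta_lambda, object$residue_class),
      subtitle = sprintf("shift = %+.2f nm (%s)", object$shift_nm,
                         object$direction)
    )
}

#' @method autoplot site_assignment
#' @export
autoplot.site_assignment <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(stats::reorder(.data$probe_name,
                                              .data$ratio_percent),
                               .data$ratio_percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$ratio_threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "100 × K'a / Ka (%)",
                  title = "Site-marker competition",
                  subtitle = object$status)
}

#' Plot a titration series
#'
#' @param series A [titration_series()].
#' @return A ggplot of intensity versus concentration.
#' @export
plot_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  ggplot2::ggplot(series, ggplot2::aes(.data$conc, .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "[Q] (mol/L)", y = "fluorescence intensity (a.u.)",
                  title = sprintf("Titration at %g K",
                                  series_temperature(series)))
}
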