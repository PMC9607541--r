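#' Fit the Stern-Volmer quenching law
#'
#' Ordinary least squares of F0/F on quencher concentration with an
#' intercept: `F0/F = 1 + Ksv [Q]`. The slope is the Stern-Volmer constant
#' Ksv (L/mol); dividing by the unquenched fluorophore lifetime tau0 gives
#' the bimolecular quenching rate constant Kq = Ksv / tau0 (L/(mol s)).
#' The fitted intercept should be close to 1; a value outside [0.9, 1.1]
#' triggers a warning (possible baseline or inner-filter artifact).
#'
#' @param series A [titration_series()] with >= 3 nonzero concentrations.
#' @param tau0 Unquenched fluorophore lifetime in seconds; ~1e-8 s for
#'   protein intrinsic fluorescence. Default `1e-8`.
#'
#' @return An object of class `sv_fit`: a list with `Ksv`, `Ksv_se`, `Kq`,
#'   `tau0`, `intercept`, `r_squared`, `temperature_K`, `n_points`, and
#'   `no_quenching` (TRUE when the fitted slope is negative). Supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @examples
#' ts <- simulate_titration(sim_config("stern_volmer", noise_cv = 0))
#' fit_stern_volmer(ts)
#' @export
fit_stern_volmer <- function(series, tau0 = 1e-8) {
  stopifnot(inherits(series, "titration_series"), tau0 > 0)
  if (sum(series$conc > 0) < 3L) {
    stop("need ≥3 nonzero concentrations for fitting", call. = FALSE)
  }
  f0 <- f_zero(series)
  dat <- tibble::tibble(conc = series$conc, ratio = f0 / series$intensity)
  fit <- stats::lm(ratio ~ conc, data = dat)
  sm <- suppressWarnings(summary(fit))  # noiseless data trips the perfect-fit warning
  co <- sm$coefficients
  ksv <- unname(co["conc", "Estimate"])
  intercept <- unname(co["(Intercept)", "Estimate"])
  no_quenching <- ksv <= 0
  if (no_quenching) {
    warning("no quenching detected: fitted Stern-Volmer slope is not positive",
            call. = FALSE)
  }
  if (intercept < 0.9 || intercept > 1.1) {
    warning(sprintf("fitted Stern-Volmer intercept %.3f outside [0.9, 1.1]",
                    intercept), call. = FALSE)
  }
  ksv_se <- unname(co["conc", "Std. Error"])
  structure(list(
    Ksv = ksv, Ksv_se = ksv_se, Kq = ksv / tau0, tau0 = tau0,
    intercept = intercept,
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    temperature_K = series_temperature(series),
    n_points = nrow(dat), no_quenching = no_quenching,
    data = dat, lm = fit
  ), class = "sv_fit")
}

#' Fit the double-logarithmic binding model
#'
#' Ordinary least squares of `log10((F0 - F) / F)` on `log10([Q])`:
#' the intercept gives the association constant (Ka = 10^intercept, L/mol)
#' and the slope the binding-site number n. Points with F >= F0 carry no
#' binding signal on the log scale and are excluded (and counted).
#' The standard error of Ka follows from the intercept SE by the delta
#' method: `se(Ka) = ln(10) * Ka * se(intercept)`.
#'
#' @param series A [titration_series()].
#'
#' @return An object of class `dlog_fit`: a list with `Ka`, `Ka_se`, `n`,
#'   `n_se`, `r_squared`, `temperature_K`, `n_points`, `n_excluded`.
#'   Supports [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @examples
#' ts <- simulate_titration(sim_config("hill_binding", noise_cv = 0))
#' fit_double_log(ts)
#' @export
fit_double_log <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f0 <- f_zero(series)
  nz <- series$conc > 0
  usable <- nz & series$intensity < f0
  excluded <- which(nz & !usable)
  if (sum(usable) < 3L) {
    stop("need ≥3 usable points (F < F0, [Q] > 0); excluded rows: ",
         if (length(excluded)) paste(excluded, collapse = ", ") else "none",
         call. = FALSE)
  }
  dat <- tibble::tibble(
    log_conc = log10(series$conc[usable]),
    log_ratio = log10((f0 - series$intensity[usable]) / series$intensity[usable])
  )
  fit <- stats::lm(log_ratio ~ log_conc, data = dat)
  sm <- suppressWarnings(summary(fit))  # noiseless data trips the perfect-fit warning
  co <- sm$coefficients
  intercept <- unname(co["(Intercept)", "Estimate"])
  ka <- 10^intercept
  structure(list(
    Ka = ka,
    Ka_se = log(10) * ka * unname(co["(Intercept)", "Std. Error"]),
    n = unname(co["log_conc", "Estimate"]),
    n_se = unname(co["log_conc", "Std. Error"]),
    r_squared = sm$r.squared,
    temperature_K = series_temperature(series),
    n_points = nrow(dat), n_excluded = length(excluded),
    data = dat, lm = fit
  ), class = "dlog_fit")
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Combines the two textbook diagnostics: the temperature trend of Ksv
#' (static quenching weakens with temperature as the ground-state complex
#' dissociates; collisional quenching strengthens) and the magnitude of Kq
#' relative to the diffusion-collision ceiling (~2e10 L/(mol s)).
#' `static` requires Ksv strictly decreasing with temperature AND all Kq
#' above the ceiling; `dynamic` requires Ksv strictly increasing AND all Kq
#' at or below it; anything else is `indeterminate`, with both criteria
#' reported. With a single temperature only the Kq criterion applies and
#' the result is flagged.
#'
#' @param fits A list of `sv_fit` objects (one per temperature), or a data
#'   frame with columns `temperature_K`, `Ksv`, `Kq`.
#' @param kq_ceiling Maximum dynamic (diffusion-limited) collisional
#'   quenching rate constant, L/(mol s). Default `2e10`.
#'
#' @return A list of class `mechanism_call` with `mechanism` (one of
#'   `"static"`, `"dynamic"`, `"indeterminate"`), `ksv_trend`,
#'   `kq_all_above_ceiling`, `kq_all_below_ceiling`, the per-temperature
#'   table, and `single_temperature` flag.
#' @examples
#' tbl <- tibble::tibble(temperature_K = c(298, 308),
#'                       Ksv = c(1.21e5, 0.41e5), Kq = c(1.21e13, 0.41e13))
#' classify_quenching_mechanism(tbl)
#' @export
classify_quenching_mechanism <- function(fits, kq_ceiling = 2e10) {
  tab <- if (is.data.frame(fits)) {
    tibble::as_tibble(fits)
  } else {
    purrr::map_dfr(fits, function(f) {
      tibble::tibble(temperature_K = f$temperature_K, Ksv = f$Ksv, Kq = f$Kq)
    })
  }
  stopifnot(all(c("temperature_K", "Ksv", "Kq") %in% names(tab)))
  tab <- dplyr::arrange(tab, .data$temperature_K)
  above <- all(tab$Kq > kq_ceiling)
  below <- all(tab$Kq <= kq_ceiling)
  single <- nrow(tab) < 2L
  if (single) {
    warning("temperature trend unavailable: single temperature; ",
            "classification from Kq criterion only", call. = FALSE)
    mech <- if (above) "static" else if (below) "dynamic" else "indeterminate"
    trend <- NA_character_
  } else {
    dK <- diff(tab$Ksv)
    trend <- if (all(dK < 0)) "decreasing" else if (all(dK > 0)) "increasing"
      else "non-monotone"
    mech <- if (trend == "decreasing" && above) "static"
      else if (trend == "increasing" && below) "dynamic"
      else "indeterminate"
  }
  structure(list(mechanism = mech, ksv_trend = trend,
                 kq_all_above_ceiling = above, kq_all_below_ceiling = below,
                 kq_ceiling = kq_ceiling, table = tab,
                 single_temperature = single),
            class = "mechanism_call")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer fit (", x$temperature_K, " K, ", x$n_points, " points)\n",
      sep = "")
  cat(sprintf("  Ksv = %.4g +/- %.2g L/mol\n", x$Ksv, x$Ksv_se))
  cat(sprintf("  Kq  = %.4g L/(mol s)   [tau0 = %g s]\n", x$Kq, x$tau0))
  cat(sprintf("  intercept = %.4f, R^2 = %.4f\n", x$intercept, x$r_squared))
  if (x$no_quenching) cat("  flag: no quenching detected\n")
  invisible(x)
}

#' @export
print.dlog_fit <- function(x, ...) {
  cat("Double-logarithmic binding fit (", x$temperature_K, " K, ",
      x$n_points, " points", sep = "")
  if (x$n_excluded > 0) cat(", ", x$n_excluded, " excluded", sep = "")
  cat(")\n")
  cat(sprintf("  Ka = %.4g +/- %.2g L/mol\n", x$Ka, x$Ka_se))
  cat(sprintf("  n  = %.3f +/- %.3f\n", x$n, x$n_se))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Quenching mechanism:", x$mechanism, "\n")
  cat("  Ksv trend with temperature:", x$ksv_trend, "\n")
  cat(sprintf("  Kq vs ceiling %.3g: all above = %s, all at/below = %s\n",
              x$kq_ceiling, x$kq_all_above_ceiling, x$kq_all_below_ceiling))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sv_fit
#' @export
tidy.sv_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Ksv", "Kq", "intercept"),
    estimate = c(x$Ksv, x$Kq, x$intercept),
    std.error = c(x$Ksv_se, x$Ksv_se / x$tau0, x$intercept_se)
  )
}

#' @method glance sv_fit
#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, temperature_K = x$temperature_K,
                 nobs = x$n_points, no_quenching = x$no_quenching)
}

#' @method tidy dlog_fit
#' @export
tidy.dlog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Ka", "n"),
    estimate = c(x$Ka, x$n),
    std.error = c(x$Ka_se, x$n_se)
  )
}

#' @method glance dlog_fit
#' @export
glance.dlog_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, temperature_K = x$temperature_K,
                 nobs = x$n_points, n_excluded = x$n_excluded)
}
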