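#' Molar gas constant, J/(mol K)
#' @export
GAS_CONSTANT <- 8.314

#' van't Hoff estimation of binding enthalpy and entropy
#'
#' Fits `ln Ka = -dH/(R T) + dS/R` to association constants measured at two
#' or more temperatures. With exactly two points the solve is exact; with
#' three or more it is ordinary least squares of ln Ka on 1/T. The enthalpy
#' is `-slope * R` and the entropy `intercept * R`. Gibbs energy is then
#' reported per temperature by two routes: `dG = dH - T dS` (from the fitted
#' pair) and `dG = -R T ln Ka` (directly from each Ka); the two agree
#' exactly at the input temperatures of a two-point solve.
#'
#' @param ka_by_temperature A data frame with columns `temperature_K` and
#'   `Ka` (L/mol), or a named numeric vector of Ka values whose names are
#'   temperatures in kelvin.
#'
#' @return An object of class `vant_hoff`: a list with `dH` (kJ/mol),
#'   `dH_se`, `dS` (J/(mol K)), `dS_se`, `r_squared`, a per-temperature
#'   tibble `table` (`temperature_K`, `Ka`, `dG_from_pair`, `dG_from_ka`,
#'   both kJ/mol, and `spontaneous`), and `forces`, the binding-force
#'   classification of the fitted signs. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' fit_vant_hoff(c(`298` = 3.79e4, `308` = 1.93e4))
#' @export
fit_vant_hoff <- function(ka_by_temperature) {
  tab <- if (is.data.frame(ka_by_temperature)) {
    tibble::as_tibble(ka_by_temperature)
  } else {
    tibble::tibble(temperature_K = as.numeric(names(ka_by_temperature)),
                   Ka = as.numeric(ka_by_temperature))
  }
  stopifnot(all(c("temperature_K", "Ka") %in% names(tab)))
  if (any(!is.finite(tab$Ka)) || any(tab$Ka <= 0)) {
    stop("all Ka must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(tab$temperature_K)) {
    stop("temperatures must be distinct", call. = FALSE)
  }
  if (nrow(tab) < 2L) stop("need >= 2 temperatures", call. = FALSE)
  tab <- dplyr::arrange(tab, .data$temperature_K)

  dat <- tibble::tibble(inv_T = 1 / tab$temperature_K, ln_ka = log(tab$Ka))
  fit <- stats::lm(ln_ka ~ inv_T, data = dat)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- unname(co["inv_T", "Estimate"])
  intercept <- unname(co["(Intercept)", "Estimate"])
  two_point <- nrow(tab) == 2L
  dH <- -slope * GAS_CONSTANT / 1000   # kJ/mol
  dS <- intercept * GAS_CONSTANT       # J/(mol K)
  dH_se <- if (two_point) NA_real_ else
    unname(co["inv_T", "Std. Error"]) * GAS_CONSTANT / 1000
  dS_se <- if (two_point) NA_real_ else
    unname(co["(Intercept)", "Std. Error"]) * GAS_CONSTANT

  table <- tab |>
    dplyr::mutate(
      dG_from_pair = dH - .data$temperature_K * dS / 1000,
      dG_from_ka = -GAS_CONSTANT * .data$temperature_K * log(.data$Ka) / 1000,
      spontaneous = .data$dG_from_pair < 0
    )
  structure(list(
    dH = dH, dH_se = dH_se, dS = dS, dS_se = dS_se,
    r_squared = if (two_point) 1 else sm$r.squared,
    two_point = two_point, table = table,
    forces = classify_binding_forces(dH, dS),
    gas_constant = GAS_CONSTANT, lm = fit
  ), class = "vant_hoff")
}

#' Gibbs free energy of binding
#'
#' Computes dG (kJ/mol) at each requested temperature by whichever routes
#' the inputs allow: `-R T ln Ka` when `Ka` is given, and `dH - T dS` when
#' the enthalpy/entropy pair is given. When both routes are available their
#' values are both reported and a discrepancy above 0.5 kJ/mol triggers a
#' warning — a useful consistency check between a directly fitted Ka and a
#' van't Hoff extrapolation.
#'
#' @param temperature_K Temperature(s), K, > 0.
#' @param Ka Association constant(s), L/mol, > 0 (recycled against
#'   `temperature_K`). Optional.
#' @param dH Enthalpy, kJ/mol. Optional (with `dS`).
#' @param dS Entropy, J/(mol K). Optional (with `dH`).
#' @return A tibble with columns `temperature_K`, `dG_from_ka` and/or
#'   `dG_from_enthalpy` (kJ/mol), `dG` (the Ka route when available,
#'   otherwise the enthalpy route), and `spontaneous`.
#' @examples
#' compute_gibbs(298, Ka = 3.79e4)                 # -26.12 kJ/mol
#' compute_gibbs(308, dH = -51.53, dS = -87.91)    # -24.45 kJ/mol
#' @export
compute_gibbs <- function(temperature_K, Ka = NULL, dH = NULL, dS = NULL) {
  stopifnot(all(temperature_K > 0))
  have_ka <- !is.null(Ka)
  have_pair <- !is.null(dH) && !is.null(dS)
  if (!have_ka && !have_pair) {
    stop("supply `Ka`, or both `dH` and `dS`", call. = FALSE)
  }
  out <- tibble::tibble(temperature_K = as.numeric(temperature_K))
  if (have_ka) {
    stopifnot(all(Ka > 0))
    out$dG_from_ka <- -GAS_CONSTANT * out$temperature_K * log(Ka) / 1000
  }
  if (have_pair) {
    out$dG_from_enthalpy <- dH - out$temperature_K * dS / 1000
  }
  if (have_ka && have_pair) {
    gap <- abs(out$dG_from_ka - out$dG_from_enthalpy)
    if (any(gap > 0.5)) {
      warning(sprintf(
        "dG routes disagree by up to %.2f kJ/mol (-RT ln Ka vs dH - T dS)",
        max(gap)), call. = FALSE)
    }
  }
  out$dG <- if (have_ka) out$dG_from_ka else out$dG_from_enthalpy
  out$spontaneous <- out$dG < 0
  out
}

#' Classify binding forces from thermodynamic signs
#'
#' The standard sign rules for the dominant non-covalent interaction:
#' dH > 0 with dS > 0 indicates hydrophobic association; dH < 0 with
#' dS < 0 indicates van der Waals contacts and hydrogen bonding; dH < 0
#' with dS > 0 indicates electrostatic interactions. A zero in either sign
#' is a boundary case: the force set is empty and flagged.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, J/(mol K).
#' @return A list of class `force_call` with `forces` (character vector,
#'   possibly empty), `boundary` (logical), and the input signs.
#' @examples
#' classify_binding_forces(-51.53, -85.25)
#' @export
classify_binding_forces <- function(dH, dS) {
  stopifnot(length(dH) == 1L, length(dS) == 1L, is.finite(dH), is.finite(dS))
  boundary <- dH == 0 || dS == 0
  forces <- if (boundary) {
    character(0)
  } else if (dH > 0 && dS > 0) {
    "hydrophobic"
  } else if (dH < 0 && dS < 0) {
    c("van der Waals", "hydrogen bond")
  } else if (dH < 0 && dS > 0) {
    "electrostatic"
  } else {
    # dH > 0, dS < 0: no standard assignment (doubly unfavourable)
    character(0)
  }
  structure(list(forces = forces, boundary = boundary,
                 sign_dH = sign(dH), sign_dS = sign(dS)),
            class = "force_call")
}

#' @export
print.force_call <- function(x, ...) {
  if (length(x$forces)) {
    cat("Binding forces:", paste(x$forces, collapse = " + "), "\n")
  } else if (x$boundary) {
    cat("Binding forces: boundary case (zero dH or dS); none assigned\n")
  } else {
    cat("Binding forces: none assigned (dH > 0, dS < 0)\n")
  }
  invisible(x)
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("van't Hoff fit (", nrow(x$table), " temperatures",
      if (x$two_point) ", exact two-point solve" else "", ")\n", sep = "")
  cat(sprintf("  dH = %.2f kJ/mol%s\n", x$dH,
              if (is.na(x$dH_se)) "" else sprintf(" +/- %.2f", x$dH_se)))
  cat(sprintf("  dS = %.2f J/(mol K)%s\n", x$dS,
              if (is.na(x$dS_se)) "" else sprintf(" +/- %.2f", x$dS_se)))
  print(x$forces)
  print(x$table)
  invisible(x)
}

#' @method tidy vant_hoff
#' @export
tidy.vant_hoff <- function(x, ...) {
  tibble::tibble(term = c("dH", "dS"),
                 estimate = c(x$dH, x$dS),
                 std.error = c(x$dH_se, x$dS_se),
                 unit = c("kJ/mol", "J/(mol K)"))
}

#' @method glance vant_hoff
#' @export
glance.vant_hoff <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = nrow(x$table),
                 two_point = x$two_point,
                 forces = paste(x$forces$forces, collapse = " + "))
}
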