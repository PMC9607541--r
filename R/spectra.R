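#' Construct an emission spectrum
#'
#' A tidy container for one fluorescence emission scan: intensity as a
#' function of emission wavelength at a fixed excitation wavelength.
#'
#' @param wavelength Numeric vector of emission wavelengths (nm), strictly
#'   increasing.
#' @param intensity Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelength`, finite and non-negative.
#' @param excitation_nm Excitation wavelength (nm).
#' @param temperature_K Sample temperature (K).
#' @param label Free-text label for the scan.
#'
#' @return A tibble of class `emission_spectrum` with columns `wavelength`
#'   and `intensity`; excitation, temperature and label are stored as
#'   attributes.
#' @examples
#' sp <- emission_spectrum(300:420, dnorm(300:420, 340, 25) * 1e4)
#' extract_peak_intensity(sp)
#' @export
emission_spectrum <- function(wavelength, intensity, excitation_nm = 280,
                              temperature_K = 298, label = "") {
  stopifnot(is.numeric(wavelength), is.numeric(intensity))
  if (length(wavelength) != length(intensity)) {
    stop("`wavelength` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("`intensity` must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(wavelength = as.numeric(wavelength),
                        intensity = as.numeric(intensity))
  attr(out, "excitation_nm") <- excitation_nm
  attr(out, "temperature_K") <- temperature_K
  attr(out, "label") <- label
  class(out) <- c("emission_spectrum", class(out))
  out
}

#' Construct a titration series
#'
#' Peak fluorescence intensity of the protein versus quencher (ligand)
#' concentration at a single temperature. The zero-concentration row defines
#' the unquenched intensity F0; it is required and must come first.
#'
#' @param conc Quencher concentrations in mol/L, non-negative, strictly
#'   increasing, first element 0.
#' @param intensity Peak fluorescence intensities (arbitrary units), all
#'   positive, same length as `conc`.
#' @param temperature_K Temperature (K).
#' @param protein_conc Protein concentration (mol/L).
#' @param readout_nm Emission wavelength at which intensity was read (nm).
#'
#' @return A tibble of class `titration_series` with columns `conc` and
#'   `intensity`; metadata stored as attributes.
#' @examples
#' ts <- titration_series(c(0, 2, 4, 6, 8, 10) * 1e-6,
#'                        c(1000, 810, 680, 590, 520, 460))
#' f_zero(ts)
#' @export
titration_series <- function(conc, intensity, temperature_K = 298,
                             protein_conc = 2e-6, readout_nm = 340) {
  stopifnot(is.numeric(conc), is.numeric(intensity))
  if (length(conc) != length(intensity)) {
    stop("`conc` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (conc[1] != 0) {
    stop("a zero-concentration row (defining F0) is required and must come first",
         call. = FALSE)
  }
  if (any(diff(conc) <= 0)) {
    dup <- which(diff(conc) <= 0) + 1L
    stop("concentrations must be strictly increasing; offending rows: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop("all intensities must be finite and positive", call. = FALSE)
  }
  out <- tibble::tibble(conc = as.numeric(conc), intensity = as.numeric(intensity))
  attr(out, "temperature_K") <- temperature_K
  attr(out, "protein_conc") <- protein_conc
  attr(out, "readout_nm") <- readout_nm
  class(out) <- c("titration_series", class(out))
  out
}

#' Unquenched intensity F0 of a titration series
#'
#' @param series A [titration_series()].
#' @return The intensity at zero quencher concentration.
#' @export
f_zero <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  series$intensity[series$conc == 0][1]
}

#' Temperature of a series or result object
#'
#' @param x An object carrying a `temperature_K` attribute.
#' @return Temperature in kelvin.
#' @export
series_temperature <- function(x) {
  tK <- attr(x, "temperature_K")
  if (is.null(tK)) stop("object carries no temperature", call. = FALSE)
  tK
}

#' Construct a synchronous fluorescence series
#'
#' Synchronous scans (fixed excitation-emission offset delta-lambda) recorded
#' at each quencher concentration, stored in long form. An offset of 15 nm
#' isolates tyrosine fluorescence; 60 nm isolates tryptophan.
#'
#' @param data A data frame with columns `conc` (mol/L), `wavelength` (nm)
#'   and `intensity`, one spectrum per concentration.
#' @param delta_lambda Excitation-emission offset in nm (conventionally 15
#'   or 60; other values allowed with a warning).
#'
#' @return A tibble of class `synchronous_series`.
#' @export
synchronous_series <- function(data, delta_lambda) {
  stopifnot(is.data.frame(data),
            all(c("conc", "wavelength", "intensity") %in% names(data)))
  if (!delta_lambda %in% c(15, 60)) {
    warning("delta_lambda is conventionally 15 (Tyr) or 60 (Trp) nm; got ",
            delta_lambda, call. = FALSE)
  }
  ok <- data |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(mono = all(diff(.data$wavelength) > 0), .groups = "drop")
  if (!all(ok$mono)) {
    stop("wavelengths must be strictly increasing within each concentration",
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "delta_lambda") <- delta_lambda
  attr(out, "residue_class") <- if (delta_lambda == 15) "Tyr"
    else if (delta_lambda == 60) "Trp" else NA_character_
  class(out) <- c("synchronous_series", class(out))
  out
}

#' Locate a band maximum by quadratic-vertex interpolation
#'
#' Finds the local maximum of the spectrum nearest `nominal_peak`, then fits
#' a quadratic to all points within `window` nm of that maximum and returns
#' the vertex. Sub-sample interpolation makes peak positions robust to the
#' wavelength sampling step.
#'
#' @param spectrum An [emission_spectrum()], or any data frame with
#'   `wavelength` and `intensity` columns.
#' @param nominal_peak Expected band center (nm); protein intrinsic emission
#'   peaks near 340 nm. Default 340.
#' @param window Half-width (nm) of the fitting window around the located
#'   maximum. Default 15.
#'
#' @return A one-row tibble with columns `peak_wavelength`, `peak_intensity`
#'   and `reliable` (FALSE when the maximum sits on the window boundary, in
#'   which case the boundary value is returned with a warning).
#' @examples
#' sp <- emission_spectrum(300:420, 1000 * exp(-((300:420) - 346)^2 / (2 * 25^2)))
#' extract_peak_intensity(sp, nominal_peak = 340, window = 20)
#' @export
extract_peak_intensity <- function(spectrum, nominal_peak = 340, window = 15) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "intensity") %in% names(spectrum)))
  wl <- spectrum$wavelength
  y <- spectrum$intensity
  if (nominal_peak < min(wl) || nominal_peak > max(wl)) {
    stop("`nominal_peak` lies outside the spectral range", call. = FALSE)
  }
  # local maxima: strictly above both neighbours (plateaus take the first point)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max)
  if (length(cand) == 0L) cand <- which.max(y)
  i0 <- cand[which.min(abs(wl[cand] - nominal_peak))]

  at_boundary <- i0 %in% c(1L, n)
  sel <- abs(wl - wl[i0]) <= window
  if (sum(sel) < 5L) {
    stop("fewer than 5 samples within the fitting window", call. = FALSE)
  }
  if (at_boundary) {
    warning("band maximum lies on the spectral boundary; returning boundary value",
            call. = FALSE)
    return(tibble::tibble(peak_wavelength = wl[i0], peak_intensity = y[i0],
                          reliable = FALSE))
  }
  # quadratic in (wl - center) for conditioning
  x <- wl[sel] - wl[i0]
  fit <- stats::lm(y[sel] ~ x + I(x^2))
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) {
    # window not curvature-dominated; fall back to the sampled maximum
    return(tibble::tibble(peak_wavelength = wl[i0], peak_intensity = y[i0],
                          reliable = FALSE))
  }
  vx <- -b[2] / (2 * b[3])
  if (abs(vx) > window) {
    warning("quadratic vertex fell outside the window; returning sampled maximum",
            call. = FALSE)
    return(tibble::tibble(peak_wavelength = wl[i0], peak_intensity = y[i0],
                          reliable = FALSE))
  }
  tibble::tibble(
    peak_wavelength = unname(wl[i0] + vx),
    peak_intensity = unname(b[1] + b[2] * vx + b[3] * vx^2),
    reliable = TRUE
  )
}

#' Read intensity at (or near) a fixed wavelength
#'
#' The default downstream readout: intensity at a fixed emission wavelength
#' (340 nm for the intrinsic protein band), linearly interpolated between
#' the two bracketing samples.
#'
#' @param spectrum An [emission_spectrum()] or data frame with `wavelength`
#'   and `intensity`.
#' @param readout_nm Wavelength (nm) at which to read intensity.
#' @return A single intensity value.
#' @export
intensity_at <- function(spectrum, readout_nm = 340) {
  stopifnot(is.data.frame(spectrum))
  wl <- spectrum$wavelength
  if (readout_nm < min(wl) || readout_nm > max(wl)) {
    stop("`readout_nm` outside the spectral range", call. = FALSE)
  }
  stats::approx(wl, spectrum$intensity, xout = readout_nm)$y
}
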