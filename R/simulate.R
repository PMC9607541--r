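# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth configuration for the synthetic generators
#'
#' Bundles the true parameters from which synthetic titrations are built, so
#' every downstream fit has a recoverable truth. The defaults are the 298 K
#' parameters of the myricetin-class flavonoid / BSA system that the package
#' reproduces: Ksv = 1.21e5 L/mol, Ka = 3.79e4 L/mol, n = 1.5,
#' dH = -51.53 kJ/mol, dS = -85.25 J/(mol K), with 1% multiplicative noise.
#'
#' @param mode Quenching model: `"stern_volmer"` (F = F0 / (1 + Ksv [Q]),
#'   the linear Stern-Volmer law) or `"hill_binding"` ((F0 - F)/F =
#'   Ka [Q]^n, the double-logarithmic binding model).
#' @param F0_true Unquenched intensity (arbitrary units), > 0.
#' @param Ksv_true Stern-Volmer constant (L/mol), > 0.
#' @param Ka_true Association constant (L/mol), > 0.
#' @param n_true Binding-site number (dimensionless), > 0.
#' @param dH_true Binding enthalpy (kJ/mol).
#' @param dS_true Binding entropy (J/(mol K)).
#' @param noise_cv Relative SD of multiplicative Gaussian intensity noise
#'   (photon-counting-like); >= 0.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("stern_volmer", "hill_binding"),
                       F0_true = 1000, Ksv_true = 1.21e5, Ka_true = 3.79e4,
                       n_true = 1.5, dH_true = -51.53, dS_true = -85.25,
                       noise_cv = 0.01, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(F0_true > 0, Ksv_true > 0, Ka_true > 0, n_true > 0, noise_cv >= 0)
  structure(list(mode = mode, F0_true = F0_true, Ksv_true = Ksv_true,
                 Ka_true = Ka_true, n_true = n_true, dH_true = dH_true,
                 dS_true = dS_true, noise_cv = noise_cv, seed = seed),
            class = "sim_config")
}

#' Default titration concentration grid
#'
#' The 6-point quencher grid used throughout: 0, 2, 4, 6, 8, 10 uM in mol/L.
#'
#' @return Numeric vector of concentrations (mol/L).
#' @export
default_conc_grid <- function() c(0, 2, 4, 6, 8, 10) * 1e-6

apply_noise <- function(f, noise_cv) {
  if (noise_cv <= 0) return(f)
  out <- f * (1 + stats::rnorm(length(f), 0, noise_cv))
  pmax(out, .Machine$double.eps * f) # intensities stay positive
}

noiseless_titration <- function(config, conc) {
  switch(config$mode,
    stern_volmer = config$F0_true / (1 + config$Ksv_true * conc),
    hill_binding = ifelse(conc == 0, config$F0_true,
                          config$F0_true / (1 + config$Ka_true * conc^config$n_true))
  )
}

#' Simulate one fluorescence quenching titration
#'
#' Generates peak intensities on a concentration grid from the configured
#' quenching law, with seeded multiplicative Gaussian noise. At zero
#' quencher the intensity is exactly F0 in either mode.
#'
#' @param config A [sim_config()].
#' @param conc_grid Quencher concentrations (mol/L), must include 0.
#' @param temperature_K Temperature recorded on the series.
#' @return A [titration_series()].
#' @examples
#' cfg <- sim_config("stern_volmer", noise_cv = 0, seed = 1)
#' simulate_titration(cfg)
#' @export
simulate_titration <- function(config, conc_grid = default_conc_grid(),
                               temperature_K = 298) {
  stopifnot(inherits(config, "sim_config"))
  if (!any(conc_grid == 0)) stop("`conc_grid` must include 0", call. = FALSE)
  conc <- sort(unique(conc_grid))
  f <- noiseless_titration(config, conc)
  f <- with_seed(config$seed, apply_noise(f, config$noise_cv))
  titration_series(conc, f, temperature_K = temperature_K)
}

#' van't Hoff binding constant at a given temperature
#'
#' Ka(T) = exp(-dH / (R T) + dS / R) with R = 8.314 J/(mol K).
#'
#' @param dH Enthalpy (kJ/mol).
#' @param dS Entropy (J/(mol K)).
#' @param temperature_K Temperature (K).
#' @return Association constant (L/mol).
#' @examples
#' ka_from_thermo(-51.53, -85.25, 298) # ~ 3.8e4
#' @export
ka_from_thermo <- function(dH, dS, temperature_K) {
  exp(-dH * 1000 / (GAS_CONSTANT * temperature_K) + dS / GAS_CONSTANT)
}

#' Simulate titrations at several temperatures
#'
#' For each temperature, the association constant follows the van't Hoff
#' relation with the configured (dH, dS); a `hill_binding` titration is then
#' generated with that Ka(T). Each series gets a deterministic sub-seed
#' derived from `config$seed`.
#'
#' @param config A [sim_config()]; its `Ka_true` is overridden per
#'   temperature by the van't Hoff value.
#' @param temperatures Vector of >= 2 distinct temperatures (K).
#' @param conc_grid Quencher concentrations (mol/L), including 0.
#' @return A named list of [titration_series()], one per temperature.
#' @export
simulate_temperature_series <- function(config, temperatures = c(298, 308),
                                        conc_grid = default_conc_grid()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(temperatures) < 2L) stop("need >= 2 temperatures", call. = FALSE)
  if (anyDuplicated(temperatures)) {
    stop("temperatures must be distinct", call. = FALSE)
  }
  out <- purrr::imap(as.list(temperatures), function(tK, i) {
    ka <- ka_from_thermo(config$dH_true, config$dS_true, tK)
    cfg <- config
    cfg$mode <- "hill_binding"
    cfg$Ka_true <- ka
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    simulate_titration(cfg, conc_grid, temperature_K = tK)
  })
  names(out) <- as.character(temperatures)
  out
}

#' Simulate a synchronous fluorescence series
#'
#' A Gaussian band whose center drifts linearly with titrant concentration
#' (positive `shift_per_conc` = red shift) and whose amplitude is quenched
#' by the Stern-Volmer law with the configured Ksv.
#'
#' @param config A [sim_config()].
#' @param delta_lambda Excitation-emission offset (nm): 15 (Tyr) or 60 (Trp).
#' @param shift_per_conc Band-center drift in nm per mol/L of titrant;
#'   its sign sets the red/blue direction.
#' @param conc_grid Titrant concentrations (mol/L), including 0.
#' @param center0 Band center at zero titrant (nm).
#' @param band_sd Gaussian band SD (nm).
#' @param wl_step Wavelength sampling step (nm).
#' @return A [synchronous_series()].
#' @export
simulate_synchronous <- function(config, delta_lambda = 60,
                                 shift_per_conc = 2e5,
                                 conc_grid = default_conc_grid(),
                                 center0 = 285, band_sd = 15, wl_step = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!any(conc_grid == 0)) stop("`conc_grid` must include 0", call. = FALSE)
  conc <- sort(unique(conc_grid))
  wl <- seq(center0 - 4 * band_sd, center0 + 4 * band_sd +
              shift_per_conc * max(conc), by = wl_step)
  make_one <- function(q) {
    center <- center0 + shift_per_conc * q
    amp <- config$F0_true / (1 + config$Ksv_true * q)
    y <- amp * exp(-(wl - center)^2 / (2 * band_sd^2))
    y <- apply_noise(y, config$noise_cv)
    tibble::tibble(conc = q, wavelength = wl, intensity = y)
  }
  dat <- with_seed(config$seed, purrr::map_dfr(conc, make_one))
  synchronous_series(dat, delta_lambda)
}

#' Simulate a glycation assay panel
#'
#' Replicated control and treated readings with a known true inhibition
#' fraction per condition: control readings are `baseline * (1 + e)` and
#' treated readings `baseline * (1 - inhibition) * (1 + e)`, with
#' `e ~ N(0, noise_cv)`. Species labels and their excitation/emission pairs
#' come from the shipped wavelength registry.
#'
#' @param true_inhibition Named numeric vector of true inhibition fractions
#'   in `[0, 1]`, one per treated condition (names become condition labels);
#'   an unnamed single value is labelled `"treated"`.
#' @param species Species label(s) from [wavelength_registry()].
#' @param baseline Control-level reading (fluorescence or absorbance units).
#' @param replicates Replicates per condition/species, >= 1.
#' @param noise_cv Relative SD of multiplicative Gaussian noise.
#' @param seed Integer RNG seed.
#' @param readout `"fluorescence"` or `"absorbance"`.
#' @return An [assay_panel()] whose control condition is `"control"`.
#' @export
simulate_glycation_panel <- function(true_inhibition, species = "Total AGEs",
                                     baseline = 1000, replicates = 3,
                                     noise_cv = 0.05, seed = NULL,
                                     readout = c("fluorescence", "absorbance")) {
  readout <- match.arg(readout)
  stopifnot(all(true_inhibition >= 0), all(true_inhibition <= 1),
            replicates >= 1, baseline > 0, noise_cv >= 0)
  # validate species against the registry (errors on unknowns)
  purrr::walk(species, wavelength_lookup)
  if (is.null(names(true_inhibition))) {
    names(true_inhibition) <- if (length(true_inhibition) == 1L) "treated"
      else paste0("treated_", seq_along(true_inhibition))
  }
  grid <- tidyr::expand_grid(
    condition = c("control", names(true_inhibition)),
    species = species,
    replicate = seq_len(replicates)
  )
  vals <- with_seed(seed, {
    mu <- ifelse(grid$condition == "control", baseline,
                 baseline * (1 - true_inhibition[grid$condition]))
    apply_noise(mu, noise_cv)
  })
  assay_panel(dplyr::mutate(grid, value = unname(vals)),
              control_condition = "control", readout = readout)
}

#' Write a synthetic titration set plus a ground-truth sidecar
#'
#' Convenience for building on-disk fixtures: writes one titration CSV per
#' temperature in the [read_titration_table()] format plus a YAML sidecar
#' recording every ground-truth parameter.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param temperatures Temperatures (K) for [simulate_temperature_series()].
#' @param conc_grid Concentration grid (mol/L).
#' @return Invisibly, a named list of written paths.
#' @export
write_synthetic_set <- function(config, dir, temperatures = c(298, 308),
                                conc_grid = default_conc_grid()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- simulate_temperature_series(config, temperatures, conc_grid)
  paths <- purrr::imap_chr(series, function(s, tK) {
    p <- file.path(dir, paste0("titration_", tK, "K.csv"))
    write_titration_table(s, p)
    p
  })
  truth_path <- file.path(dir, "truth.yaml")
  yaml::write_yaml(unclass(config), truth_path)
  invisible(list(titrations = paths, truth = truth_path))
}
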