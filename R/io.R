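concentration_factor <- function(units) {
  switch(tolower(units),
    "m" = , "mol/l" = 1,
    "mm" = 1e-3,
    "um" = , "µm" = , "μm" = 1e-6,
    "nm" = 1e-9,
    stop("unknown concentration unit: ", units, call. = FALSE)
  )
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a titration manifest
#'
#' A manifest is a small YAML (key: value) file declaring how to interpret a
#' titration table: `units` (concentration unit in the file; default "uM"),
#' `temperature_K`, `excitation_nm`, `readout_nm`, and optionally
#' `protein_conc` (mol/L).
#'
#' @param x Path to a YAML file, or a named list with the same fields.
#' @return A named list with defaults filled in.
#' @export
read_manifest <- function(x) {
  m <- if (is.character(x)) yaml::read_yaml(x) else as.list(x)
  defaults <- list(units = "uM", temperature_K = 298, excitation_nm = 280,
                   readout_nm = 340, protein_conc = 2e-6)
  utils::modifyList(defaults, m)
}

#' Read a titration table from delimited text
#'
#' Reads a two-column (`conc`, `intensity`) comma- or tab-delimited file,
#' converts concentrations to mol/L per the manifest's declared unit, sorts
#' ascending, and validates the series: a zero-concentration row (defining
#' F0) is required, duplicate concentrations are an error, and at least
#' three nonzero concentrations are needed for the downstream fits.
#'
#' @param path Path to the delimited file (delimiter auto-detected among
#'   comma and tab).
#' @param manifest A manifest list or YAML path (see [read_manifest()]).
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path, manifest = list()) {
  m <- read_manifest(manifest)
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  if (!all(c("conc", "intensity") %in% names(tab))) {
    stop("titration file must have columns `conc` and `intensity`",
         call. = FALSE)
  }
  fac <- concentration_factor(m$units)
  tab <- tab |>
    dplyr::mutate(conc = .data$conc * fac) |>
    dplyr::arrange(.data$conc)
  if (anyDuplicated(tab$conc)) {
    dup <- which(duplicated(tab$conc) | duplicated(tab$conc, fromLast = TRUE))
    stop("duplicate concentrations in rows (sorted order): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!any(tab$conc == 0)) {
    stop("missing zero-concentration row (needed to define F0)", call. = FALSE)
  }
  if (sum(tab$conc > 0) < 3L) {
    stop("need ≥3 nonzero concentrations for fitting", call. = FALSE)
  }
  titration_series(tab$conc, tab$intensity,
                   temperature_K = m$temperature_K,
                   protein_conc = m$protein_conc,
                   readout_nm = m$readout_nm)
}

#' Write a titration series to delimited text
#'
#' Writes the `conc` (mol/L) and `intensity` columns as CSV; the file
#' round-trips through [read_titration_table()] with a `units: "mol/L"`
#' manifest to full precision.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  readr::write_csv(tibble::tibble(conc = series$conc,
                                  intensity = series$intensity), path)
  invisible(path)
}

#' Read a multi-column spectra table
#'
#' Reads delimited text with a `wavelength_nm` column and one intensity
#' column per titrant concentration, headers of the form `I_<conc><unit>`
#' (e.g. `I_2uM`). Returns spectra in long form.
#'
#' @param path Path to the delimited file.
#' @param manifest Manifest list or YAML path; `units` applies when a column
#'   header carries no unit suffix.
#' @return A tibble with columns `conc` (mol/L), `wavelength`, `intensity`.
#' @export
read_spectra_table <- function(path, manifest = list()) {
  m <- read_manifest(manifest)
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  if (!"wavelength_nm" %in% names(tab)) {
    stop("spectra file must have a `wavelength_nm` column", call. = FALSE)
  }
  icols <- setdiff(names(tab), "wavelength_nm")
  if (!length(icols)) stop("no intensity columns found", call. = FALSE)
  parse_conc <- function(h) {
    body <- sub("^I_", "", h)
    mm <- regmatches(body, regexec("^([0-9.eE+-]+)([A-Za-z/]*)$", body))[[1]]
    if (length(mm) < 2L) stop("cannot parse intensity header: ", h, call. = FALSE)
    val <- as.numeric(mm[2])
    unit <- if (nzchar(mm[3])) mm[3] else m$units
    val * concentration_factor(unit)
  }
  concs <- vapply(icols, parse_conc, numeric(1))
  tab |>
    tidyr::pivot_longer(dplyr::all_of(icols), names_to = ".col",
                        values_to = "intensity") |>
    dplyr::mutate(conc = unname(concs[.data$.col])) |>
    dplyr::select(conc = "conc", wavelength = "wavelength_nm", "intensity") |>
    dplyr::arrange(.data$conc, .data$wavelength)
}
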