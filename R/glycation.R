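#' Excitation/emission registry for glycation fluorophores
#'
#' The excitation and emission wavelengths at which each fluorescent
#' species is read: the classical AGE fluorophores, the glycoxidation
#' products formed by oxidation of Trp/Tyr residues, and the thioflavin T
#' (ThT) amyloid reporter.
#'
#' @return A tibble with columns `species`, `excitation_nm`, `emission_nm`.
#' @export
wavelength_registry <- function() {
  tibble::tribble(
    ~species,               ~excitation_nm, ~emission_nm,
    "Total AGEs",           350,            440,
    "Vesperlysine",         350,            405,
    "Crossline",            380,            440,
    "Argpyrimidine",        320,            380,
    "Pentosidine",          335,            385,
    "Dityrosine",           330,            415,
    "Kynurenine",           365,            480,
    "N'-formylkynurenine",  325,            434,
    "ThT",                  440,            485
  )
}

#' Look up the excitation/emission pair for a species
#'
#' @param species A species label present in [wavelength_registry()]
#'   (case-insensitive).
#' @return A one-row tibble with `species`, `excitation_nm`, `emission_nm`.
#' @examples
#' wavelength_lookup("Pentosidine")
#' @export
wavelength_lookup <- function(species) {
  stopifnot(length(species) == 1L, is.character(species))
  reg <- wavelength_registry()
  i <- match(tolower(species), tolower(reg$species))
  if (is.na(i)) {
    stop("unknown species '", species, "'; known species: ",
         paste(reg$species, collapse = ", "), call. = FALSE)
  }
  reg[i, ]
}

#' Construct an assay panel
#'
#' Long-form replicated readings (fluorescence or absorbance) per
#' condition and species, with one condition designated as the control
#' that defines the F0 (or A0) reference.
#'
#' @param data Data frame with columns `condition`, `species`, `replicate`,
#'   `value`.
#' @param control_condition The condition label defining the reference.
#' @param readout `"fluorescence"` or `"absorbance"`.
#' @return A tibble of class `assay_panel`.
#' @export
assay_panel <- function(data, control_condition = "control",
                        readout = c("fluorescence", "absorbance")) {
  readout <- match.arg(readout)
  stopifnot(is.data.frame(data),
            all(c("condition", "species", "replicate", "value") %in% names(data)))
  if (!control_condition %in% data$condition) {
    stop("control condition '", control_condition, "' not present",
         call. = FALSE)
  }
  treated_species <- unique(data$species[data$condition != control_condition])
  ctrl_species <- unique(data$species[data$condition == control_condition])
  missing <- setdiff(treated_species, ctrl_species)
  if (length(missing)) {
    stop("species missing from the control condition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "control_condition") <- control_condition
  attr(out, "readout") <- readout
  class(out) <- c("assay_panel", class(out))
  out
}

#' Read an assay panel from long-format delimited text
#'
#' @param path Delimited file (comma or tab) with columns `condition`,
#'   `species`, `replicate`, `value`.
#' @param control_condition,readout Passed to [assay_panel()].
#' @return An [assay_panel()].
#' @export
read_assay_panel <- function(path, control_condition = "control",
                             readout = c("fluorescence", "absorbance")) {
  tab <- readr::read_delim(path, delim = detect_delim(path),
                           show_col_types = FALSE, trim_ws = TRUE)
  assay_panel(tab, control_condition, match.arg(readout))
}

#' Inhibition rate from replicated readings
#'
#' The fractional suppression of a glycation readout relative to the
#' uninhibited control, as a percentage:
#' `100 * (1 - mean(treated) / mean(control))`. The SD propagates the
#' replicate SDs of both groups through the ratio. Negative values
#' (readings above control) are reported, not clipped, and flagged as
#' enhancement. The same convention is applied to absorbance readouts.
#'
#' @param treated Replicate readings under the inhibitor.
#' @param control Replicate readings of the uninhibited control; mean > 0.
#' @return A one-row tibble with `inhibition_percent`, `sd_percent`
#'   (NA when either group has a single replicate), `n_treated`,
#'   `n_control`, `enhancement`.
#' @examples
#' inhibition_rate(c(660, 655, 665), c(1000, 995, 1005))  # ~34%
#' @export
inhibition_rate <- function(treated, control) {
  stopifnot(is.numeric(treated), is.numeric(control),
            length(treated) >= 1L, length(control) >= 1L)
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be positive", call. = FALSE)
  mt <- mean(treated)
  pct <- 100 * (1 - mt / mc)
  sd_pct <- if (length(treated) > 1L && length(control) > 1L) {
    st <- stats::sd(treated); sc <- stats::sd(control)
    100 * sqrt((st / mc)^2 + (mt * sc / mc^2)^2)
  } else NA_real_
  tibble::tibble(inhibition_percent = pct, sd_percent = sd_pct,
                 n_treated = length(treated), n_control = length(control),
                 enhancement = pct < 0)
}

#' Per-species inhibition table for an assay panel
#'
#' Applies [inhibition_rate()] to every treated condition x species cell of
#' a panel against its control, and annotates each species with its
#' registered excitation/emission pair when available.
#'
#' @param panel An [assay_panel()].
#' @return A tibble with one row per (condition, species): the
#'   [inhibition_rate()] columns plus `excitation_nm`/`emission_nm`.
#' @export
inhibition_table <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  ctrl_label <- attr(panel, "control_condition")
  ctrl <- panel |>
    dplyr::filter(.data$condition == ctrl_label) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(control_values = list(.data$value), .groups = "drop")
  out <- panel |>
    dplyr::filter(.data$condition != ctrl_label) |>
    dplyr::group_by(.data$condition, .data$species) |>
    dplyr::summarise(treated_values = list(.data$value), .groups = "drop") |>
    dplyr::left_join(ctrl, by = "species") |>
    dplyr::mutate(stats = purrr::map2(.data$treated_values,
                                      .data$control_values, inhibition_rate)) |>
    dplyr::select(-"treated_values", -"control_values") |>
    tidyr::unnest("stats")
  reg <- wavelength_registry()
  dplyr::left_join(out, reg, by = "species")
}

#' Thioflavin T relative fibril index
#'
#' ThT fluorescence (read at 440/485 nm ex/em) increases on binding the
#' cross-beta structure of amyloid-like fibrils; the ratio of mean treated
#' to mean control intensity is a simple relative fibrillation index
#' (1 = no change, < 1 = suppression).
#'
#' @param treated Replicate ThT readings under the condition of interest.
#' @param control Replicate readings of the reference condition; mean > 0.
#' @return A one-row tibble with `fibril_index`, `sd_index` (NA with single
#'   replicates), `n_treated`, `n_control`.
#' @export
tht_fibril_index <- function(treated, control) {
  stopifnot(is.numeric(treated), is.numeric(control))
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be positive", call. = FALSE)
  mt <- mean(treated)
  idx <- mt / mc
  sd_idx <- if (length(treated) > 1L && length(control) > 1L) {
    st <- stats::sd(treated); sc <- stats::sd(control)
    sqrt((st / mc)^2 + (mt * sc / mc^2)^2)
  } else NA_real_
  tibble::tibble(fibril_index = idx, sd_index = sd_idx,
                 n_treated = length(treated), n_control = length(control))
}

#' Compare conditions by one-way ANOVA with Tukey's HSD
#'
#' A thin reporting layer (convenience, not a contribution of this
#' package) over `stats::aov()` and `stats::TukeyHSD()`: per species, a
#' one-way ANOVA of reading on condition followed by all pairwise Tukey
#' contrasts.
#'
#' @param panel An [assay_panel()] with >= 2 replicates per cell.
#' @return A tibble with one row per species x pairwise contrast:
#'   `species`, `contrast`, `diff`, `conf.low`, `conf.high`, `p.adj`, and
#'   the ANOVA `f.statistic` / `p.value` for that species.
#' @export
compare_conditions <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  panel |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(df, key) {
      df$condition <- factor(df$condition)
      if (nlevels(df$condition) < 2L) {
        stop("species '", key$species, "' has a single condition", call. = FALSE)
      }
      fit <- stats::aov(value ~ condition, data = df)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$condition
      tibble::tibble(
        contrast = rownames(tk),
        diff = tk[, "diff"], conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
        p.adj = tk[, "p adj"],
        f.statistic = an["condition", "F value"],
        p.value = an["condition", "Pr(>F)"]
      )
    }) |>
    dplyr::ungroup()
}
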