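#' Known serum-albumin site-marker probes
#'
#' The classical marker ligands used to localize a new ligand's binding
#' site by competition: warfarin marks site 1 (subdomain IIA), ibuprofen
#' site 2 (subdomain IIIA), methyl orange site 3.
#'
#' @return A tibble with columns `probe_name` and `site_id`.
#' @export
probe_sites <- function() {
  tibble::tibble(
    probe_name = c("warfarin", "ibuprofen", "methyl orange"),
    site_id = c(1L, 2L, 3L)
  )
}

site_for_probe <- function(probe_name) {
  ps <- probe_sites()
  i <- match(tolower(probe_name), ps$probe_name)
  if (any(is.na(i))) {
    stop("unknown probe(s): ",
         paste(probe_name[is.na(i)], collapse = ", "),
         "; known probes: ", paste(ps$probe_name, collapse = ", "),
         call. = FALSE)
  }
  ps$site_id[i]
}

#' Remaining-signal ratio of a site-marker displacement experiment
#'
#' The printed displacement statistic is the ratio of the complex's
#' fluorescence in the presence (F2) versus absence (F1) of the marker
#' probe, times 100. Note this is a remaining-signal ratio, not a
#' "fraction displaced": 100% means the probe had no effect. Ratios above
#' 100% (probe-induced enhancement) are reported, not clipped, and flagged.
#'
#' @param F2 Intensity (or intensities) with the probe present.
#' @param F1 Matching intensity without the probe; must be > 0.
#' @return A tibble with columns `F2`, `F1`, `percent` (100 F2/F1) and
#'   `enhancement` (`percent > 100`).
#' @examples
#' probe_displacement_percent(c(500, 600), c(1000, 500))
#' @export
probe_displacement_percent <- function(F2, F1) {
  stopifnot(is.numeric(F2), is.numeric(F1))
  if (any(F1 <= 0)) stop("F1 must be positive", call. = FALSE)
  pct <- 100 * F2 / F1
  tibble::tibble(F2 = as.numeric(F2), F1 = as.numeric(F1),
                 percent = pct, enhancement = pct > 100)
}

#' Construct a site-marker displacement experiment
#'
#' Pairs the ligand titration recorded with a marker probe pre-bound
#' (1:1 probe:protein) against the probe-free titration on the same
#' concentration grid.
#'
#' @param probe_name One of the [probe_sites()] names.
#' @param series_with_probe [titration_series()] with the probe present.
#' @param series_without_probe [titration_series()] without the probe.
#' @param probe_ratio Probe:protein molar ratio (recorded; default 1).
#' @return A list of class `displacement_experiment`.
#' @export
displacement_experiment <- function(probe_name, series_with_probe,
                                    series_without_probe, probe_ratio = 1) {
  stopifnot(inherits(series_with_probe, "titration_series"),
            inherits(series_without_probe, "titration_series"))
  site_id <- site_for_probe(probe_name)
  if (!isTRUE(all.equal(series_with_probe$conc, series_without_probe$conc))) {
    stop("both series must share the same concentration grid", call. = FALSE)
  }
  structure(list(probe_name = tolower(probe_name), site_id = site_id,
                 series_with_probe = series_with_probe,
                 series_without_probe = series_without_probe,
                 probe_ratio = probe_ratio),
            class = "displacement_experiment")
}

#' Per-concentration displacement profile
#'
#' @param experiment A [displacement_experiment()].
#' @return A tibble with `conc` plus the [probe_displacement_percent()]
#'   columns at each concentration.
#' @export
displacement_profile <- function(experiment) {
  stopifnot(inherits(experiment, "displacement_experiment"))
  dplyr::bind_cols(
    tibble::tibble(conc = experiment$series_with_probe$conc),
    probe_displacement_percent(experiment$series_with_probe$intensity,
                               experiment$series_without_probe$intensity)
  )
}

#' Assign the primary binding site by marker competition
#'
#' Fits the association constant in the presence of each probe (K'a, via
#' [fit_double_log()] on the with-probe series), forms the retention ratio
#' `100 * K'a / Ka` against the probe-free reference constant, and assigns
#' the site whose probe suppresses binding most — the minimum ratio —
#' provided that ratio is below `ratio_threshold` and the next-lowest
#' ratio exceeds it by at least `separation` percentage points. Otherwise
#' the call is ambiguous, with the reason reported.
#'
#' @param x Either a list of [displacement_experiment()] objects (>= 2
#'   probes), or a data frame with columns `probe_name` and `Ka_prime`
#'   (L/mol) when the constants are already fitted.
#' @param Ka_reference Probe-free association constant (L/mol). Required
#'   with the data-frame input; with experiments it defaults to a
#'   [fit_double_log()] on the first experiment's probe-free series.
#' @param ratio_threshold Maximum retention ratio (%) for an assignment.
#'   Default 60.
#' @param separation Minimum gap (percentage points) between the lowest and
#'   next-lowest ratio. Default 10.
#'
#' @return An object of class `site_assignment`: a list with `ratios` (a
#'   tibble: `probe_name`, `site_id`, `Ka_prime`, `ratio_percent`),
#'   `Ka_reference`, `assigned_site`, `assigned_probe`, and `status`
#'   (`"assigned"`, `"ambiguous: tie"`, or
#'   `"ambiguous: no competing probe"`).
#' @examples
#' tbl <- tibble::tibble(
#'   probe_name = c("warfarin", "methyl orange", "ibuprofen"),
#'   Ka_prime = c(0.98e4, 1.79e4, 3.38e4))
#' assign_primary_site(tbl, Ka_reference = 3.79e4)
#' @export
assign_primary_site <- function(x, Ka_reference = NULL, ratio_threshold = 60,
                                separation = 10) {
  stopifnot(ratio_threshold > 0, separation >= 0)
  if (is.data.frame(x)) {
    stopifnot(all(c("probe_name", "Ka_prime") %in% names(x)))
    if (is.null(Ka_reference)) {
      stop("`Ka_reference` is required with a data-frame input", call. = FALSE)
    }
    ratios <- tibble::as_tibble(x) |>
      dplyr::mutate(probe_name = tolower(.data$probe_name),
                    site_id = site_for_probe(.data$probe_name))
  } else {
    stopifnot(is.list(x), length(x) >= 2L,
              all(vapply(x, inherits, logical(1), "displacement_experiment")))
    if (is.null(Ka_reference)) {
      ref_fit <- tryCatch(
        fit_double_log(x[[1]]$series_without_probe),
        error = function(e) stop("reference fit failed: ",
                                 conditionMessage(e), call. = FALSE))
      Ka_reference <- ref_fit$Ka
    }
    ratios <- purrr::map_dfr(x, function(ex) {
      fit <- tryCatch(
        fit_double_log(ex$series_with_probe),
        error = function(e) stop("fit failed for probe '", ex$probe_name,
                                 "': ", conditionMessage(e), call. = FALSE))
      tibble::tibble(probe_name = ex$probe_name, site_id = ex$site_id,
                     Ka_prime = fit$Ka)
    })
  }
  if (nrow(ratios) < 2L) stop("need >= 2 probes", call. = FALSE)
  stopifnot(Ka_reference > 0)
  ratios <- ratios |>
    dplyr::mutate(ratio_percent = 100 * .data$Ka_prime / Ka_reference) |>
    dplyr::arrange(.data$ratio_percent) |>
    dplyr::select("probe_name", "site_id", "Ka_prime", "ratio_percent")

  lo <- ratios$ratio_percent[1]
  next_lo <- ratios$ratio_percent[2]
  if (lo >= ratio_threshold) {
    status <- "ambiguous: no competing probe"
    assigned_site <- NA_integer_; assigned_probe <- NA_character_
  } else if (next_lo - lo < separation) {
    status <- "ambiguous: tie"
    assigned_site <- NA_integer_; assigned_probe <- NA_character_
  } else {
    status <- "assigned"
    assigned_site <- ratios$site_id[1]
    assigned_probe <- ratios$probe_name[1]
  }
  structure(list(ratios = ratios, Ka_reference = Ka_reference,
                 assigned_site = assigned_site, assigned_probe = assigned_probe,
                 status = status, ratio_threshold = ratio_threshold,
                 separation = separation),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat("Site-marker competition (Ka_reference =",
      format(x$Ka_reference, digits = 4), "L/mol)\n")
  print(x$ratios)
  if (x$status == "assigned") {
    cat("Primary binding site: site ", x$assigned_site, " (",
        x$assigned_probe, " probe)\n", sep = "")
  } else {
    cat("Assignment:", x$status, "\n")
    if (x$status == "ambiguous: tie") {
      tied <- x$ratios[x$ratios$ratio_percent - min(x$ratios$ratio_percent) <
                         x$separation, ]
      cat("  tied probes:", paste(tied$probe_name, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @method tidy site_assignment
#' @export
tidy.site_assignment <- function(x, ...) x$ratios

#' @method glance site_assignment
#' @export
glance.site_assignment <- function(x, ...) {
  tibble::tibble(status = x$status, assigned_site = x$assigned_site,
                 assigned_probe = x$assigned_probe,
                 Ka_reference = x$Ka_reference)
}
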