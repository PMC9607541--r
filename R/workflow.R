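# key = value serialization for diff-able stage reports
write_kv <- function(x, path) {
  flat <- unlist(x)
  lines <- paste0(names(flat), " = ",
                  vapply(flat, format, character(1), digits = 15))
  writeLines(lines, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Read and validate a workflow manifest
#'
#' A workflow manifest is a YAML file (or equivalent list) that names the
#' input files and analysis settings for [run_full_workflow()]:
#'
#' * `titrations`: list of entries with `path` and per-file manifest fields
#'   (`units`, `temperature_K`, ...), one per temperature;
#' * `probes` (optional): named list (probe name -> entry with `path`) of
#'   with-probe titrations sharing the first titration's grid;
#' * `synchronous` (optional): list of entries with `path` and
#'   `delta_lambda`;
#' * `glycation` (optional): entry with `path` (long-format panel file) and
#'   `control_condition`;
#' * settings: `tau0` (s, default 1e-8), `kq_ceiling` (default 2e10),
#'   `ratio_threshold` (60), `separation` (10), `shift_call_threshold`
#'   (0.5), `seed`, `output_dir`.
#'
#' @param x Path to a YAML manifest or a list.
#' @param base_dir Directory against which relative paths resolve
#'   (defaults to the manifest's directory, or `.` for a list).
#' @return A validated manifest list with defaults filled in.
#' @export
read_workflow_manifest <- function(x, base_dir = NULL) {
  if (is.character(x)) {
    if (is.null(base_dir)) base_dir <- dirname(x)
    m <- yaml::read_yaml(x)
  } else {
    if (is.null(base_dir)) base_dir <- "."
    m <- as.list(x)
  }
  defaults <- list(tau0 = 1e-8, kq_ceiling = 2e10, ratio_threshold = 60,
                   separation = 10, shift_call_threshold = 0.5,
                   seed = 1L, output_dir = NULL)
  m <- utils::modifyList(defaults, m)
  stopifnot(m$tau0 > 0, m$kq_ceiling > 0, m$ratio_threshold > 0,
            m$shift_call_threshold >= 0)
  if (is.null(m$titrations) || !length(m$titrations)) {
    stop("manifest must list at least one titration", call. = FALSE)
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  check_path <- function(entry, what) {
    entry$path <- resolve(entry$path)
    if (!file.exists(entry$path)) {
      stop("missing input file for ", what, ": ", entry$path, call. = FALSE)
    }
    entry
  }
  m$titrations <- purrr::imap(m$titrations, function(e, i) {
    check_path(e, paste0("titration #", i))
  })
  if (!is.null(m$probes)) {
    m$probes <- purrr::imap(m$probes, function(e, nm) {
      check_path(e, paste0("probe '", nm, "'"))
    })
  }
  if (!is.null(m$synchronous)) {
    m$synchronous <- purrr::imap(m$synchronous, function(e, i) {
      check_path(e, paste0("synchronous series #", i))
    })
  }
  if (!is.null(m$glycation)) m$glycation <- check_path(m$glycation, "glycation panel")
  m
}

#' Run the complete binding + glycation workflow
#'
#' Executes the full inference chain on the files a manifest names, in the
#' order the underlying experiments build on one another: titration
#' reading, Stern-Volmer quenching fits and mechanism classification,
#' double-logarithmic binding fits, van't Hoff thermodynamics with force
#' typing, site-marker displacement (when probe files are given),
#' synchronous peak-shift analysis and glycation inhibition statistics
#' (when given). Deterministic given inputs and seed. When
#' `output_dir` is set, each stage writes a diff-able key-value report and
#' delimited tables there.
#'
#' @param manifest Path to a YAML workflow manifest or an equivalent list;
#'   see [read_workflow_manifest()].
#' @return An object of class `workflow_report`: a list with elements
#'   `quenching` (per-temperature `sv_fit`s), `mechanism`, `binding`
#'   (per-temperature `dlog_fit`s), `thermodynamics`, and, when inputs are
#'   present, `displacement`, `synchronous`, `glycation`.
#' @export
run_full_workflow <- function(manifest) {
  m <- read_workflow_manifest(manifest)
  out_dir <- m$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  series <- stage("read_titrations", purrr::map(m$titrations, function(e) {
    read_titration_table(e$path, e[setdiff(names(e), "path")])
  }))
  temps <- vapply(series, series_temperature, numeric(1))
  names(series) <- as.character(temps)

  sv <- stage("stern_volmer", purrr::map(series, fit_stern_volmer, tau0 = m$tau0))
  mech <- stage("mechanism",
                classify_quenching_mechanism(sv, kq_ceiling = m$kq_ceiling))
  dlog <- stage("double_log", purrr::map(series, fit_double_log))
  ka_tab <- tibble::tibble(temperature_K = temps,
                           Ka = vapply(dlog, function(f) f$Ka, numeric(1)))
  thermo <- if (nrow(ka_tab) >= 2L) stage("vant_hoff", fit_vant_hoff(ka_tab)) else NULL

  report <- list(quenching = sv, mechanism = mech, binding = dlog,
                 thermodynamics = thermo)

  if (!is.null(m$probes)) {
    report$displacement <- stage("displacement", {
      base <- series[[1]]
      exps <- purrr::imap(m$probes, function(e, nm) {
        with_probe <- read_titration_table(e$path, e[setdiff(names(e), "path")])
        displacement_experiment(nm, with_probe, base)
      })
      assign_primary_site(unname(exps), ratio_threshold = m$ratio_threshold,
                          separation = m$separation)
    })
  }
  if (!is.null(m$synchronous)) {
    report$synchronous <- stage("synchronous", purrr::map(m$synchronous, function(e) {
      dat <- read_spectra_table(e$path, e[setdiff(names(e), c("path", "delta_lambda"))])
      detect_peak_shift(synchronous_series(dat, e$delta_lambda),
                        call_threshold = m$shift_call_threshold)
    }))
  }
  if (!is.null(m$glycation)) {
    report$glycation <- stage("glycation", {
      ctrl <- m$glycation$control_condition %||% "control"
      panel <- read_assay_panel(m$glycation$path, control_condition = ctrl)
      inhibition_table(panel)
    })
  }

  if (!is.null(out_dir)) write_workflow_report(report, out_dir)
  class(report) <- "workflow_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_workflow_report <- function(report, out_dir) {
  sv_tab <- purrr::map_dfr(report$quenching, function(f) {
    tibble::tibble(temperature_K = f$temperature_K, Ksv = f$Ksv,
                   Ksv_se = f$Ksv_se, Kq = f$Kq, intercept = f$intercept,
                   r_squared = f$r_squared)
  })
  readr::write_csv(sv_tab, file.path(out_dir, "stern_volmer.csv"))
  dl_tab <- purrr::map_dfr(report$binding, function(f) {
    tibble::tibble(temperature_K = f$temperature_K, Ka = f$Ka, Ka_se = f$Ka_se,
                   n = f$n, n_se = f$n_se, r_squared = f$r_squared)
  })
  readr::write_csv(dl_tab, file.path(out_dir, "binding.csv"))
  kv <- list(mechanism = report$mechanism$mechanism,
             ksv_trend = report$mechanism$ksv_trend,
             kq_all_above_ceiling = report$mechanism$kq_all_above_ceiling)
  if (!is.null(report$thermodynamics)) {
    th <- report$thermodynamics
    kv <- c(kv, list(dH_kJ_mol = th$dH, dS_J_mol_K = th$dS,
                     forces = paste(th$forces$forces, collapse = " + ")))
    readr::write_csv(th$table, file.path(out_dir, "thermodynamics.csv"))
  }
  if (!is.null(report$displacement)) {
    d <- report$displacement
    readr::write_csv(d$ratios, file.path(out_dir, "displacement.csv"))
    kv <- c(kv, list(site_status = d$status, assigned_site = d$assigned_site))
  }
  if (!is.null(report$synchronous)) {
    sh <- purrr::map_dfr(report$synchronous, glance)
    readr::write_csv(sh, file.path(out_dir, "synchronous.csv"))
  }
  if (!is.null(report$glycation)) {
    readr::write_csv(report$glycation, file.path(out_dir, "glycation.csv"))
  }
  write_kv(kv, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("== Quenching (Stern-Volmer) ==\n")
  purrr::walk(x$quenching, print)
  print(x$mechanism)
  cat("\n== Binding (double-log) ==\n")
  purrr::walk(x$binding, print)
  if (!is.null(x$thermodynamics)) {
    cat("\n== Thermodynamics (van't Hoff) ==\n")
    print(x$thermodynamics)
  }
  if (!is.null(x$displacement)) {
    cat("\n== Site-marker displacement ==\n")
    print(x$displacement)
  }
  if (!is.null(x$synchronous)) {
    cat("\n== Synchronous peak shifts ==\n")
    purrr::walk(x$synchronous, print)
  }
  if (!is.null(x$glycation)) {
    cat("\n== Glycation inhibition ==\n")
    print(x$glycation)
  }
  invisible(x)
}
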