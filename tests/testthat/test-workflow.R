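make_workflow_fixture <- function(dir, noise_cv = 0, seed = 1) {
  cfg <- sim_config(dH_true = -51.53, dS_true = -85.25, n_true = 1.5,
                    noise_cv = noise_cv, seed = seed)
  set <- write_synthetic_set(cfg, dir, temperatures = c(298, 308))
  # with-probe titrations: binding suppressed per probe at 298 K
  base <- make_hill_series(Ka = ka_from_thermo(-51.53, -85.25, 298), n = 1.5)
  probes <- list(warfarin = 0.98e4, `methyl orange` = 1.79e4,
                 ibuprofen = 3.38e4)
  probe_entries <- lapply(names(probes), function(nm) {
    s <- make_hill_series(Ka = probes[[nm]], n = 1.5)
    p <- file.path(dir, paste0("probe_", gsub(" ", "_", nm), ".csv"))
    write_titration_table(s, p)
    list(path = p, units = "mol/L", temperature_K = 298)
  })
  names(probe_entries) <- names(probes)
  panel <- simulate_glycation_panel(c(myr = 0.34), replicates = 3,
                                    noise_cv = 0, seed = seed)
  gly_path <- file.path(dir, "glycation.csv")
  readr::write_csv(panel, gly_path)
  list(
    titrations = list(
      list(path = set$titrations[["298"]], units = "mol/L", temperature_K = 298),
      list(path = set$titrations[["308"]], units = "mol/L", temperature_K = 308)
    ),
    probes = probe_entries,
    glycation = list(path = gly_path, control_condition = "control"),
    seed = seed
  )
}

test_that("the full workflow reproduces the thermodynamics end-to-end", {
  dir <- withr::local_tempdir()
  manifest <- make_workflow_fixture(dir)
  report <- run_full_workflow(manifest)
  # hill-law data on this grid quenches weakly, so the apparent Ksv falls
  # with temperature but Kq sits below the collision ceiling
  expect_identical(report$mechanism$ksv_trend, "decreasing")
  expect_true(report$mechanism$mechanism %in%
                c("static", "dynamic", "indeterminate"))
  expect_equal(report$thermodynamics$dH, -51.53, tolerance = 1e-3)
  expect_equal(report$thermodynamics$dS, -85.25, tolerance = 1e-2)
  expect_setequal(report$thermodynamics$forces$forces,
                  c("van der Waals", "hydrogen bond"))
  expect_identical(report$displacement$assigned_site, 1L)
  expect_equal(report$glycation$inhibition_percent, 34, tolerance = 1e-9)
})

test_that("workflow output is byte-identical on rerun", {
  dir <- withr::local_tempdir()
  manifest <- make_workflow_fixture(dir, noise_cv = 0.01, seed = 9)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  # weakly quenched noisy data legitimately warns about a flat SV slope
  suppressWarnings(run_full_workflow(c(manifest, list(output_dir = out1))))
  suppressWarnings(run_full_workflow(c(manifest, list(output_dir = out2))))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_true("summary.txt" %in% list.files(out1))
})

test_that("a missing probe file is reported by probe name", {
  dir <- withr::local_tempdir()
  manifest <- make_workflow_fixture(dir)
  manifest$probes$warfarin$path <- file.path(dir, "nonexistent.csv")
  expect_error(run_full_workflow(manifest), "warfarin")
})

test_that("stage errors name the failing stage", {
  dir <- withr::local_tempdir()
  manifest <- make_workflow_fixture(dir)
  flat <- titration_series(default_conc_grid(), rep(1000, 6))
  write_titration_table(flat, manifest$titrations[[1]]$path)
  expect_error(suppressWarnings(run_full_workflow(manifest)), "stage '")
})

test_that("manifests can come from YAML on disk", {
  dir <- withr::local_tempdir()
  manifest <- make_workflow_fixture(dir)
  ypath <- file.path(dir, "workflow.yaml")
  yaml::write_yaml(manifest, ypath)
  report <- run_full_workflow(ypath)
  expect_equal(report$thermodynamics$dH, -51.53, tolerance = 1e-3)
})
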