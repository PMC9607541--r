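test_that("stern_volmer generator matches the closed form", {
  cfg <- sim_config("stern_volmer", F0_true = 1000, Ksv_true = 1.21e5,
                    noise_cv = 0)
  ts <- simulate_titration(cfg, conc_grid = c(0, 1e-5))
  expect_equal(ts$intensity[ts$conc == 1e-5], 1000 / (1 + 1.21), tolerance = 1e-12)
  expect_equal(round(ts$intensity[2], 2), 452.49)
})

test_that("zero quencher returns F0 exactly in both modes", {
  for (mode in c("stern_volmer", "hill_binding")) {
    cfg <- sim_config(mode, F0_true = 1234, noise_cv = 0)
    ts <- simulate_titration(cfg)
    expect_identical(ts$intensity[ts$conc == 0], 1234)
  }
})

test_that("generators are deterministic under a seed and leave the RNG alone", {
  cfg <- sim_config("hill_binding", noise_cv = 0.05, seed = 7)
  a <- simulate_titration(cfg)
  set.seed(99); before <- rnorm(1)
  b <- simulate_titration(cfg)
  set.seed(99); after <- rnorm(1)
  expect_identical(a$intensity, b$intensity)
  expect_identical(before, after)
  cfg2 <- sim_config("hill_binding", noise_cv = 0.05, seed = 8)
  expect_false(identical(simulate_titration(cfg2)$intensity, a$intensity))
})

test_that("van't Hoff generator reproduces the known binding constant", {
  ka <- ka_from_thermo(-51.53, -85.27, 298)
  expect_lt(abs(ka - 3.79e4), 0.18e4)  # within the reported uncertainty
})

test_that("zero enthalpy gives temperature-independent Ka", {
  cfg <- sim_config(dH_true = 0, dS_true = 50, noise_cv = 0)
  kas <- sapply(c(288, 298, 308, 318), function(tK)
    ka_from_thermo(cfg$dH_true, cfg$dS_true, tK))
  expect_true(all(abs(diff(kas)) < 1e-9 * kas[1]))
})

test_that("temperature series round-trips (dH, dS) through the fits", {
  cfg <- sim_config(dH_true = -51.53, dS_true = -85.25, n_true = 1,
                    noise_cv = 0)
  series <- simulate_temperature_series(cfg, c(288, 298, 308))
  ka_tab <- tibble::tibble(
    temperature_K = as.numeric(names(series)),
    Ka = vapply(series, function(s) fit_double_log(s)$Ka, numeric(1)))
  th <- fit_vant_hoff(ka_tab)
  expect_equal(th$dH, -51.53, tolerance = 1e-9)
  expect_equal(th$dS, -85.25, tolerance = 1e-9)
})

test_that("temperature series validates its inputs", {
  cfg <- sim_config(noise_cv = 0)
  expect_error(simulate_temperature_series(cfg, 298), ">= 2")
  expect_error(simulate_temperature_series(cfg, c(298, 298)), "distinct")
})

test_that("null shift gives identical synchronous band centers", {
  cfg <- sim_config(noise_cv = 0)
  s <- simulate_synchronous(cfg, delta_lambda = 60, shift_per_conc = 0)
  res <- detect_peak_shift(s)
  expect_equal(diff(range(res$peaks$peak_wavelength)), 0, tolerance = 1e-8)
  expect_identical(res$direction, "none")
})

test_that("zero-noise glycation panel encodes its truth exactly", {
  p <- simulate_glycation_panel(c(myr = 0.34), baseline = 1000,
                                replicates = 3, noise_cv = 0)
  tab <- inhibition_table(p)
  expect_equal(tab$inhibition_percent, 34)
  expect_equal(tab$excitation_nm, 350)
  expect_equal(tab$emission_nm, 440)
})

test_that("noiseless parameter recovery is exact for both fits", {
  sv <- fit_stern_volmer(simulate_titration(sim_config("stern_volmer",
                                                       noise_cv = 0)))
  expect_equal(sv$Ksv, 1.21e5, tolerance = 1e-9)
  expect_equal(sv$r_squared, 1, tolerance = 1e-9)
  dl <- fit_double_log(simulate_titration(sim_config("hill_binding",
                                                     noise_cv = 0)))
  expect_equal(dl$Ka, 3.79e4, tolerance = 1e-9)
  expect_equal(dl$n, 1.5, tolerance = 1e-9)
})

test_that("truth sidecar and titration files are written together", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(noise_cv = 0.01, seed = 3)
  paths <- write_synthetic_set(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  truth <- yaml::read_yaml(paths$truth)
  expect_equal(truth$Ka_true, cfg$Ka_true)
  back <- read_titration_table(paths$titrations[["298"]],
                               list(units = "mol/L", temperature_K = 298))
  expect_equal(nrow(back), 6)
})
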