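test_that("constructors enforce series invariants", {
  expect_error(titration_series(c(1e-6, 2e-6), c(10, 9)), "zero-concentration")
  expect_error(titration_series(c(0, 2e-6, 2e-6, 4e-6), c(10, 9, 8, 7)),
               "strictly increasing")
  expect_error(titration_series(c(0, 1e-6), c(10, -1)), "positive")
  expect_error(emission_spectrum(c(300, 300, 301), c(1, 2, 3)),
               "strictly increasing")
  expect_error(emission_spectrum(300:302, c(1, -2, 3)), "non-negative")
})

test_that("peak extraction recovers a symmetric band exactly", {
  sp <- gaussian_spectrum(center = 340, sd = 25, amplitude = 1000)
  pk <- extract_peak_intensity(sp, nominal_peak = 340, window = 15)
  expect_equal(pk$peak_wavelength, 340, tolerance = 1e-8)
  # quadratic approximates the Gaussian crown; a small downward bias is expected
  expect_equal(pk$peak_intensity, 1000, tolerance = 0.01)
  expect_true(pk$reliable)
})

test_that("peak extraction follows the data, not the nominal guess", {
  sp <- gaussian_spectrum(center = 346, sd = 25)
  pk <- extract_peak_intensity(sp, nominal_peak = 340, window = 20)
  expect_equal(pk$peak_wavelength, 346, tolerance = 0.05)
})

test_that("peak center is recovered within 0.5 nm under 1% noise", {
  set.seed(42)
  centers <- replicate(50, {
    wl <- seq(290, 500, by = 1)
    y <- 1000 * exp(-(wl - 340)^2 / (2 * 25^2))
    y <- pmax(y * (1 + rnorm(length(y), 0, 0.01)), 0)
    extract_peak_intensity(emission_spectrum(wl, y), 340, 15)$peak_wavelength
  })
  expect_lt(abs(mean(centers) - 340), 0.5)
})

test_that("peak extraction is invariant under uniform intensity scaling", {
  sp <- gaussian_spectrum(center = 338, sd = 20)
  pk1 <- extract_peak_intensity(sp, 340, 15)
  for (c in c(0.2, 7, 1e4)) {
    sp2 <- emission_spectrum(sp$wavelength, sp$intensity * c)
    pk2 <- extract_peak_intensity(sp2, 340, 15)
    expect_equal(pk2$peak_wavelength, pk1$peak_wavelength)
    expect_equal(pk2$peak_intensity, pk1$peak_intensity * c)
  }
})

test_that("a boundary maximum is flagged unreliable with a warning", {
  wl <- 300:400
  sp <- emission_spectrum(wl, seq_along(wl) + 0)  # monotone ramp
  expect_warning(pk <- extract_peak_intensity(sp, 395, 10), "boundary")
  expect_false(pk$reliable)
  expect_equal(pk$peak_wavelength, 400)
})

test_that("titration tables round-trip through disk to full precision", {
  ts <- make_hill_series()
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(ts, path)
  back <- read_titration_table(path, list(units = "mol/L"))
  expect_equal(back$conc, ts$conc)
  expect_equal(back$intensity, ts$intensity)
})

test_that("micromolar file units convert to mol/L", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conc,intensity", "0,1000", "2,900", "4,820", "6,760",
               "8,700", "10,660"), path)
  ts <- read_titration_table(path, list(units = "uM"))
  expect_equal(ts$conc, c(0, 2, 4, 6, 8, 10) * 1e-6)
})

test_that("table validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conc,intensity", "0,1000"), path)
  expect_error(read_titration_table(path), "3 nonzero")
  writeLines(c("conc,intensity", "2,900", "4,820", "6,760", "8,700"), path)
  expect_error(read_titration_table(path), "zero-concentration")
  writeLines(c("conc,intensity", "0,1000", "2,900", "2,910", "4,820", "6,760"),
             path)
  expect_error(read_titration_table(path), "duplicate")
})

test_that("multi-column spectra files parse headers into concentrations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,I_0uM,I_2uM,I_4uM",
               "300,10,9,8", "301,11,10,9", "302,12,11,10"), path)
  long <- read_spectra_table(path)
  expect_equal(sort(unique(long$conc)), c(0, 2e-6, 4e-6))
  expect_equal(nrow(long), 9)
  expect_equal(long$intensity[long$conc == 4e-6 & long$wavelength == 302], 10)
})
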