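test_that("Stern-Volmer fit is exact on noiseless data", {
  ts <- make_sv_series(Ksv = 1.21e5)
  fit <- fit_stern_volmer(ts)
  expect_equal(fit$Ksv, 1.21e5, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_false(fit$no_quenching)
})

test_that("Kq = Ksv / tau0 identity holds for any lifetime", {
  ts <- make_sv_series()
  for (tau0 in c(1e-8, 5e-9, 2.3e-8)) {
    fit <- fit_stern_volmer(ts, tau0 = tau0)
    expect_identical(fit$Kq, fit$Ksv / tau0)
  }
})

test_that("constant intensity is flagged as no quenching", {
  ts <- titration_series(default_conc_grid(), rep(1000, 6))
  expect_warning(fit <- fit_stern_volmer(ts), "no quenching")
  expect_lt(abs(fit$Ksv), 1e-9)
  expect_true(fit$no_quenching)
})

test_that("an off-unity intercept triggers a warning", {
  conc <- default_conc_grid()
  # quenched points consistent with an F0/F intercept of 1.3, not 1
  f <- c(1000, 1000 / (1.3 + 1.21e5 * conc[-1]))
  expect_warning(fit_stern_volmer(titration_series(conc, f)), "intercept")
})

test_that("double-log fit recovers (Ka, n) exactly on noiseless data", {
  ts <- make_hill_series(Ka = 3.79e4, n = 1.5)
  fit <- fit_double_log(ts)
  expect_equal(fit$Ka, 3.79e4, tolerance = 1e-10)
  expect_equal(fit$n, 1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("half-quenching occurs at [Q] = 1/Ka when n = 1", {
  ka <- 2e5
  ts <- make_hill_series(Ka = ka, n = 1, conc = c(0, 1e-6, 1 / ka, 1e-5))
  expect_equal(ts$intensity[ts$conc == 1 / ka], f_zero(ts) / 2)
  fit <- fit_double_log(ts)
  expect_equal(fit$Ka, ka, tolerance = 1e-9)
})

test_that("unusable points are excluded and named", {
  conc <- c(0, 2, 4, 6, 8, 10) * 1e-6
  f <- c(1000, 1001, 1002, 900, 800, 700)  # two points above F0
  ts <- titration_series(conc, f)
  fit <- fit_double_log(ts)
  expect_equal(fit$n_excluded, 2L)
  expect_equal(fit$n_points, 3L)
  f_bad <- c(1000, 1001, 1002, 1003, 800, 700)
  expect_error(fit_double_log(titration_series(conc, f_bad)), "excluded rows")
})

test_that("both fits are invariant under uniform intensity rescaling", {
  sv0 <- fit_stern_volmer(make_sv_series())
  dl0 <- fit_double_log(make_hill_series())
  for (c in c(0.01, 3.7, 1e3)) {
    sv <- fit_stern_volmer(titration_series(sv0$data$conc,
                                            c * closed_form_sv(sv0$data$conc, 1000, 1.21e5)))
    expect_equal(sv$Ksv, sv0$Ksv, tolerance = 1e-9)
    conc <- default_conc_grid()
    dl <- fit_double_log(titration_series(conc,
                                          c * closed_form_hill(conc, 1000, 3.79e4, 1.5)))
    expect_equal(dl$Ka, dl0$Ka, tolerance = 1e-9)
    expect_equal(dl$n, dl0$n, tolerance = 1e-9)
  }
})

test_that("the double-log slope approaches 1 in the low-saturation limit", {
  # single-site Stern-Volmer data: (F0-F)/F = Ksv [Q] exactly, so n = 1
  ksv <- 1e4                       # Ksv * max[Q] = 0.1
  ts <- make_sv_series(Ksv = ksv)
  fit <- fit_double_log(ts)
  expect_lt(abs(fit$n - 1), 0.02)
})

test_that("mechanism classification covers the criteria truth table", {
  mk <- function(ksv, kq) {
    tibble::tibble(temperature_K = c(298, 308), Ksv = ksv, Kq = kq)
  }
  expect_identical(
    classify_quenching_mechanism(mk(c(1.21e5, 0.41e5), c(1.21e13, 0.41e13)))$mechanism,
    "static")
  expect_identical(
    classify_quenching_mechanism(mk(c(50, 80), c(5e9, 8e9)))$mechanism,
    "dynamic")
  # conflicting criteria in every combination -> indeterminate
  expect_identical(
    classify_quenching_mechanism(mk(c(1e5, 2e5), c(1e13, 2e13)))$mechanism,
    "indeterminate")
  expect_identical(
    classify_quenching_mechanism(mk(c(2e5, 1e5), c(1e9, 5e8)))$mechanism,
    "indeterminate")
  expect_identical(
    classify_quenching_mechanism(mk(c(1e5, 1e5), c(1e13, 1e13)))$mechanism,
    "indeterminate")
  expect_identical(
    classify_quenching_mechanism(mk(c(2e5, 1e5), c(1e13, 1e9)))$mechanism,
    "indeterminate")
})

test_that("single-temperature classification falls back to Kq with a flag", {
  one <- tibble::tibble(temperature_K = 298, Ksv = 1.21e5, Kq = 1.21e13)
  expect_warning(call <- classify_quenching_mechanism(one), "single temperature")
  expect_identical(call$mechanism, "static")
  expect_true(call$single_temperature)
})

test_that("tidy and glance expose the fitted constants", {
  sv <- fit_stern_volmer(make_sv_series())
  td <- generics::tidy(sv)
  expect_identical(td$term, c("Ksv", "Kq", "intercept"))
  expect_equal(td$estimate[2], td$estimate[1] / sv$tau0)
  gl <- generics::glance(fit_double_log(make_hill_series()))
  expect_equal(gl$r.squared, 1, tolerance = 1e-9)
})
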