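# Noiseless titration on the standard 6-point grid at a given temperature,
# built directly from the closed-form quenching laws (independent of the
# package's own generators where a test needs an outside oracle).
closed_form_sv <- function(conc, F0, Ksv) F0 / (1 + Ksv * conc)
closed_form_hill <- function(conc, F0, Ka, n) {
  ifelse(conc == 0, F0, F0 / (1 + Ka * conc^n))
}

make_sv_series <- function(F0 = 1000, Ksv = 1.21e5, temperature_K = 298,
                           conc = default_conc_grid()) {
  titration_series(conc, closed_form_sv(conc, F0, Ksv),
                   temperature_K = temperature_K)
}

make_hill_series <- function(F0 = 1000, Ka = 3.79e4, n = 1.5,
                             temperature_K = 298, conc = default_conc_grid()) {
  titration_series(conc, closed_form_hill(conc, F0, Ka, n),
                   temperature_K = temperature_K)
}

gaussian_spectrum <- function(center = 340, sd = 25, amplitude = 1000,
                              wl = seq(290, 500, by = 1)) {
  emission_spectrum(wl, amplitude * exp(-(wl - center)^2 / (2 * sd^2)))
}
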