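# Shared fixtures built in code. All seeds fixed; nothing is read from disk.

fixture_models <- make_fixture_models(1L)

fixture_composite <- function(with_penicillin = FALSE) {
  comps <- list(fixture_models$water, fixture_models$MOPSH,
                fixture_models[["MOPS-"]])
  if (with_penicillin) comps <- c(comps, list(fixture_models$penicillinG))
  composite_model(comps)
}

quiet_noise <- function(seed = 1L) {
  noise_config(spectral_noise_sd = 0, reference_ph_sd = 0,
               laser_power_cv = 0, seed = seed)
}

# Exact calibration at the stated-world factor k = sigma_H / sigma_- = 0.996:
# two synthetic points lying exactly on conc_ratio = k * zeta_ratio.
exact_calibration <- function(composite = fixture_composite(), k = 0.996) {
  zr <- c(1, 2)
  calibrate(data.frame(zeta_ratio = zr,
                       reference_ph = pka_mops(308.15) + log10(k * zr),
                       temperature = 308.15),
            composite = composite)
}

expect_ph_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
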