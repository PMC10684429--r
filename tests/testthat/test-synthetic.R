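test_that("speciate splits total MOPS according to the pKa", {
  pka <- pka_mops(308.15)
  st <- speciate(0.05, pka, 308.15)
  expect_equal(st$c_mopsh, 0.025, tolerance = 1e-12)
  expect_equal(st$c_mops_minus, 0.025, tolerance = 1e-12)
  # one decade above the pKa: 10:1 split
  st1 <- speciate(0.05, pka + 1, 308.15)
  expect_equal(st1$c_mops_minus, 0.05 * 10 / 11, tolerance = 1e-12)
  expect_equal(st1$c_mopsh, 0.05 / 11, tolerance = 1e-12)
  st0 <- speciate(0, 7, 308.15)
  expect_equal(st0$c_mopsh + st0$c_mops_minus, 0)
})

test_that("titrate converts stoichiometrically and respects mass balance", {
  st <- buffer_state(0.05, 0.025, 0.025, 308.15, volume = 0.03)
  expect_identical(titrate(st, 0)$c_mopsh, st$c_mopsh)
  # 1.5e-4 mol NaOH in 30 mL of 25/25 mM: -> 20/30 mM, dpH = log10(30/20)
  up <- titrate(st, 1.5e-4)
  expect_equal(up$c_mopsh, 0.020, tolerance = 1e-12)
  expect_equal(up$c_mops_minus, 0.030, tolerance = 1e-12)
  expect_equal(up$true_ph - st$true_ph, log10(30 / 20), tolerance = 1e-12)
  # acid goes the other way and over-titration errors
  down <- titrate(up, -1.5e-4)
  expect_equal(down$c_mopsh, st$c_mopsh, tolerance = 1e-12)
  expect_error(titrate(st, 1e-3), class = "goodph_validation_error")
  expect_error(titrate(st, -1e-3), class = "goodph_validation_error")
  # mass conservation through a long random walk, with dilution
  s <- st
  withr::with_seed(3, {
    for (i in 1:50) {
      mol <- runif(1, -0.2, 0.2) * s$c_mopsh * s$volume
      mol <- max(min(mol, s$c_mopsh * s$volume), -s$c_mops_minus * s$volume)
      s <- titrate(s, mol, added_volume = 1e-5)
    }
  })
  expect_equal(s$c_mopsh + s$c_mops_minus, s$total_mops, tolerance = 1e-12)
})

test_that("charge_balance_ph reproduces textbook limits", {
  expect_equal(charge_balance_ph(0, 0, 0, 298.15), 7.0, tolerance = 1e-3)
  # 50 mM strong base alone: pH = 14 + log10(0.05)
  expect_equal(charge_balance_ph(0, 0.05, 0, 298.15), 12.699, tolerance = 1e-3)
  # half-neutralized buffer sits at the pKa
  expect_equal(charge_balance_ph(0.05, 0.025, 0, 308.15), pka_mops(308.15),
               tolerance = 0.01)
})

test_that("add_salt raises ionic strength without moving the speciation", {
  st <- buffer_state(0.05, 0.025, 0.025, 308.15, volume = 0.03)
  expect_equal(add_salt(st, 0)$ionic_strength, st$ionic_strength)
  salted <- add_salt(st, 0.003)   # 100 mM NaCl into 30 mL
  # 0.1 (NaCl) + 0.025 (MOPS-/Na+): hand sum of (1/2) sum c z^2
  expect_equal(salted$ionic_strength, 0.125, tolerance = 1e-3)
  expect_equal(salted$true_ph, st$true_ph, tolerance = 1e-12)
  expect_lt(attr(salted, "ph_activity"), salted$true_ph)
})

test_that("the 31-addition salt series reaches ~1.1 M ionic strength", {
  sim <- simulate_salt_series(7.0, fixture_models, quiet_noise(5))
  expect_length(sim$series, 32L)                 # initial + 31 additions
  expect_equal(sum(diff(sim$truth$ionic_strength) > 0), 31L)
  expect_gt(max(sim$truth$ionic_strength), 1.0)
  expect_lt(max(sim$truth$ionic_strength), 1.3)
  # the first 12 steps are five times smaller than the rest
  di <- diff(sim$truth$ionic_strength)
  expect_lt(mean(di[1:12]) * 4, mean(di[13:31]))
  expect_equal(sd(sim$truth$true_ph), 0, tolerance = 1e-12)
})

test_that("fixture tables honour the pH-sensitive band assignments", {
  for (seed in c(1L, 7L, 123L)) {
    tabs <- make_fixture_models(seed)
    pd <- tabs[["MOPS-"]]$peaks$position
    pp <- tabs$MOPSH$peaks$position
    expect_true(any(pd >= 2718 & pd <= 2738))    # grows with pH
    expect_true(any(pd >= 2950 & pd <= 2965))
    expect_true(any(pp >= 2990 & pp <= 3030))    # shrinks with pH
    # water bands are broad and centred outside the fit window
    expect_true(all(tabs$water$peaks$position > 3100))
    expect_true(all(tabs$water$peaks$fwhm > 150))
    expect_false(is.null(tabs$water$free_parameters))
  }
  expect_equal(make_fixture_models(9L), make_fixture_models(9L))
})

test_that("synthesize_spectrum is the exact forward model at zero noise", {
  st <- speciate(0.05, 7.2, 308.15)
  sp <- synthesize_spectrum(st, fixture_models, quiet_noise())
  sig <- default_cross_sections()
  grid <- default_grid()
  wpk <- goodph:::perturb_water(fixture_models$water$peaks, st$temperature,
                                st$ionic_strength)
  manual <- sig[["water"]] * 55.345 * goodph:::eval_peak_table(wpk, grid) +
    sig[["MOPSH"]] * st$c_mopsh * eval_component(fixture_models$MOPSH, grid) +
    sig[["MOPS-"]] * st$c_mops_minus *
      eval_component(fixture_models[["MOPS-"]], grid) +
    0.05 + 1e-5 * (grid - 2505)
  expect_equal(sp$intensity, manual, tolerance = 1e-12)
  # determinism under a fixed seed
  nz <- noise_config(seed = 99)
  a <- synthesize_spectrum(st, fixture_models, nz)
  b <- synthesize_spectrum(st, fixture_models, nz)
  expect_identical(a$intensity, b$intensity)
  expect_error(
    synthesize_spectrum(st, fixture_models[c("water", "MOPSH")], nz),
    class = "goodph_validation_error")
})

test_that("pH sweep reproduces the band increase/decrease pattern", {
  grid <- default_grid()
  band <- function(sp, lo, hi) {
    keep <- grid >= lo & grid <= hi
    sum(sp$intensity[keep])
  }
  sweeps <- lapply(seq(6, 8, length.out = 7), function(ph) {
    synthesize_spectrum(speciate(0.05, ph, 308.15), fixture_models,
                        quiet_noise())
  })
  grow <- vapply(sweeps, band, numeric(1), 2765, 2938)
  shrink <- vapply(sweeps, band, numeric(1), 2990, 3030)
  expect_true(all(diff(grow) > 0))
  expect_true(all(diff(shrink) < 0))
})

test_that("titration series matches its design and is seed-stable", {
  nz <- noise_config(seed = 21)
  sim <- simulate_titration_series(titration_plan(), fixture_models, nz)
  expect_length(sim$series, 60L)                 # 3 runs x 20 points
  expect_equal(nrow(sim$truth), 60L)
  expect_equal(range(sim$truth$true_ph), c(6, 8))
  expect_equal(unique(sim$truth$temperature), 308.15)
  sim2 <- simulate_titration_series(titration_plan(), fixture_models, nz)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$series$spectra[[13]]$intensity,
                   sim2$series$spectra[[13]]$intensity)
})

test_that("enzyme simulation is monotone with conserved buffer", {
  sim <- simulate_enzyme_reaction(models = fixture_models,
                                  noise = quiet_noise(4), record_every = 300)
  tr <- sim$truth
  expect_false(sim$truncated)
  expect_true(all(diff(tr$true_ph) <= 0))
  expect_true(all(diff(tr$substrate) <= 0))
  expect_true(all(tr$substrate >= 0))
  expect_equal(tr$c_mopsh + tr$c_mops_minus, rep(0.05, nrow(tr)),
               tolerance = 1e-12)
  # vmax -> 0 keeps the pH flat
  kin0 <- kinetics_config(vmax = 1e-15, duration = 600, dt = 5)
  flat <- simulate_enzyme_reaction(kin0, models = fixture_models,
                                   noise = quiet_noise(4), record_every = 300)
  expect_equal(sd(flat$truth$true_ph), 0, tolerance = 1e-9)
})

test_that("buffer exhaustion truncates and flags the series", {
  kin <- kinetics_config(vmax = 5e-5, km = 0.005, s0 = 0.06,
                         duration = 120000, dt = 10)
  sim <- simulate_enzyme_reaction(kin, initial = speciate(0.05, 7.2, 298.15),
                                  models = fixture_models,
                                  noise = quiet_noise(4), record_every = 6000)
  expect_true(sim$truncated)
  expect_true(all(sim$truth$c_mops_minus > 0))
})
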