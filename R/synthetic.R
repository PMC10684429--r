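# Synthetic-data generator: fixture peak tables, forward spectral synthesis
# and simulated experiments (titration, salt series, enzyme reaction) with
# known chemical ground truth. Everything is deterministic under a seed.

#' Noise model for synthetic spectra
#'
#' @param spectral_noise_sd Gaussian noise standard deviation as a fraction
#'   of the maximum clean intensity. Default 0.005 (0.5%), representing a
#'   180 s accumulated acquisition; scale by `sqrt(3)` for 60 s.
#' @param reference_ph_sd Standard deviation of the simulated reference
#'   electrode reading, pH levels (the physical electrode is specified to
#'   about +-0.05).
#' @param laser_power_cv Coefficient of variation of a per-spectrum global
#'   intensity scale factor (log-normal), emulating laser power / focus
#'   fluctuation that the ratiometric evaluation must cancel.
#' @param seed Integer seed; must be set explicitly.
#' @return A `noise_config`.
#' @export
noise_config <- function(spectral_noise_sd = 0.005, reference_ph_sd = 0.02,
                         laser_power_cv = 0.05, seed) {
  if (missing(seed) || is.null(seed)) {
    gp_validation_error("noise_config requires an explicit seed")
  }
  assert_scalar_number(spectral_noise_sd, "spectral_noise_sd", lower = 0)
  assert_scalar_number(reference_ph_sd, "reference_ph_sd", lower = 0)
  assert_scalar_number(laser_power_cv, "laser_power_cv", lower = 0)
  structure(list(spectral_noise_sd = spectral_noise_sd,
                 reference_ph_sd = reference_ph_sd,
                 laser_power_cv = laser_power_cv,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Michaelis-Menten kinetics configuration for the enzyme scenario
#'
#' Defaults emulate the penicillin amidase hydrolysis of 50 mM penicillin G
#' in 50 mM MOPS: starting near pH 8.2, the pH falls to about 6.8 over
#' roughly 4.2 hours.
#'
#' @param vmax Maximum reaction rate, mol/(L s).
#' @param km Michaelis constant, mol/L.
#' @param s0 Initial penicillin G concentration, mol/L.
#' @param duration Simulated time, s.
#' @param dt Integrator step, s.
#' @return A `kinetics_config`.
#' @export
kinetics_config <- function(vmax = 3.2e-6, km = 0.02, s0 = 0.05,
                            duration = 15000, dt = 5) {
  for (nm in c("vmax", "km", "s0", "duration", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      gp_validation_error(sprintf("'%s' must be a single positive number", nm))
    }
  }
  if (dt >= duration) gp_validation_error("dt must be smaller than duration")
  structure(list(vmax = vmax, km = km, s0 = s0, duration = duration, dt = dt),
            class = "kinetics_config")
}

#' Default wavenumber grid of the simulated instrument
#'
#' 2505-3825 cm^-1 at 1 cm^-1 spacing (the recorded range); hard-model
#' fitting uses the 2700-3100 cm^-1 window of this grid.
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(2505, 3825, by = 1)

#' Default Raman scattering cross-sections of the fixture world
#'
#' Arbitrary units chosen so that 50 mM MOPS bands are a sizeable fraction
#' of the water envelope inside the fit window. The protonated/deprotonated
#' ratio is 0.996 — the stated-world value of the ratiometric calibration
#' factor, reflecting the near-identical molecular structures of the two
#' species.
#' @return Named numeric vector over `water`, `MOPSH`, `MOPS-`,
#'   `penicillinG`.
#' @export
default_cross_sections <- function() {
  c(water = 1 / 55.345, "MOPSH" = 9.96, "MOPS-" = 10, penicillinG = 10)
}

# molarity of (nearly) pure water, mol/L
WATER_CONC <- 55.345

#' Generate fixture pure-component peak tables
#'
#' Deterministic under `seed`. The water model has two broad bands (near
#' 3230 and 3420 cm^-1, FWHM 200-280 cm^-1) whose low-wavenumber tails reach
#' the 2700-3100 cm^-1 fit window; its position and linewidth are declared
#' free. The MOPS- table always places peaks inside the bands that grow with
#' pH (2718-2738, 2765-2938, 2950-2965 cm^-1) and the MOPSH table inside the
#' bands that shrink (2938-2950, 2965-2982, 2990-3030 cm^-1), with partial
#' overlap between the species so the mixture fit is non-trivial. The
#' penicillin G table overlaps both (aliphatic C-H near 2900, aromatic C-H
#' near 3060 cm^-1). Peak counts are smaller than a real hard model would
#' use; each component's maximum intensity is normalized to 1.
#'
#' @param seed Integer seed.
#' @return Named list of [pure_component_model()] objects: `water` (free
#'   position/linewidth), `MOPSH`, `MOPS-`, `penicillinG`.
#' @export
make_fixture_models <- function(seed = 1L) {
  with_seed(derive_seed(seed, 11L), {
    jit <- function(x, frac) x * exp(stats::runif(length(x), -frac, frac))
    eta <- function(n) stats::runif(n, 0.3, 0.7)
    inside <- function(lo, hi) stats::runif(1, lo, hi)

    water <- data.frame(
      height = jit(c(0.85, 1.0), 0.05),
      position = c(3230, 3420) + stats::runif(2, -3, 3),
      fwhm = jit(c(220, 260), 0.05),
      eta = stats::runif(2, 0.55, 0.75))

    mops_d <- data.frame(    # deprotonated: bands that grow with pH
      height = jit(c(0.35, 0.55, 0.90, 0.65, 0.50, 0.70), 0.1),
      position = c(inside(2722, 2734), inside(2790, 2820), inside(2858, 2878),
                   inside(2898, 2918), inside(2952, 2963), inside(2878, 2895)),
      fwhm = jit(c(14, 34, 26, 22, 11, 20), 0.1),
      eta = eta(6))

    mops_h <- data.frame(    # protonated: bands that shrink with pH
      height = jit(c(0.55, 0.50, 0.75, 0.60, 0.90), 0.1),
      position = c(inside(2845, 2865), inside(2905, 2920), inside(2940, 2949),
                   inside(2967, 2980), inside(2995, 3025)),
      fwhm = jit(c(30, 24, 10, 12, 24), 0.1),
      eta = eta(5))

    pen_g <- data.frame(     # superimposes both MOPS species
      height = jit(c(0.45, 0.60, 0.50, 0.40, 0.90), 0.1),
      position = c(inside(2868, 2885), inside(2928, 2942), inside(2955, 2968),
                   inside(2998, 3012), inside(3058, 3072)),
      fwhm = jit(c(26, 18, 14, 18, 20), 0.1),
      eta = eta(5))

    normalize <- function(pk) {
      grid <- default_grid()
      pk$height <- pk$height / max(eval_peak_table(pk, grid))
      pk
    }
    list(
      water = free_water_parameters(
        pure_component_model("water", normalize(water))),
      MOPSH = pure_component_model("MOPSH", normalize(mops_h)),
      "MOPS-" = pure_component_model("MOPS-", normalize(mops_d)),
      penicillinG = pure_component_model("penicillinG", normalize(pen_g)))
  })
}

# Water band response to temperature and ionic strength: small linear
# perturbations (position +0.05 cm^-1/K from 308.15 K; linewidth +0.1% per
# 100 mM ionic strength), exercising the free water parameters of the fit.
perturb_water <- function(water_peaks, temperature, ionic_strength) {
  water_peaks$position <- water_peaks$position + 0.05 * (temperature - 308.15)
  water_peaks$fwhm <- water_peaks$fwhm * (1 + 0.001 * ionic_strength / 0.1)
  water_peaks
}

#' Synthesize a Raman spectrum from a buffer state
#'
#' Forward model: clean intensity is the cross-section-weighted sum of the
#' component tables at the state's concentrations (water at 55.345 mol/L,
#' its peaks perturbed by temperature and ionic strength) plus a linear
#' baseline; the whole spectrum is multiplied by a log-normal per-spectrum
#' scale factor (laser-power fluctuation) and Gaussian noise is added with
#' standard deviation `spectral_noise_sd` times the maximum intensity.
#' Deterministic under the noise seed. With all noise terms zero the output
#' equals the corresponding [eval_mixture()] evaluation exactly.
#'
#' @param state A [buffer_state()].
#' @param models Fixture models from [make_fixture_models()] (must contain
#'   `water`, `MOPSH`, `MOPS-`; `penicillinG` only when
#'   `penicillin_conc > 0`).
#' @param noise A [noise_config()].
#' @param penicillin_conc Penicillin G concentration, mol/L.
#' @param cross_sections Named cross-sections, see
#'   [default_cross_sections()].
#' @param grid Wavenumber grid.
#' @param baseline `c(intercept, slope_per_cm1)` of the synthetic baseline
#'   (slope applied to `grid - 2505`).
#' @return A [raman_spectrum()] carrying the state's temperature and true pH
#'   (as `reference_ph` the *true* value; simulated noisy electrode readings
#'   are handled by the experiment-level simulators).
#' @export
synthesize_spectrum <- function(state, models, noise,
                                penicillin_conc = 0,
                                cross_sections = default_cross_sections(),
                                grid = default_grid(),
                                baseline = c(0.05, 1e-5)) {
  if (!inherits(state, "buffer_state")) {
    gp_validation_error("state must be a buffer_state")
  }
  if (!inherits(noise, "noise_config")) {
    gp_validation_error("noise must be a noise_config")
  }
  need <- c("water", "MOPSH", "MOPS-")
  if (penicillin_conc > 0) need <- c(need, "penicillinG")
  missing_tbl <- setdiff(need, names(models))
  if (length(missing_tbl) > 0L) {
    gp_validation_error(sprintf("missing species table(s): %s",
                                paste(missing_tbl, collapse = ", ")))
  }
  wpk <- perturb_water(models$water$peaks, state$temperature,
                       state$ionic_strength)
  clean <- cross_sections[["water"]] * WATER_CONC * eval_peak_table(wpk, grid) +
    cross_sections[["MOPSH"]] * state$c_mopsh *
      eval_peak_table(models$MOPSH$peaks, grid) +
    cross_sections[["MOPS-"]] * state$c_mops_minus *
      eval_peak_table(models[["MOPS-"]]$peaks, grid) +
    baseline[1L] + baseline[2L] * (grid - 2505)
  if (penicillin_conc > 0) {
    clean <- clean + cross_sections[["penicillinG"]] * penicillin_conc *
      eval_peak_table(models$penicillinG$peaks, grid)
  }
  y <- with_seed(noise$seed, {
    scale <- if (noise$laser_power_cv > 0) {
      sdlog <- sqrt(log(1 + noise$laser_power_cv^2))
      exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    } else 1
    out <- scale * clean
    if (noise$spectral_noise_sd > 0) {
      out <- out + stats::rnorm(length(grid), 0,
                                noise$spectral_noise_sd * max(out))
    }
    out
  })
  raman_spectrum(grid, y, temperature = state$temperature,
                 reference_ph = state$true_ph,
                 label = sprintf("synthetic pH %.3f", state$true_ph))
}

#' Titration experiment plan
#'
#' The default mirrors the probe's calibration design: three identical runs
#' of 20 points each, pH rising from 6 to 8 at 35 degC (308.15 K) in 30 mL
#' of 50 mM MOPS — 60 data points in total.
#'
#' @param runs Number of runs.
#' @param points_per_run Spectra per run.
#' @param ph_range `c(lo, hi)` pH span of each run.
#' @param temperature Kelvin.
#' @param total_mops Total MOPS concentration, mol/L.
#' @param volume Sample volume, litres.
#' @return A `titration_plan`.
#' @export
titration_plan <- function(runs = 3L, points_per_run = 20L,
                           ph_range = c(6, 8), temperature = 308.15,
                           total_mops = 0.05, volume = 0.03) {
  assert_scalar_number(runs, "runs", lower = 1)
  assert_scalar_number(points_per_run, "points_per_run", lower = 1)
  if (length(ph_range) != 2L || ph_range[1L] >= ph_range[2L]) {
    gp_validation_error("ph_range must be c(lo, hi) with lo < hi")
  }
  assert_temperature(temperature)
  structure(list(runs = as.integer(runs),
                 points_per_run = as.integer(points_per_run),
                 ph_range = as.double(ph_range), temperature = temperature,
                 total_mops = total_mops, volume = volume),
            class = "titration_plan")
}

#' Simulate a titration series with synthetic spectra and ground truth
#'
#' For each run and pH set-point, speciates the buffer, synthesizes a noisy
#' spectrum, and records both the true pH and a noisy reference-electrode
#' reading (`true + N(0, reference_ph_sd)`). All randomness derives from the
#' noise seed; per-spectrum child seeds keep runs reproducible and
#' independent.
#'
#' @param plan A [titration_plan()].
#' @param models Fixture models from [make_fixture_models()].
#' @param noise A [noise_config()].
#' @param penicillin_conc Optional constant penicillin G concentration added
#'   to every sample (spectral superimposition scenario), mol/L.
#' @return List with `series` (a [spectrum_series()], spectra carrying the
#'   *noisy* reference pH in their metadata) and `truth` (data frame: `run`,
#'   `point`, `true_ph`, `reference_ph`, `temperature`, `ionic_strength`,
#'   `c_mopsh`, `c_mops_minus`).
#' @export
simulate_titration_series <- function(plan = titration_plan(), models,
                                      noise, penicillin_conc = 0) {
  if (!inherits(plan, "titration_plan")) {
    gp_validation_error("plan must be a titration_plan")
  }
  ph_values <- seq(plan$ph_range[1L], plan$ph_range[2L],
                   length.out = plan$points_per_run)
  spectra <- list()
  rows <- list()
  idx <- 0L
  for (run in seq_len(plan$runs)) {
    for (j in seq_len(plan$points_per_run)) {
      idx <- idx + 1L
      st <- speciate(plan$total_mops, ph_values[j], plan$temperature,
                     volume = plan$volume)
      child <- noise
      child$seed <- derive_seed(noise$seed, idx)
      sp <- synthesize_spectrum(st, models, child,
                                penicillin_conc = penicillin_conc)
      ref <- with_seed(derive_seed(noise$seed, 500000L + idx),
                       st$true_ph + stats::rnorm(1, 0, noise$reference_ph_sd))
      sp$reference_ph <- ref
      sp$label <- sprintf("run%d_point%02d", run, j)
      spectra[[idx]] <- sp
      rows[[idx]] <- data.frame(
        run = run, point = j, true_ph = st$true_ph, reference_ph = ref,
        temperature = st$temperature, ionic_strength = st$ionic_strength,
        c_mopsh = st$c_mopsh, c_mops_minus = st$c_mops_minus)
    }
  }
  list(series = spectrum_series(spectra, label = "titration"),
       truth = do.call(rbind, rows))
}

#' Simulate an ionic-strength (NaCl) series
#'
#' Starting from 50 mM MOPS at a preset pH, performs 31 NaCl additions (the
#' first 12 five times smaller than the remaining 19) raising the ionic
#' strength to roughly 1.1 mol/L, with one synthetic spectrum per step.
#' The concentration-based speciation — and hence the true pH the probe
#' should report — is unchanged by the salt; the activity-corrected pH is
#' recorded alongside to quantify the neglected effect.
#'
#' @param start_ph Initial pH (the physical study used 6.3, 7.0 and 7.7).
#' @param models,noise As in [simulate_titration_series()].
#' @param temperature Kelvin.
#' @param n_small,n_large Number of small and large additions.
#' @param small_mol Moles of NaCl per small addition (large additions are
#'   5x).
#' @return List with `series` and `truth` (`step`, `true_ph`,
#'   `ph_activity`, `ionic_strength`, ...).
#' @export
simulate_salt_series <- function(start_ph = 7.0, models, noise,
                                 temperature = 308.15, n_small = 12L,
                                 n_large = 19L, small_mol = 3.7e-4) {
  st <- speciate(0.05, start_ph, temperature, volume = 0.03)
  additions <- c(rep(small_mol, n_small), rep(small_mol * 5, n_large))
  spectra <- list(); rows <- list()
  record <- function(step, st) {
    child <- noise
    child$seed <- derive_seed(noise$seed, step + 1L)
    sp <- synthesize_spectrum(st, models, child)
    ref <- with_seed(derive_seed(noise$seed, 600000L + step),
                     st$true_ph + stats::rnorm(1, 0, noise$reference_ph_sd))
    sp$reference_ph <- ref
    pa <- attr(st, "ph_activity")
    list(sp = sp,
         row = data.frame(step = step, true_ph = st$true_ph,
                          ph_activity = if (is.null(pa)) st$true_ph else pa,
                          reference_ph = ref,
                          ionic_strength = st$ionic_strength,
                          temperature = st$temperature))
  }
  rec <- record(0L, st)
  spectra[[1L]] <- rec$sp; rows[[1L]] <- rec$row
  for (i in seq_along(additions)) {
    st <- add_salt(st, additions[i], added_volume = additions[i] / 6)
    rec <- record(i, st)
    spectra[[i + 1L]] <- rec$sp; rows[[i + 1L]] <- rec$row
  }
  list(series = spectrum_series(spectra, label = "salt"),
       truth = do.call(rbind, rows))
}

#' Simulate the enzyme-reaction pH decay
#'
#' Integrates Michaelis-Menten substrate consumption
#' `dS/dt = -vmax S/(km + S)` with classical fourth-order Runge-Kutta.
#' Each mole of substrate hydrolyzed releases one effective proton (the
#' newly formed phenylacetic acid carboxyl; the second product's carboxyl
#' was already deprotonated in this pH range), converting MOPS- to MOPSH
#' mole for mole. The pH trajectory follows from the concentration-based
#' Henderson-Hasselbalch relation and is monotone non-increasing. If the
#' deprotonated buffer would be exhausted the series is truncated and
#' flagged.
#'
#' @param kin A [kinetics_config()].
#' @param initial A [buffer_state()]; default 50 mM MOPS at pH 8.2, 25 degC.
#' @param models,noise As in [simulate_titration_series()]; pass
#'   `noise_config(spectral_noise_sd = 0.005 * sqrt(3), ...)` to emulate the
#'   shorter 60 s acquisitions used for kinetic monitoring.
#' @param record_every Interval between recorded spectra, s.
#' @return List with `series`, `truth` (`time`, `true_ph`, `reference_ph`,
#'   `substrate`, `c_mopsh`, `c_mops_minus`, `temperature`), and `truncated`
#'   flag.
#' @export
simulate_enzyme_reaction <- function(kin = kinetics_config(),
                                     initial = speciate(0.05, 8.2, 298.15),
                                     models, noise, record_every = 60) {
  if (!inherits(kin, "kinetics_config")) {
    gp_validation_error("kin must be a kinetics_config")
  }
  pka <- pka_mops(initial$temperature)
  if (abs(initial$true_ph - pka) > 1.3 + 1e-9 &&
      initial$true_ph < pka) {
    gp_validation_error("initial pH below the working range")
  }
  n_steps <- ceiling(kin$duration / kin$dt)
  times <- seq(0, by = kin$dt, length.out = n_steps + 1L)
  s <- numeric(n_steps + 1L)
  s[1L] <- kin$s0
  rate <- function(S) -kin$vmax * S / (kin$km + S)
  for (i in seq_len(n_steps)) {
    h <- kin$dt
    k1 <- rate(s[i])
    k2 <- rate(s[i] + h / 2 * k1)
    k3 <- rate(s[i] + h / 2 * k2)
    k4 <- rate(s[i] + h * k3)
    s[i + 1L] <- max(s[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  x <- kin$s0 - s                      # cumulative acid released
  truncated <- FALSE
  keep_n <- n_steps + 1L
  if (any(x >= initial$c_mops_minus)) {
    truncated <- TRUE
    keep_n <- which(x >= initial$c_mops_minus)[1L] - 1L
  }
  rec_idx <- which(times %% record_every == 0)
  rec_idx <- rec_idx[rec_idx <= keep_n]
  spectra <- list(); rows <- list()
  for (j in seq_along(rec_idx)) {
    i <- rec_idx[j]
    st <- buffer_state(
      total_mops = initial$total_mops,
      c_mopsh = initial$c_mopsh + x[i],
      c_mops_minus = initial$c_mops_minus - x[i],
      temperature = initial$temperature, volume = initial$volume,
      c_na = initial$c_na, c_cl = initial$c_cl)
    child <- noise
    child$seed <- derive_seed(noise$seed, j)
    sp <- synthesize_spectrum(st, models, child, penicillin_conc = s[i])
    ref <- with_seed(derive_seed(noise$seed, 700000L + j),
                     st$true_ph + stats::rnorm(1, 0, noise$reference_ph_sd))
    sp$reference_ph <- ref
    sp$label <- sprintf("t=%gs", times[i])
    spectra[[j]] <- sp
    rows[[j]] <- data.frame(
      time = times[i], true_ph = st$true_ph, reference_ph = ref,
      substrate = s[i], c_mopsh = st$c_mopsh, c_mops_minus = st$c_mops_minus,
      temperature = st$temperature)
  }
  list(series = spectrum_series(spectra, label = "enzyme",
                                timestamps = times[rec_idx]),
       truth = do.call(rbind, rows),
       truncated = truncated)
}
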