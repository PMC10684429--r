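# Canonical component names used by the pH probe throughout the package.
MOPS_PROT <- "MOPSH"
MOPS_DEPROT <- "MOPS-"

#' Temperature-dependent pKa of MOPS
#'
#' Empirical correlation (Roy-type):
#' \deqn{pK_a(T) = 814.077/T + 9.865 - 0.9501\,\ln T}
#' with `T` in kelvin and a natural logarithm. Strictly decreasing over the
#' biologically relevant range (about 7.31 at 15 degC, 7.18 at 25 degC,
#' 7.06 at 35 degC).
#'
#' @param temperature Temperature in kelvin, within `[273.15, 373.15]`;
#'   vectorized.
#' @return The pKa (dimensionless, pH levels).
#' @export
pka_mops <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) == 0L ||
      any(!is.finite(temperature)) ||
      any(temperature < 273.15) || any(temperature > 373.15)) {
    gp_validation_error("temperature must be finite kelvin in [273.15, 373.15]")
  }
  814.077 / temperature + 9.865 - 0.9501 * log(temperature)
}

#' pH from the MOPS concentration ratio (and back)
#'
#' Henderson-Hasselbalch on a concentration basis: the pH equals the
#' temperature-dependent pKa plus the decadic logarithm of the
#' deprotonated-to-protonated concentration ratio. The activity-coefficient
#' ratio of the two species is taken as 1 (a neutral and a singly charged
#' species), which is exactly the assumption that makes the probe
#' calibration-light; its cost is quantified separately by
#' [activity_corrected_ph()].
#'
#' @param conc_ratio `c(MOPS-)/c(MOPSH)`, `> 0`.
#' @param ph pH value.
#' @param temperature Temperature in kelvin.
#' @return `ph_from_ratio()` returns the pH; `ratio_from_ph()` its exact
#'   inverse, the concentration ratio `10^(ph - pKa(T))`.
#' @export
ph_from_ratio <- function(conc_ratio, temperature) {
  if (!is.numeric(conc_ratio) || any(!is.finite(conc_ratio)) || any(conc_ratio <= 0)) {
    gp_validation_error("conc_ratio must be > 0")
  }
  pka_mops(temperature) + log10(conc_ratio)
}

#' @rdname ph_from_ratio
#' @export
ratio_from_ph <- function(ph, temperature) {
  if (!is.numeric(ph) || any(!is.finite(ph))) {
    gp_validation_error("ph must be finite")
  }
  10^(ph - pka_mops(temperature))
}

#' Ratiometric calibration of the pH probe
#'
#' Fits the single calibration factor `k` in
#' `conc_ratio = k * zeta_ratio`, where `zeta_ratio` is the fitted
#' MOPS-/MOPSH weight ratio of each calibration spectrum and `conc_ratio`
#' is computed from the reference pH via [ratio_from_ph()]. `k` is the
#' least-squares slope through the origin; physically it is the ratio of
#' the two species' Raman scattering cross-sections and is expected to be
#' close to 1.
#'
#' @param points Data frame with columns `zeta_ratio`, `reference_ph`,
#'   `temperature` (kelvin); one row per calibration spectrum. At least 2
#'   rows.
#' @param composite Optional [composite_model()] reference stored with the
#'   calibration (required by [predict_ph()]).
#' @param weighted If `TRUE`, weight each point by the inverse variance of
#'   its concentration ratio propagated from a reference-electrode error of
#'   `sigma_ref` pH levels (the fluctuation of the concentration ratio
#'   grows exponentially with pH). Default unweighted.
#' @param sigma_ref Reference electrode standard error used for the
#'   weighted variant, pH levels.
#' @return A `calibration_model` with fields `k`, `composite`, `points`,
#'   `created_at`.
#' @export
calibrate <- function(points, composite = NULL, weighted = FALSE,
                      sigma_ref = 0.05) {
  points <- as.data.frame(points)
  need <- c("zeta_ratio", "reference_ph", "temperature")
  if (!all(need %in% names(points))) {
    gp_validation_error("points needs columns zeta_ratio, reference_ph, temperature")
  }
  if (nrow(points) < 2L) {
    gp_validation_error("calibration requires at least 2 points")
  }
  if (any(!is.finite(points$zeta_ratio)) || any(points$zeta_ratio <= 0)) {
    gp_validation_error("all zeta ratios must be finite and > 0 (zeta_MOPSH > 0)")
  }
  points$conc_ratio <- mapply(ratio_from_ph, points$reference_ph,
                              points$temperature)
  w <- if (weighted) {
    # var(conc_ratio) ~ (ln 10 * conc_ratio * sigma_ref)^2
    1 / (log(10) * points$conc_ratio * sigma_ref)^2
  } else {
    rep(1, nrow(points))
  }
  k <- sum(w * points$conc_ratio * points$zeta_ratio) /
    sum(w * points$zeta_ratio^2)
  structure(list(k = k, composite = composite, points = points,
                 weighted = weighted, created_at = format(Sys.time(), tz = "UTC")),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> k = %.6g (%s, %d points)\n",
              x$k, if (x$weighted) "weighted" else "unweighted",
              nrow(x$points)))
  invisible(x)
}

#' Predict pH from a Raman spectrum
#'
#' The measurement core of the probe: fits the calibrated composite hard
#' model to the spectrum, forms the MOPS-/MOPSH weight ratio, converts it to
#' a concentration ratio through the calibration factor, and applies
#' [ph_from_ratio()] with the pKa at the measurement temperature. The
#' prediction is ratiometric: invariant to uniform intensity scaling (laser
#' power, focus) and to any exact linear baseline, both absorbed by the fit.
#'
#' @param spectrum A [raman_spectrum()] covering the fit window.
#' @param calibration A [calibration_model()] whose `composite` contains the
#'   `"MOPSH"` and `"MOPS-"` components.
#' @param temperature Temperature in kelvin; defaults to the spectrum's
#'   metadata.
#' @return A `ph_prediction` with fields `ph`, `zeta_ratio`, `conc_ratio`,
#'   `pka`, `temperature`, `in_range` (FALSE when the implied pH leaves
#'   `pKa +- 1.3`, the effective MOPS working range), `converged`, `fit`.
#' @export
predict_ph <- function(spectrum, calibration, temperature = NULL) {
  if (!inherits(calibration, "calibration_model")) {
    gp_validation_error("calibration must be a calibration_model")
  }
  if (is.null(calibration$composite)) {
    gp_validation_error("calibration carries no composite model")
  }
  if (is.null(temperature)) temperature <- spectrum$temperature
  if (is.null(temperature)) {
    gp_validation_error("temperature missing (argument and spectrum metadata)")
  }
  assert_temperature(temperature)
  comps <- names(calibration$composite$components)
  if (!all(c(MOPS_PROT, MOPS_DEPROT) %in% comps)) {
    gp_validation_error("composite model must contain 'MOPSH' and 'MOPS-' components")
  }
  fit <- fit_mixture(calibration$composite, spectrum)
  z_d <- fit$weights[[MOPS_DEPROT]]
  z_p <- fit$weights[[MOPS_PROT]]
  if (z_p <= 1e-12 * max(z_d, 1e-300)) {
    gp_range_error("pH above working range: protonated MOPS weight is zero")
  }
  if (z_d <= 1e-12 * max(z_p, 1e-300)) {
    gp_range_error("pH below working range: deprotonated MOPS weight is zero")
  }
  zeta_ratio <- z_d / z_p
  conc_ratio <- calibration$k * zeta_ratio
  pka <- pka_mops(temperature)
  ph <- pka + log10(conc_ratio)
  structure(
    list(ph = ph, zeta_ratio = zeta_ratio, conc_ratio = conc_ratio,
         pka = pka, temperature = temperature,
         in_range = abs(ph - pka) <= 1.3,
         converged = fit$converged, fit = fit),
    class = "ph_prediction")
}

#' @export
print.ph_prediction <- function(x, ...) {
  cat(sprintf("<ph_prediction> pH = %.3f (T = %.2f K, pKa = %.4f)%s%s\n",
              x$ph, x$temperature, x$pka,
              if (x$in_range) "" else "  [OUT OF WORKING RANGE]",
              if (x$converged) "" else "  [fit not converged]"))
  invisible(x)
}

#' Fit every spectrum of a series and tabulate the MOPS weight ratios
#'
#' Convenience bridge between the simulator/reader and
#' [calibrate()]/[predict_ph()]: runs the mixture fit on each spectrum and
#' returns one row per spectrum with the weight ratio and metadata.
#'
#' @param series A [spectrum_series()].
#' @param composite A [composite_model()] containing the MOPS components.
#' @return Data frame with columns `zeta_ratio`, `reference_ph`,
#'   `temperature`, `converged`, `residual_rms`.
#' @export
evaluate_series <- function(series, composite) {
  if (!inherits(series, "spectrum_series")) {
    gp_validation_error("series must be a spectrum_series")
  }
  rows <- lapply(series$spectra, function(sp) {
    fit <- fit_mixture(composite, sp)
    z_p <- fit$weights[[MOPS_PROT]]
    data.frame(
      zeta_ratio = if (z_p > 0) fit$weights[[MOPS_DEPROT]] / z_p else NA_real_,
      reference_ph = if (is.null(sp$reference_ph)) NA_real_ else sp$reference_ph,
      temperature = if (is.null(sp$temperature)) NA_real_ else sp$temperature,
      converged = fit$converged,
      residual_rms = fit$residual_rms)
  })
  do.call(rbind, rows)
}

#' Root-mean-square error between predicted and reference pH
#'
#' @param predicted,reference Equal-length numeric vectors of pH values.
#' @return `sqrt(mean((predicted - reference)^2))`, pH levels.
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) == 0L) {
    gp_validation_error("predicted and reference must have equal non-zero length")
  }
  sqrt(mean((predicted - reference)^2))
}

#' Leave-one-out cross-validation of the ratiometric calibration
#'
#' For each calibration point, refits `k` on the remaining points, predicts
#' the held-out point's pH from its weight ratio, and returns the RMSE over
#' all points (RMSECV).
#'
#' @param points As in [calibrate()]; at least 3 rows.
#' @param weighted Passed through to [calibrate()].
#' @return The RMSECV in pH levels, with attribute `predictions`.
#' @export
loo_crossval <- function(points, weighted = FALSE) {
  points <- as.data.frame(points)
  if (nrow(points) < 3L) {
    gp_validation_error("leave-one-out cross-validation requires at least 3 points")
  }
  preds <- vapply(seq_len(nrow(points)), function(i) {
    cal <- calibrate(points[-i, , drop = FALSE], weighted = weighted)
    pka_mops(points$temperature[i]) +
      log10(cal$k * points$zeta_ratio[i])
  }, numeric(1))
  out <- rmse(preds, points$reference_ph)
  attr(out, "predictions") <- preds
  out
}

#' Extended Debye-Hueckel activity coefficient (decadic log)
#'
#' \deqn{\log_{10}\gamma = \frac{-A z^2 \sqrt I}{1 + B\sqrt I} + b I}
#' Empirical extension of Debye-Hueckel theory; `A` is
#' temperature-dependent, `B` reflects the ion radius, and `b` is an
#' empirical, component-specific correction. For a neutral species (z = 0)
#' only the `b I` term survives.
#'
#' @param A Debye-Hueckel limiting slope (about 0.51 for water at 25 degC).
#' @param z Integer charge of the species.
#' @param I Ionic strength, mol/L, `>= 0`.
#' @param B Ion-size parameter.
#' @param b Empirical linear coefficient.
#' @return `log10(gamma)`.
#' @export
debye_huckel_log_gamma <- function(A, z, I, B, b) {
  if (!is.numeric(I) || any(I < 0)) gp_validation_error("ionic strength must be >= 0")
  -A * z^2 * sqrt(I) / (1 + B * sqrt(I)) + b * I
}

#' Activity-corrected pH (diagnostic only)
#'
#' Quantifies the error committed by the unit-activity-ratio assumption of
#' the measurement path: adds `log10(gamma_MOPS-) - log10(gamma_MOPSH)` to a
#' concentration-based pH, with the deprotonated species carrying charge -1
#' and the protonated species neutral (its ionic term vanishes; only its
#' `b I` term can contribute). This correction is never applied inside
#' [predict_ph()]; it exists to study, in simulation, how large the
#' neglected effect would be at a given ionic strength.
#'
#' @param concentration_ph Concentration-based pH.
#' @param I Ionic strength, mol/L.
#' @param A,B Debye-Hueckel parameters for the deprotonated species.
#' @param b_deprot,b_prot Empirical linear coefficients of the two species.
#' @return The corrected pH.
#' @export
activity_corrected_ph <- function(concentration_ph, I, A = 0.51, B = 1.5,
                                  b_deprot = 0, b_prot = 0) {
  lg_d <- debye_huckel_log_gamma(A, -1L, I, B, b_deprot)
  lg_p <- debye_huckel_log_gamma(A, 0L, I, B, b_prot)
  concentration_ph + lg_d - lg_p
}
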