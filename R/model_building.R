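#' Configuration for pure-component peak fitting
#'
#' @param n_peaks Number of pseudo-Voigt peaks to fit, or `NULL` for
#'   automatic residual-driven peak addition.
#' @param max_iterations Maximum outer optimizer iterations per refit.
#' @param tolerance Relative residual improvement below which automatic peak
#'   addition stops.
#' @param residual_threshold Target root-mean-square residual as a fraction
#'   of the spectrum's maximum intensity.
#' @param seed Seed for any randomized restarts (the default scheme is
#'   deterministic; the seed is recorded for provenance).
#' @return A `peak_fit_config`.
#' @export
peak_fit_config <- function(n_peaks = NULL, max_iterations = 200L,
                            tolerance = 1e-6, residual_threshold = 1e-3,
                            seed = 1L) {
  if (!is.null(n_peaks)) {
    assert_scalar_number(n_peaks, "n_peaks", lower = 1, upper = 64)
    n_peaks <- as.integer(n_peaks)
  }
  assert_scalar_number(max_iterations, "max_iterations", lower = 1)
  if (tolerance <= 0) gp_validation_error("tolerance must be > 0")
  assert_scalar_number(residual_threshold, "residual_threshold", lower = 0)
  structure(list(n_peaks = n_peaks, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, residual_threshold = residual_threshold,
                 seed = as.integer(seed)),
            class = "peak_fit_config")
}

# Local maxima of y, strictly above both neighbours on at least one side,
# returned in descending height order.
detect_peak_positions <- function(nu, y, min_frac = 0.01) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  idx <- which(is_max & y > min_frac * max(y))
  idx[order(y[idx], decreasing = TRUE)]
}

# Initial peak table from detected maxima: FWHM = half the distance to the
# nearest neighbouring maximum (floor 4 cm^-1), Gaussian fraction 0.5.
init_peaks_from_maxima <- function(nu, y, idx) {
  pos <- nu[idx]
  fw <- vapply(seq_along(pos), function(i) {
    others <- pos[-i]
    if (length(others) == 0L) return(max((max(nu) - min(nu)) / 8, 4))
    max(min(abs(others - pos[i])) / 2, 4)
  }, numeric(1))
  data.frame(height = pmax(y[idx], 0), position = pos, fwhm = fw, eta = 0.5)
}

# Variable-projection fit of a set of pseudo-Voigt peaks, optionally jointly
# with a known component model (its weight and free parameters co-fitted)
# and a linear baseline. Peak heights, the known component's weight and the
# baseline are linear and solved inside each residual evaluation.
vp_peak_fit <- function(nu, y, peaks, known = NULL, baseline = FALSE,
                        config = peak_fit_config()) {
  k <- nrow(peaks)
  nu_c <- nu - mean(nu)
  span <- max(nu) - min(nu)

  theta <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  for (i in seq_len(k)) {
    theta <- c(theta, peaks$position[i], peaks$fwhm[i], peaks$eta[i])
    lo <- c(lo, min(nu), 1, 0)
    hi <- c(hi, max(nu), span, 1)
  }
  n_known_free <- 0L
  if (!is.null(known) && !is.null(known$free_parameters)) {
    fp <- known$free_parameters
    n_known_free <- nrow(fp)
    for (i in seq_len(n_known_free)) {
      theta <- c(theta, known$peaks[[fp$parameter[i]]][fp$peak[i]])
      lo <- c(lo, fp$lower[i]); hi <- c(hi, fp$upper[i])
    }
  }

  known_profile <- function(theta) {
    pk <- known$peaks
    if (n_known_free > 0L) {
      fp <- known$free_parameters
      off <- 3L * k
      for (i in seq_len(n_known_free)) {
        pk[[fp$parameter[i]]][fp$peak[i]] <- theta[off + i]
      }
    }
    eval_peak_table(pk, nu)
  }

  n_lin <- k + (!is.null(known)) + if (baseline) 2L else 0L
  last <- new.env(parent = emptyenv())
  resid_fn <- function(theta) {
    X <- matrix(0, nrow = length(nu), ncol = n_lin)
    for (i in seq_len(k)) {
      X[, i] <- pv_profile(nu, theta[3 * i - 2], theta[3 * i - 1], theta[3 * i])
    }
    col <- k
    if (!is.null(known)) {
      col <- col + 1L
      X[, col] <- known_profile(theta)
    }
    if (baseline) {
      X[, col + 1L] <- 1
      X[, col + 2L] <- nu_c
    }
    beta <- solve_linear_nonneg(X, y, nonneg_idx = seq_len(k + (!is.null(known))))
    last$beta <- beta
    as.numeric(X %*% beta - y)
  }

  res <- lm_minimize(theta, resid_fn, lo, hi, max_iter = config$max_iterations)
  r <- resid_fn(res$par)
  beta <- last$beta
  th <- res$par
  out_peaks <- data.frame(
    height = beta[seq_len(k)],
    position = th[seq(1, by = 3, length.out = k)],
    fwhm = th[seq(2, by = 3, length.out = k)],
    eta = th[seq(3, by = 3, length.out = k)])
  known_weight <- if (!is.null(known)) beta[k + 1L] else NA_real_
  bl <- c(0, 0)
  if (baseline) {
    b <- beta[(n_lin - 1L):n_lin]
    bl <- c(b[1L] - b[2L] * mean(nu), b[2L])
  }
  known_adjusted <- NULL
  if (n_known_free > 0L) {
    fp <- known$free_parameters
    known_adjusted <- data.frame(peak = fp$peak, parameter = fp$parameter,
                                 value = th[3L * k + seq_len(n_known_free)])
  }
  list(peaks = out_peaks, known_weight = known_weight,
       known_adjusted = known_adjusted, baseline = bl,
       residual = r, residual_rms = sqrt(mean(r^2)),
       fitted = y + r, converged = res$converged)
}

# Greedy residual-driven peak construction: fit the current peak set, then
# repeatedly add one peak at the residual's maximum and refit, until the
# target count (fixed mode) or the residual threshold / improvement
# tolerance (automatic mode) is reached.
greedy_peak_fit <- function(nu, y, config, known = NULL, baseline = FALSE,
                            residual_ref = max(abs(y))) {
  auto <- is.null(config$n_peaks)
  cap <- if (auto) 64L else config$n_peaks
  idx <- detect_peak_positions(nu, if (is.null(known)) y else pmax(y, 0))
  if (length(idx) == 0L) idx <- which.max(y)
  if (length(idx) > cap) idx <- idx[seq_len(cap)]
  peaks <- init_peaks_from_maxima(nu, y, idx)
  fit <- vp_peak_fit(nu, y, peaks, known = known, baseline = baseline,
                     config = config)
  repeat {
    n <- nrow(fit$peaks)
    if (n >= cap) break
    if (auto && fit$residual_rms <= config$residual_threshold * residual_ref) break
    r <- y - fit$fitted
    i_new <- which.max(r)
    if (r[i_new] <= 0) break
    cand <- rbind(fit$peaks,
                  data.frame(height = r[i_new], position = nu[i_new],
                             fwhm = 8, eta = 0.5))
    fit2 <- vp_peak_fit(nu, y, cand, known = known, baseline = baseline,
                        config = config)
    improvement <- (fit$residual_rms - fit2$residual_rms) /
      max(fit$residual_rms, .Machine$double.xmin)
    if (auto && improvement < config$tolerance) break
    fit <- fit2
  }
  fit
}

#' Build a pure-component model from a (pseudo-)pure spectrum
#'
#' Fits a sum of pseudo-Voigt peaks to a spectrum of a single component.
#' Peaks are initialized at detected local maxima (descending height, initial
#' FWHM half the distance to the nearest neighbouring maximum, Gaussian
#' fraction 0.5) and refined by variable-projection Levenberg-Marquardt;
#' with `n_peaks = NULL` additional peaks are added greedily at the
#' residual's maximum until the residual target is met.
#'
#' @param spectrum A [raman_spectrum()], already cropped to the fit window,
#'   with `max(intensity) > 0`.
#' @param config A [peak_fit_config()].
#' @param name Component name for the returned model.
#' @return A [pure_component_model()] whose `converged` attribute reports
#'   whether the residual target was met; `residual_rms` attribute carries
#'   the achieved root-mean-square residual.
#' @export
fit_pure_component <- function(spectrum, config = peak_fit_config(),
                               name = "component") {
  if (!inherits(spectrum, "raman_spectrum")) {
    gp_validation_error("spectrum must be a raman_spectrum")
  }
  y <- spectrum$intensity
  if (max(abs(y)) == 0) gp_validation_error("all-zero spectrum")
  fit <- greedy_peak_fit(spectrum$wavenumber, y, config,
                         residual_ref = max(y))
  keep <- fit$peaks$height > 0
  model <- pure_component_model(name, fit$peaks[keep, , drop = FALSE])
  attr(model, "residual_rms") <- fit$residual_rms
  attr(model, "converged") <-
    fit$residual_rms <= config$residual_threshold * max(y)
  model
}

#' Complemental hard modeling: extract a solute model from a binary spectrum
#'
#' Given the Raman spectrum of a binary aqueous solution and the known
#' component's model (water), jointly fits the known model's weight and free
#' parameters, a linear baseline, and a fresh set of pseudo-Voigt peaks for
#' the unknown solute, effectively subtracting the water contribution. New
#' peaks are added greedily at the residual's maximum.
#'
#' @param binary_spectrum A [raman_spectrum()] of known + one unknown
#'   component, cropped to the fit window.
#' @param known The known component's [pure_component_model()] (typically
#'   water, with position/linewidth free).
#' @param config A [peak_fit_config()]; `n_peaks`, if set, is the peak count
#'   for the unknown component.
#' @param name Name for the returned solute model.
#' @return A [pure_component_model()] for the unknown component. Attributes:
#'   `known_weight` (fitted weight of the known model), `baseline`,
#'   `known_adjusted` (fitted free parameters of the known model),
#'   `residual_rms`, `converged`.
#' @export
complemental_hard_modeling <- function(binary_spectrum, known,
                                       config = peak_fit_config(),
                                       name = "solute") {
  if (!inherits(known, "pure_component_model")) {
    gp_validation_error("known must be a pure_component_model")
  }
  nu <- binary_spectrum$wavenumber
  y <- binary_spectrum$intensity
  if (max(abs(y)) == 0) gp_validation_error("all-zero spectrum")

  # Is the known model alone sufficient? Then there is nothing to extract.
  base <- vp_peak_fit(nu, y, known$peaks[0, , drop = FALSE], known = known,
                      baseline = TRUE, config = config)
  if (base$residual_rms <= config$residual_threshold * max(y)) {
    gp_degenerate_error(
      "the known component alone explains the spectrum; no solute to extract")
  }

  fit <- greedy_peak_fit(nu, y, config, known = known, baseline = TRUE,
                         residual_ref = max(y))
  keep <- fit$peaks$height > 1e-10 * max(y)
  solute_peaks <- fit$peaks[keep, , drop = FALSE]
  if (nrow(solute_peaks) == 0L) {
    gp_degenerate_error("no solute peaks with positive height were recovered")
  }

  # peaks that land on top of known (water) peaks are suspect
  for (i in seq_len(nrow(solute_peaks))) {
    d <- abs(known$peaks$position - solute_peaks$position[i])
    if (any(d <= known$peaks$fwhm)) {
      warning(sprintf(
        "recovered peak at %.1f cm-1 lies within 1 FWHM of a known-component peak",
        solute_peaks$position[i]), call. = FALSE)
    }
  }

  model <- pure_component_model(name, solute_peaks)
  attr(model, "known_weight") <- fit$known_weight
  attr(model, "known_adjusted") <- fit$known_adjusted
  attr(model, "baseline") <- fit$baseline
  attr(model, "residual_rms") <- fit$residual_rms
  attr(model, "converged") <-
    fit$residual_rms <= config$residual_threshold * max(y)
  model
}

#' Equilibrium purity of a MOPS species at a given pH
#'
#' Fraction of total MOPS present as the requested species at equilibrium,
#' used to validate that endpoint spectra (pH 2 for the protonated form,
#' pH 12 for the deprotonated form) are sufficiently pure before building a
#' pure-component model. The conventional purity threshold is 99.9%.
#'
#' @param ph pH value in `[0, 14]`.
#' @param species `"protonated"` or `"deprotonated"`.
#' @param temperature Temperature in kelvin (sets the pKa).
#' @return The species fraction in `[0, 1]`.
#' @export
protonation_endpoint_check <- function(ph, species = c("protonated", "deprotonated"),
                                       temperature = 308.15) {
  species <- match.arg(species)
  assert_scalar_number(ph, "ph", lower = 0, upper = 14)
  r <- 10^(ph - pka_mops(temperature))   # [MOPS-]/[MOPSH]
  if (species == "protonated") 1 / (1 + r) else r / (1 + r)
}
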