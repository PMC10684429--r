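#' Pseudo-Voigt peak
#'
#' The lineshape primitive of the hard model. A pseudo-Voigt is the
#' height-normalized convex combination of a Gaussian and a Lorentzian that
#' share apex position and full width at half maximum (FWHM):
#' \deqn{I(\nu) = h\,[\eta\,e^{-4\ln 2\,(\nu-\nu_0)^2/w^2} +
#'   (1-\eta)\,(1 + 4(\nu-\nu_0)^2/w^2)^{-1}]}
#' so the value at `position` equals `height` exactly and both mixing
#' partners have FWHM `fwhm`.
#'
#' @param height Apex height, counts, `>= 0`.
#' @param position Apex position, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1, `> 0`.
#' @param eta Gaussian fraction in `[0, 1]` (1 = pure Gaussian, 0 = pure
#'   Lorentzian).
#' @return A `pseudo_voigt_peak` object.
#' @export
pseudo_voigt_peak <- function(height, position, fwhm, eta = 0.5) {
  assert_scalar_number(height, "height", lower = 0)
  assert_scalar_number(position, "position")
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0) {
    gp_validation_error("fwhm must be a single positive number")
  }
  assert_scalar_number(eta, "eta", lower = 0, upper = 1)
  structure(list(height = as.double(height), position = as.double(position),
                 fwhm = as.double(fwhm), eta = as.double(eta)),
            class = "pseudo_voigt_peak")
}

# Unit-height pseudo-Voigt profile; vectorized over nu.
pv_profile <- function(nu, position, fwhm, eta) {
  u2 <- ((nu - position) / fwhm)^2
  eta * exp(-4 * log(2) * u2) + (1 - eta) / (1 + 4 * u2)
}

#' Evaluate a pseudo-Voigt peak on a wavenumber grid
#'
#' @param peak A [pseudo_voigt_peak()].
#' @param wavenumbers Numeric vector, cm^-1.
#' @return Intensity vector, same length as `wavenumbers`.
#' @export
eval_peak <- function(peak, wavenumbers) {
  if (!inherits(peak, "pseudo_voigt_peak")) {
    gp_validation_error("peak must be a pseudo_voigt_peak")
  }
  peak$height * pv_profile(wavenumbers, peak$position, peak$fwhm, peak$eta)
}

#' Pure-component hard model
#'
#' A named sum of pseudo-Voigt peaks representing one chemical species'
#' Raman signature (e.g. water, protonated MOPS, deprotonated MOPS,
#' penicillin G), together with the set of peak parameters that may vary
#' during a mixture fit. By convention only the water peaks' position and
#' linewidth are free: the water band changes shape with temperature and
#' ionic strength while the solute bands are held rigid.
#'
#' @param name Component name, unique within a composite model.
#' @param peaks Either a list of [pseudo_voigt_peak()] objects or a
#'   data.frame with columns `height`, `position`, `fwhm`, `eta`.
#' @param free_parameters Data frame with columns `peak` (1-based index),
#'   `parameter` (`"position"` or `"fwhm"`), `lower`, `upper` (absolute
#'   bounds for the fit). `NULL` means the component is rigid.
#' @return A `pure_component_model`.
#' @export
pure_component_model <- function(name, peaks, free_parameters = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    gp_validation_error("component name must be a non-empty string")
  }
  if (is.data.frame(peaks)) {
    need <- c("height", "position", "fwhm", "eta")
    if (!all(need %in% names(peaks))) {
      gp_validation_error("peaks data.frame needs columns height, position, fwhm, eta")
    }
    pk <- peaks[need]
  } else if (is.list(peaks) && length(peaks) > 0L &&
             all(vapply(peaks, inherits, logical(1), "pseudo_voigt_peak"))) {
    pk <- do.call(rbind, lapply(peaks, function(p) {
      data.frame(height = p$height, position = p$position,
                 fwhm = p$fwhm, eta = p$eta)
    }))
  } else {
    gp_validation_error("peaks must be pseudo_voigt_peak objects or a data.frame")
  }
  if (nrow(pk) < 1L) gp_validation_error("a component needs at least one peak")
  if (any(pk$fwhm <= 0) || any(pk$height < 0) ||
      any(pk$eta < 0) || any(pk$eta > 1)) {
    gp_validation_error("invalid peak parameters (fwhm > 0, height >= 0, eta in [0,1])")
  }
  if (!is.null(free_parameters)) {
    need <- c("peak", "parameter")
    if (!is.data.frame(free_parameters) || !all(need %in% names(free_parameters))) {
      gp_validation_error("free_parameters needs columns peak, parameter")
    }
    if (any(free_parameters$peak < 1L) || any(free_parameters$peak > nrow(pk))) {
      gp_validation_error("free_parameters reference non-existent peaks")
    }
    if (!all(free_parameters$parameter %in% c("position", "fwhm"))) {
      gp_validation_error("free parameters must be 'position' or 'fwhm'")
    }
    if (is.null(free_parameters$lower) || is.null(free_parameters$upper)) {
      free_parameters <- default_free_bounds(pk, free_parameters)
    }
  }
  structure(list(name = name, peaks = pk, free_parameters = free_parameters),
            class = "pure_component_model")
}

# Default bounds: position may move +-20 cm^-1, linewidth by a factor in
# [0.5, 2] of the stored value. Prevents peak-identity swaps during fits.
default_free_bounds <- function(pk, free) {
  free$lower <- NA_real_; free$upper <- NA_real_
  for (i in seq_len(nrow(free))) {
    p <- free$peak[i]
    if (free$parameter[i] == "position") {
      free$lower[i] <- pk$position[p] - 20
      free$upper[i] <- pk$position[p] + 20
    } else {
      free$lower[i] <- pk$fwhm[p] * 0.5
      free$upper[i] <- pk$fwhm[p] * 2
    }
  }
  free
}

#' Mark the position and linewidth of every peak of a component as free
#'
#' Convenience used for the water component whose band shape responds to
#' temperature and ionic strength.
#'
#' @param component A [pure_component_model()].
#' @return The component with `free_parameters` filled in with default
#'   bounds (position +-20 cm^-1, linewidth x 0.5-2).
#' @export
free_water_parameters <- function(component) {
  n <- nrow(component$peaks)
  free <- data.frame(peak = rep(seq_len(n), each = 2L),
                     parameter = rep(c("position", "fwhm"), n))
  pure_component_model(component$name, component$peaks,
                       default_free_bounds(component$peaks, free))
}

#' Evaluate a pure-component model
#'
#' Element-wise sum of [eval_peak()] over all of the component's peaks.
#'
#' @param model A [pure_component_model()].
#' @param wavenumbers Numeric vector, cm^-1.
#' @return Intensity vector.
#' @export
eval_component <- function(model, wavenumbers) {
  if (!inherits(model, "pure_component_model")) {
    gp_validation_error("model must be a pure_component_model")
  }
  eval_peak_table(model$peaks, wavenumbers)
}

#' Evaluate a component with adjusted peak parameters applied
#'
#' @param model A [pure_component_model()].
#' @param adjusted Data frame with columns `peak`, `parameter`, `value`
#'   (as returned in fit results), or `NULL`.
#' @param wavenumbers Numeric vector, cm^-1.
#' @return Intensity vector.
#' @export
eval_component_adjusted <- function(model, adjusted, wavenumbers) {
  pk <- model$peaks
  if (!is.null(adjusted)) {
    for (i in seq_len(nrow(adjusted))) {
      pk[[adjusted$parameter[i]]][adjusted$peak[i]] <- adjusted$value[i]
    }
  }
  eval_peak_table(pk, wavenumbers)
}

eval_peak_table <- function(pk, wavenumbers) {
  out <- numeric(length(wavenumbers))
  for (i in seq_len(nrow(pk))) {
    out <- out + pk$height[i] *
      pv_profile(wavenumbers, pk$position[i], pk$fwhm[i], pk$eta[i])
  }
  out
}

#' Composite mixture model
#'
#' An ordered set of pure-component models plus a linear baseline, evaluated
#' over a fixed fit window. This is the hard model that is fitted to mixture
#' spectra: the fit determines one non-negative weight per component, the two
#' baseline coefficients, and any free peak parameters.
#'
#' @param components List of [pure_component_model()] objects with unique
#'   names.
#' @param fit_window Length-2 numeric, `c(lo, hi)` in cm^-1; default the
#'   2700-3100 cm^-1 MOPS evaluation window.
#' @param baseline_order Baseline polynomial order; only `1` (linear) is
#'   supported.
#' @return A `composite_model`.
#' @export
composite_model <- function(components, fit_window = c(2700, 3100),
                            baseline_order = 1L) {
  if (!is.list(components) || length(components) < 1L ||
      !all(vapply(components, inherits, logical(1), "pure_component_model"))) {
    gp_validation_error("components must be a non-empty list of pure_component_model")
  }
  nms <- vapply(components, function(c) c$name, character(1))
  if (anyDuplicated(nms)) gp_validation_error("component names must be unique")
  if (length(fit_window) != 2L || fit_window[1L] >= fit_window[2L]) {
    gp_validation_error("fit_window must be c(lo, hi) with lo < hi")
  }
  if (baseline_order != 1L) gp_validation_error("only a linear baseline is supported")
  names(components) <- nms
  structure(list(components = components, fit_window = as.double(fit_window),
                 baseline_order = 1L),
            class = "composite_model")
}

#' Evaluate a composite model at given weights and baseline
#'
#' Computes `sum_i zeta_i * component_i + intercept + slope * nu`, optionally
#' after applying adjusted peak parameters (as produced by a mixture fit).
#'
#' @param model A [composite_model()].
#' @param weights Named numeric vector covering every component.
#' @param baseline Length-2 numeric `c(intercept, slope)`.
#' @param wavenumbers Numeric vector, cm^-1.
#' @param adjusted_parameters Optional data frame with columns `component`,
#'   `peak`, `parameter`, `value` overriding stored peak parameters.
#' @return Intensity vector.
#' @export
eval_mixture <- function(model, weights, baseline, wavenumbers,
                         adjusted_parameters = NULL) {
  if (!inherits(model, "composite_model")) {
    gp_validation_error("model must be a composite_model")
  }
  nms <- names(model$components)
  if (is.null(names(weights)) || !all(nms %in% names(weights))) {
    gp_validation_error(sprintf(
      "weights must be named and cover all components (%s)",
      paste(nms, collapse = ", ")))
  }
  if (length(baseline) != 2L) gp_validation_error("baseline must be c(intercept, slope)")
  out <- baseline[1L] + baseline[2L] * wavenumbers
  for (nm in nms) {
    pk <- apply_adjusted(model$components[[nm]]$peaks, nm, adjusted_parameters)
    out <- out + weights[[nm]] * eval_peak_table(pk, wavenumbers)
  }
  out
}

apply_adjusted <- function(pk, component_name, adjusted) {
  if (is.null(adjusted)) return(pk)
  rows <- adjusted[adjusted$component == component_name, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    pk[[rows$parameter[i]]][rows$peak[i]] <- rows$value[i]
  }
  pk
}

#' Read or write pure-component / composite models as JSON
#'
#' The on-disk schema for a component is
#' `{name, peaks: [{height, position_cm1, fwhm_cm1, gaussian_fraction}],
#'   free_parameters: [{peak, parameter, bounds: [lo, hi]}]}`;
#' a composite file holds `{components: [...], fit_window, baseline_order}`
#' with components inlined. Round trips preserve all parameters exactly
#' (full double precision).
#'
#' @param model A [pure_component_model()] or [composite_model()].
#' @param path JSON file path.
#' @return `read_model()` returns the deserialized model; `write_model()`
#'   returns `NULL` invisibly.
#' @export
write_model <- function(model, path) {
  obj <- serialize_model(model)
  ok <- tryCatch({
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gp_io_error(sprintf("cannot write model to %s", path))
  invisible(NULL)
}

serialize_model <- function(model) {
  if (inherits(model, "pure_component_model")) {
    peaks <- lapply(seq_len(nrow(model$peaks)), function(i) {
      list(height = model$peaks$height[i], position_cm1 = model$peaks$position[i],
           fwhm_cm1 = model$peaks$fwhm[i], gaussian_fraction = model$peaks$eta[i])
    })
    free <- NULL
    if (!is.null(model$free_parameters)) {
      free <- lapply(seq_len(nrow(model$free_parameters)), function(i) {
        list(peak = model$free_parameters$peak[i],
             parameter = model$free_parameters$parameter[i],
             bounds = c(model$free_parameters$lower[i],
                        model$free_parameters$upper[i]))
      })
    }
    list(type = "pure_component", name = model$name, peaks = peaks,
         free_parameters = free)
  } else if (inherits(model, "composite_model")) {
    list(type = "composite",
         components = lapply(model$components, serialize_model),
         fit_window = model$fit_window, baseline_order = model$baseline_order)
  } else {
    gp_validation_error("model must be a pure_component_model or composite_model")
  }
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) gp_io_error(sprintf("file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) gp_parse_error(sprintf(
                    "%s: invalid JSON (%s)", path, conditionMessage(e))))
  deserialize_model(obj, path)
}

deserialize_model <- function(obj, path = "<json>") {
  type <- obj$type
  if (identical(type, "composite")) {
    comps <- lapply(obj$components, deserialize_model, path = path)
    return(composite_model(comps,
                           fit_window = as.double(unlist(obj$fit_window)),
                           baseline_order = as.integer(obj$baseline_order)))
  }
  if (!identical(type, "pure_component") && is.null(obj$peaks)) {
    gp_parse_error(sprintf("%s: not a recognized model file", path))
  }
  pk <- do.call(rbind, lapply(obj$peaks, function(p) {
    data.frame(height = as.double(p$height), position = as.double(p$position_cm1),
               fwhm = as.double(p$fwhm_cm1), eta = as.double(p$gaussian_fraction))
  }))
  free <- NULL
  if (!is.null(obj$free_parameters) && length(obj$free_parameters) > 0L) {
    free <- do.call(rbind, lapply(obj$free_parameters, function(f) {
      b <- as.double(unlist(f$bounds))
      data.frame(peak = as.integer(f$peak), parameter = as.character(f$parameter),
                 lower = b[1L], upper = b[2L])
    }))
  }
  pure_component_model(obj$name, pk, free)
}
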