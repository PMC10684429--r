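# Solution chemistry of the simulated MOPS system: speciation, titration,
# ionic strength, and an independent charge-balance oracle.

KW <- 1e-14   # water autoprotolysis constant, concentration basis

#' Buffer state of a simulated MOPS sample
#'
#' Chemical ground truth for one simulated sample: total MOPS and its split
#' into protonated/deprotonated species, the strong-ion content (sodium and
#' chloride from NaOH/HCl/NaCl additions), temperature, volume, ionic
#' strength and concentration-based true pH. Constructed by [speciate()] and
#' transformed by [titrate()] and [add_salt()]; not usually built by hand.
#'
#' @param total_mops,c_mopsh,c_mops_minus Concentrations in mol/L;
#'   `c_mopsh + c_mops_minus` must equal `total_mops`.
#' @param temperature Kelvin.
#' @param volume Sample volume in litres.
#' @param c_na,c_cl Strong-ion concentrations, mol/L.
#' @param true_ph Concentration-based pH; recomputed from the speciation if
#'   omitted.
#' @return A `buffer_state`.
#' @export
buffer_state <- function(total_mops, c_mopsh, c_mops_minus, temperature,
                         volume = 0.03, c_na = c_mops_minus, c_cl = 0,
                         true_ph = NULL) {
  assert_scalar_number(total_mops, "total_mops", lower = 0)
  assert_scalar_number(c_mopsh, "c_mopsh", lower = 0)
  assert_scalar_number(c_mops_minus, "c_mops_minus", lower = 0)
  assert_temperature(temperature)
  assert_scalar_number(volume, "volume", lower = 1e-9)
  if (abs(c_mopsh + c_mops_minus - total_mops) > 1e-9 * max(total_mops, 1e-12)) {
    gp_validation_error("c_mopsh + c_mops_minus must equal total_mops")
  }
  if (is.null(true_ph)) {
    true_ph <- if (c_mopsh > 0 && c_mops_minus > 0) {
      pka_mops(temperature) + log10(c_mops_minus / c_mopsh)
    } else NA_real_
  }
  h <- if (is.finite(true_ph)) 10^(-true_ph) else 0
  oh <- if (h > 0) KW / h else 0
  ionic_strength <- 0.5 * (c_na + c_cl + c_mops_minus + h + oh)
  structure(list(total_mops = total_mops, c_mopsh = c_mopsh,
                 c_mops_minus = c_mops_minus, temperature = temperature,
                 volume = volume, c_na = c_na, c_cl = c_cl,
                 ionic_strength = ionic_strength, true_ph = true_ph),
            class = "buffer_state")
}

#' @export
print.buffer_state <- function(x, ...) {
  cat(sprintf(paste0("<buffer_state> %.1f mM MOPS (%.2f/%.2f mM H/-), pH %.3f, ",
                     "T %.2f K, I %.1f mM, V %.1f mL\n"),
              x$total_mops * 1e3, x$c_mopsh * 1e3, x$c_mops_minus * 1e3,
              x$true_ph, x$temperature, x$ionic_strength * 1e3, x$volume * 1e3))
  invisible(x)
}

#' Speciate a MOPS solution at a given pH
#'
#' Splits the total MOPS concentration into protonated and deprotonated
#' species so that `c(MOPS-)/c(MOPSH) = 10^(pH - pKa(T))`. The deprotonated
#' fraction is assumed to carry a sodium counter-ion (titration from the
#' free acid with NaOH), which sets the initial strong-ion content.
#'
#' @param total_mops Total MOPS concentration, mol/L.
#' @param ph Target pH.
#' @param temperature Kelvin.
#' @param volume Sample volume in litres.
#' @return A [buffer_state()].
#' @export
speciate <- function(total_mops, ph, temperature, volume = 0.03) {
  assert_scalar_number(total_mops, "total_mops", lower = 0)
  assert_scalar_number(ph, "ph")
  r <- ratio_from_ph(ph, temperature)
  c_minus <- total_mops * r / (1 + r)
  c_h <- total_mops - c_minus
  buffer_state(total_mops, c_h, c_minus, temperature, volume = volume,
               c_na = c_minus, c_cl = 0,
               true_ph = if (total_mops > 0) ph else NA_real_)
}

#' Titrate a buffered sample with strong base or strong acid
#'
#' Stoichiometric conversion between the two MOPS species: added NaOH
#' converts MOPSH to MOPS-, added HCl (negative `strong_base_mol`) converts
#' MOPS- back, and all concentrations are diluted by the added volume. The
#' new pH follows from the concentration-based Henderson-Hasselbalch
#' relation; within the buffered range (pH 6-8) this agrees with the full
#' charge-balance solution ([charge_balance_ph()]) to better than 0.002 pH.
#'
#' @param state A [buffer_state()].
#' @param strong_base_mol Moles of NaOH added (negative for HCl).
#' @param added_volume Added solution volume in litres.
#' @return The new [buffer_state()].
#' @export
titrate <- function(state, strong_base_mol, added_volume = 0) {
  if (!inherits(state, "buffer_state")) {
    gp_validation_error("state must be a buffer_state")
  }
  assert_scalar_number(strong_base_mol, "strong_base_mol")
  assert_scalar_number(added_volume, "added_volume", lower = 0)
  v <- state$volume
  n_h <- state$c_mopsh * v
  n_m <- state$c_mops_minus * v
  n_na <- state$c_na * v
  n_cl <- state$c_cl * v
  if (strong_base_mol > 0) {
    if (strong_base_mol > n_h + 1e-15) {
      gp_validation_error(sprintf(
        "over-titration: %.3g mol NaOH exceeds %.3g mol protonated MOPS",
        strong_base_mol, n_h))
    }
    n_h <- n_h - strong_base_mol
    n_m <- n_m + strong_base_mol
    n_na <- n_na + strong_base_mol
  } else if (strong_base_mol < 0) {
    acid <- -strong_base_mol
    if (acid > n_m + 1e-15) {
      gp_validation_error(sprintf(
        "over-titration: %.3g mol HCl exceeds %.3g mol deprotonated MOPS",
        acid, n_m))
    }
    n_m <- n_m - acid
    n_h <- n_h + acid
    n_cl <- n_cl + acid
  }
  v_new <- v + added_volume
  buffer_state(total_mops = (n_h + n_m) / v_new,
               c_mopsh = n_h / v_new, c_mops_minus = n_m / v_new,
               temperature = state$temperature, volume = v_new,
               c_na = n_na / v_new, c_cl = n_cl / v_new)
}

#' Charge-balance pH of a MOPS / strong-ion mixture (oracle)
#'
#' Independent of the stoichiometric bookkeeping in [titrate()]: solves
#' `[Na+] + [H3O+] - [MOPS-] - [Cl-] - [OH-] = 0` for the pH by bisection on
#' `[0, 14]` to 1e-6 pH, with `[MOPS-] = C_T Ka/(Ka + [H3O+])` and
#' `Kw = 1e-14` on a concentration basis. Used as the reference the fast
#' path is validated against.
#'
#' @param total_mops Total MOPS concentration, mol/L.
#' @param strong_base_conc Sodium (strong base) concentration, mol/L.
#' @param strong_acid_conc Chloride (strong acid) concentration, mol/L.
#' @param temperature Kelvin.
#' @return The pH.
#' @export
charge_balance_ph <- function(total_mops, strong_base_conc = 0,
                              strong_acid_conc = 0, temperature = 308.15) {
  assert_scalar_number(total_mops, "total_mops", lower = 0)
  assert_scalar_number(strong_base_conc, "strong_base_conc", lower = 0)
  assert_scalar_number(strong_acid_conc, "strong_acid_conc", lower = 0)
  ka <- 10^(-pka_mops(temperature))
  f <- function(ph) {
    h <- 10^(-ph)
    strong_base_conc + h - total_mops * ka / (ka + h) -
      strong_acid_conc - KW / h
  }
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
    gp_numeric_error("charge balance has no sign change on pH in [0, 14]")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Add NaCl to a buffered sample
#'
#' Raises the ionic strength (computed as `0.5 * sum(c_i z_i^2)` over Na+,
#' Cl-, MOPS-, H3O+ and OH-) without changing the concentration-based
#' speciation ratio; all concentrations are diluted by the added volume. An
#' activity-aware pH (`ph_activity`, via [activity_corrected_ph()]) is
#' attached for robustness studies; the concentration-based `true_ph` is
#' what the probe is calibrated against.
#'
#' @param state A [buffer_state()].
#' @param nacl_mol Moles of NaCl added, `>= 0`.
#' @param added_volume Added solution volume in litres.
#' @return The new [buffer_state()] with attribute `ph_activity`.
#' @export
add_salt <- function(state, nacl_mol, added_volume = 0) {
  if (!inherits(state, "buffer_state")) {
    gp_validation_error("state must be a buffer_state")
  }
  assert_scalar_number(nacl_mol, "nacl_mol", lower = 0)
  assert_scalar_number(added_volume, "added_volume", lower = 0)
  v <- state$volume
  v_new <- v + added_volume
  out <- buffer_state(
    total_mops = state$total_mops * v / v_new,
    c_mopsh = state$c_mopsh * v / v_new,
    c_mops_minus = state$c_mops_minus * v / v_new,
    temperature = state$temperature, volume = v_new,
    c_na = (state$c_na * v + nacl_mol) / v_new,
    c_cl = (state$c_cl * v + nacl_mol) / v_new)
  attr(out, "ph_activity") <-
    activity_corrected_ph(out$true_ph, out$ionic_strength)
  out
}
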