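---
title: "Methods: Raman pH determination with a MOPS buffer as its own indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman pH determination with a MOPS buffer as its own indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goodph)
```

## The measurement model

A MOPS-buffered aqueous medium contains two buffer species, protonated
MOPSH and deprotonated MOPS⁻, whose C–H stretching bands differ. The pH
follows from the concentration-based Henderson–Hasselbalch relation

$$\mathrm{pH} = \mathrm{p}K_a(T) + \log_{10}\frac{c_{\mathrm{MOPS}^-}}{c_{\mathrm{MOPSH}}},
\qquad
\mathrm{p}K_a(T) = \frac{814.077\,\mathrm{K}}{T} + 9.865 - 0.9501\,\ln(T/\mathrm{K}).$$

Two assumptions are built in:

* **Unit activity ratio.** The full thermodynamic relation carries
  $\log_{10}(\gamma_{\mathrm{MOPS}^-}/\gamma_{\mathrm{MOPSH}})$. Because the
  pair is neutral/singly-charged — the lowest charge an acid–base indicator
  can have — this term is set to zero in the measurement path. The package
  quarantines the extended Debye–Hückel machinery
  (`debye_huckel_log_gamma()`, `activity_corrected_ph()`) in
  simulation/diagnostic code; it is never applied inside `predict_ph()`.
  At I = 0.1 mol/L with A = 0.51, B = 1.5 the neglected term is ≈ 0.11 pH;
  the point of the design is that the *calibration* is performed under the
  same convention, so the systematic part largely cancels within the
  working range.
* **Known temperature.** The pKa moves by ≈ −0.25 pH between 15 and 35 °C,
  so every prediction needs the sample temperature (kelvin internally; the
  CLI accepts `35C` or `308.15K`). All pH algebra uses log₁₀; the natural
  logarithm appears only inside the pKa correlation.

## Spectral evaluation

Pure components are hard-modeled as sums of height-normalized pseudo-Voigt
peaks with four parameters each (height, position, FWHM, Gaussian
fraction); both mixing partners share one FWHM, so "height" and
"linewidth" are literal. A mixture spectrum over 2700–3100 cm⁻¹ is fitted
as

$$y(\nu) \approx \sum_i \zeta_i\,M_i(\nu) + a + b\nu$$

with non-negative weights $\zeta_i$ and a linear baseline. The water
peaks' position and linewidth are free during the fit (bounded to
±20 cm⁻¹ and ×[0.5, 2] to prevent peak-identity swaps) because the water
envelope changes shape with temperature and ionic strength; all solute
peaks are rigid.

The optimizer exploits the separable structure (variable projection): the
weights, heights and baseline are solved by constrained linear least
squares inside every evaluation of the nonlinear residual, and a
box-constrained Levenberg–Marquardt with central-difference Jacobian
iterates only over the few free shape parameters. The same engine builds
pure-component models from scratch (`fit_pure_component()`) and performs
complemental hard modeling (`complemental_hard_modeling()`): the known
water model's weight and free parameters are co-fitted while new peaks are
added greedily at the residual's maximum, starting from local-maximum
detection (initial FWHM = half the distance to the nearest neighbouring
maximum, floor 4 cm⁻¹; initial Gaussian fraction 0.5). Automatic peak
addition stops when the residual target (`residual_threshold`, a fraction
of the maximum intensity) is reached or the relative residual improvement
falls below `tolerance`. The iteration schedule is this package's own
choice; only the final peak counts of the original hard models are public.

### Numerical choices

* **Mixture-fit iteration cap (40).** Only the low-wavenumber tails of the
  two water bands reach the fit window, which makes their position/width
  nearly degenerate with each other and the baseline. On noisy spectra the
  optimizer crawls along this flat valley indefinitely while the MOPS
  weight *ratio* — the only quantity that matters — changes by well under
  10⁻³ pH after iteration ~15. The cap trades invisible precision for a
  ~5× speedup; a capped fit whose final relative improvement was < 10⁻⁴ is
  reported as converged (stagnated, not diverged). Noiseless spectra
  converge in < 10 iterations to residuals near machine precision, which is
  what the exactness-style acceptance criteria exercise.
* **Non-negativity** of weights/heights uses a naive active-set scheme
  (solve unconstrained, drop offending columns, repeat) — adequate for the
  handful of well-conditioned columns involved.
* **Ties/degeneracies.** A CHM call errors with a degenerate-input
  condition when the known model alone already explains the spectrum; CHM
  peaks landing within one FWHM of a known (water) peak raise a warning.
* **Out-of-range policy.** Predictions are flagged, not clamped, when the
  implied pH leaves pKa ± 1.3 (the effective pH 6–8 working range of
  MOPS); a vanishing MOPSH (or MOPS⁻) weight raises a range error instead
  of returning ±∞.

## Calibration

`calibrate()` fits `conc_ratio = k · zeta_ratio` through the origin,
unweighted by default. The reference-pH error propagates exponentially
into the concentration ratio (σ ≈ ln 10 · ratio · σ_ref), so a
1/σ²-weighted variant is offered; the unweighted default mirrors the
simple ratio-vs-ratio correlation the method was introduced with, and an
intercept is deliberately not entertained (a zero weight ratio must mean a
zero concentration ratio). `loo_crossval()` reports the leave-one-out
RMSECV over the calibration set; both it and held-out RMSEP use the plain
root-mean-square error.

## The synthetic world

The generator emulates the physical experiments the probe was
characterized with; its defaults are those conditions, chosen once:

* **Titration/calibration design:** 3 runs × 20 points, pH 6→8, 35 °C,
  30 mL of 50 mM MOPS (60 points in total).
* **Fixture peak tables** (`make_fixture_models()`): water as two broad
  bands near 3230/3420 cm⁻¹ whose tails reach the fit window; MOPS⁻ peaks
  always inside the bands that grow with pH (2718–2738, 2765–2938,
  2950–2965 cm⁻¹), MOPSH peaks inside the bands that shrink (2938–2950,
  2965–2982, 2990–3030 cm⁻¹), with deliberate overlap between species;
  penicillin G overlapping both plus an aromatic C–H band near
  3060 cm⁻¹. Peak counts (2/5/6/5) are smaller than the original
  instrument hard models (2/10/14/14), whose numeric peak parameters are
  not available; these tables are *synthetic stand-ins*, seeded and
  normalized to unit maximum.
* **Cross sections:** σ(MOPSH)/σ(MOPS⁻) = 0.996, making the stated-world
  calibration factor equal the experimentally determined one; water's cross section is
  scaled so the 55.3 mol/L water envelope and the 50 mM solute bands have
  comparable in-window amplitudes.
* **Noise model:** Gaussian spectral noise of 0.5% of the maximum
  intensity (180 s-accumulation equivalent; ×√3 for the 60 s kinetic
  acquisitions — the accumulation-time scaling is a modeling choice, the
  original noise levels were not quantified), reference-electrode noise
  sd 0.02 pH, and a log-normal per-spectrum intensity scale with cv 5%
  for laser-power fluctuation. The instrument grid is 2505–3825 cm⁻¹ at
  1 cm⁻¹ (the sampling interval was not published; 1 cm⁻¹ is typical for
  an 1800 l/mm grating).
* **Water response:** +0.05 cm⁻¹/K position shift and +0.1% linewidth per
  100 mM ionic strength — magnitudes invented (the physical effect is
  documented only qualitatively), chosen small but resolvable so the free
  water parameters are genuinely exercised.
* **Chemistry:** speciation/titration is stoichiometric with explicit
  Na⁺/Cl⁻ bookkeeping and dilution; it is validated against an independent
  charge-balance bisection oracle (`charge_balance_ph()`, Kw = 10⁻¹⁴,
  concentration basis) to < 0.002 pH inside the buffered range. The NaCl
  series performs 31 additions (12 small, then 19 five-times-larger,
  3.7×10⁻⁴ mol each small step — sized so the final ionic strength reaches
  ≈ 1.1 mol/L in the growing volume).
* **Enzyme scenario:** Michaelis–Menten substrate decay integrated with
  RK4; one effective proton per turnover (only the newly formed
  phenylacetic-acid carboxyl titrates; the other product's carboxyl was
  already deprotonated in this range), converting MOPS⁻ → MOPSH mole for
  mole. Product Raman contributions are omitted, as in the original hard
  model; the penicillin G component scales with remaining substrate.
  Defaults vmax = 3.2 µmol/(L·s), Km = 20 mM, S₀ = 50 mM, 25 °C, start
  pH 8.2 were chosen so the trajectory reproduces the behaviour of the
  physical reaction (pH 8.2 → ≈ 6.85 over ≈ 4.2 h); that observation
  constrains the trajectory, not the kinetic constants, so these values
  are a choice, made once. Buffer exhaustion truncates the series with a flag.

**What a green test does and does not establish.** The synthetic world has
exactly the model structure the fitter assumes (pseudo-Voigt peaks, linear
baseline, Gaussian noise). Green acceptance tests therefore demonstrate
that the pipeline is a faithful, well-conditioned implementation of the
method — recovery of known ground truth, ratiometric invariances, oracle
agreement — not that the method achieves 0.05 pH on a real instrument,
where lineshape misfit, cosmic rays, fluorescence backgrounds and
electrode drift exist. The error statistics of the physical probe cannot
be reproduced without the original spectra; the acceptance surrogate
(median held-out RMSEP ≈ 0.011 pH) is accordingly *better* than the
physical 0.04–0.05 pH values and is compared against them only as an
upper bound.

## Known limitations

* Single-buffer systems only; no multi-indicator mixtures, no pH outside
  pKa ± 1.3.
* CHM extracts one unknown at a time.
* The JCAMP-DX reader covers the plain AFFN `XYDATA=(X++(Y..Y))` and
  `XYPOINTS` dialects; compressed (SQZ/DIF) encodings and proprietary
  instrument formats are out of scope.
* Asymmetric lineshapes, Voigt-by-convolution and wavenumber-dependent
  instrument response are not modeled.
* The activity diagnostic uses literature-typical A, B, b parameters;
  MOPS-specific values are not established, so the diagnostic is
  qualitative.
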