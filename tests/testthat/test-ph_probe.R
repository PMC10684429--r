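test_that("pka_mops matches a high-precision evaluation of the correlation", {
  # frozen 30-digit reference values (mpmath) of 814.077/T + 9.865 - 0.9501 ln T
  expect_equal(pka_mops(288.15), 7.30931133247722, tolerance = 1e-9)
  expect_equal(pka_mops(298.15), 7.18214099763321, tolerance = 1e-9)
  expect_equal(pka_mops(308.15), 7.06219013973828, tolerance = 1e-9)
  expect_error(pka_mops(200), class = "goodph_validation_error")
})

test_that("pka_mops is strictly decreasing over the bioprocess range", {
  temps <- seq(288.15, 313.15, by = 0.5)
  expect_true(all(diff(pka_mops(temps)) < 0))
})

test_that("ph_from_ratio / ratio_from_ph are exact inverses", {
  expect_equal(ph_from_ratio(1, 298.15), pka_mops(298.15))
  expect_equal(ph_from_ratio(10, 308.15), pka_mops(308.15) + 1)
  expect_equal(ratio_from_ph(pka_mops(308.15) + 2, 308.15), 100,
               tolerance = 1e-12)
  # the worked mixture spectrum: ratio 0.847 at 35 degC maps to pH 6.99
  expect_equal(ph_from_ratio(0.847, 308.15), 6.99007355007, tolerance = 1e-9)
  for (temp in c(288.15, 298.15, 308.15, 313.15)) {
    for (ph in seq(5, 9, by = 0.5)) {
      expect_equal(ph_from_ratio(ratio_from_ph(ph, temp), temp), ph,
                   tolerance = 1e-12)
    }
  }
  expect_error(ph_from_ratio(0, 298.15), class = "goodph_validation_error")
  expect_error(ph_from_ratio(-1, 298.15), class = "goodph_validation_error")
})

test_that("calibrate fits the origin-constrained slope", {
  # identity data
  cal <- calibrate(data.frame(
    zeta_ratio = c(0.5, 1, 2),
    reference_ph = ph_from_ratio(c(0.5, 1, 2), 308.15),
    temperature = 308.15))
  expect_equal(cal$k, 1, tolerance = 1e-12)

  # cross-sections sigma_- = 2, sigma_H = 1: zeta ratios double the
  # concentration ratios, so k = sigma_H / sigma_- = 0.5; the closed form
  # sum(c z)/sum(z^2) = (0.5 + 2 + 8)/(1 + 4 + 16) = 0.5 was verified by a
  # brute-force grid search over k
  cal2 <- calibrate(data.frame(
    zeta_ratio = c(1, 2, 4),
    reference_ph = ph_from_ratio(c(0.5, 1, 2), 308.15),
    temperature = 308.15))
  expect_equal(cal2$k, 0.5, tolerance = 1e-12)

  expect_error(calibrate(data.frame(zeta_ratio = 2, reference_ph = 7,
                                    temperature = 308.15)),
               class = "goodph_validation_error")
  expect_error(calibrate(data.frame(zeta_ratio = c(0, 1),
                                    reference_ph = c(7, 7.2),
                                    temperature = 308.15)),
               class = "goodph_validation_error")
})

test_that("rmse follows its definition", {
  expect_equal(rmse(c(7, 7.5), c(7, 7.5)), 0)
  expect_equal(rmse(rep(7.1, 5), rep(7.0, 5)), 0.1)
  # hand arithmetic: sqrt(mean(0.03^2 + 0.04^2 + 0.05^2))
  expect_equal(rmse(c(7.03, 6.96, 7.05), c(7, 7, 7)), 0.0408248290464,
               tolerance = 1e-10)
  expect_error(rmse(1:3, 1:4), class = "goodph_validation_error")
})

test_that("loo_crossval matches brute-force fold enumeration", {
  # collinear points: every fold recovers the same k, RMSECV = 0
  zr <- c(0.5, 1, 2, 4)
  pts <- data.frame(zeta_ratio = zr,
                    reference_ph = ph_from_ratio(0.8 * zr, 308.15),
                    temperature = 308.15)
  expect_equal(as.numeric(loo_crossval(pts)), 0, tolerance = 1e-12)

  # perturb one point and enumerate the three folds by hand
  pts3 <- data.frame(zeta_ratio = c(1, 2, 3),
                     reference_ph = ph_from_ratio(c(1.05, 2, 3), 308.15),
                     temperature = 308.15)
  manual <- vapply(1:3, function(i) {
    rest <- pts3[-i, ]
    cr <- ratio_from_ph(rest$reference_ph, 308.15)
    k <- sum(cr * rest$zeta_ratio) / sum(rest$zeta_ratio^2)
    ph_from_ratio(k * pts3$zeta_ratio[i], 308.15)
  }, numeric(1))
  expect_equal(as.numeric(loo_crossval(pts3)),
               rmse(manual, pts3$reference_ph), tolerance = 1e-12)
  expect_gt(as.numeric(loo_crossval(pts3)), 0)

  expect_error(loo_crossval(pts3[1:2, ]), class = "goodph_validation_error")
})

test_that("extended Debye-Hueckel terms behave as specified", {
  # neutral species: only the linear term survives
  expect_equal(debye_huckel_log_gamma(0.51, 0, 0.2, 1.5, 0.1), 0.02)
  expect_equal(debye_huckel_log_gamma(0.51, 1, 0, 1.5, 0.3), 0)
  # hand evaluation at I = 0.1
  expect_equal(debye_huckel_log_gamma(0.51, 1, 0.1, 1.5, 0),
               -0.109388594411, tolerance = 1e-10)
  expect_error(debye_huckel_log_gamma(0.51, 1, -0.1, 1.5, 0),
               class = "goodph_validation_error")
})

test_that("activity correction is zero at I = 0 and negative beyond", {
  expect_equal(activity_corrected_ph(7, 0), 7)
  expect_equal(activity_corrected_ph(7, 0.1) - 7, -0.109388594411,
               tolerance = 1e-10)
  for (I in c(0.01, 0.1, 0.5, 1.1)) {
    expect_lt(activity_corrected_ph(7, I), 7)
  }
})

test_that("predict_ph round-trips a noiseless synthetic spectrum", {
  cal <- exact_calibration()
  st <- speciate(0.05, 7.0, 308.15)
  sp <- synthesize_spectrum(st, fixture_models, quiet_noise())
  pred <- predict_ph(sp, cal)
  expect_ph_close(pred$ph, 7.0, 1e-3)
  expect_true(pred$in_range)
  expect_true(pred$converged)
  expect_equal(pred$conc_ratio, cal$k * pred$zeta_ratio)
})

test_that("predictions far outside the working range are flagged or error", {
  cal <- exact_calibration()
  st <- speciate(0.05, 9.5, 308.15)   # 99.6% deprotonated
  sp <- synthesize_spectrum(st, fixture_models, quiet_noise())
  res <- tryCatch(predict_ph(sp, cal), error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "goodph_range_error")
  } else {
    expect_false(res$in_range)
  }
})

test_that("predicted pH is strictly increasing along a noiseless titration", {
  cal <- exact_calibration()
  ph_true <- seq(6.2, 7.8, length.out = 8)
  preds <- vapply(ph_true, function(ph) {
    st <- speciate(0.05, ph, 308.15)
    predict_ph(synthesize_spectrum(st, fixture_models, quiet_noise()), cal)$ph
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_lt(max(abs(preds - ph_true)), 1e-3)
})
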