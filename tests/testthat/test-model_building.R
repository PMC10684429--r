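window <- seq(2700, 3100, by = 1)

test_that("fit_pure_component recovers a single known peak to 1e-4 relative", {
  truth <- pseudo_voigt_peak(height = 2, position = 2900, fwhm = 25, eta = 0.37)
  sp <- raman_spectrum(window, eval_peak(truth, window))
  m <- fit_pure_component(sp, peak_fit_config(n_peaks = 1), "x")
  got <- unlist(m$peaks[1, c("height", "position", "fwhm", "eta")])
  want <- c(2, 2900, 25, 0.37)
  expect_true(all(abs(got / want - 1) < 1e-4))
  expect_true(attr(m, "converged"))
})

test_that("automatic peak addition is parsimonious and accurate", {
  # noiseless k-peak inputs, separations >= 2 FWHM: fitted count equals k
  cases <- list(
    list(pos = c(2800), fw = c(20)),
    list(pos = c(2750, 2880, 3010), fw = c(18, 22, 15)),
    list(pos = c(2730, 2800, 2870, 2950, 3050), fw = c(12, 16, 20, 14, 18)))
  for (cs in cases) {
    k <- length(cs$pos)
    pks <- lapply(seq_len(k), function(i) {
      pseudo_voigt_peak(0.5 + 0.1 * i, cs$pos[i], cs$fw[i], 0.2 + 0.1 * i)
    })
    y <- Reduce(`+`, lapply(pks, eval_peak, window))
    m <- fit_pure_component(raman_spectrum(window, y), peak_fit_config(), "x")
    expect_identical(nrow(m$peaks), k)
    expect_lt(attr(m, "residual_rms"), 1e-6 * max(y))
  }
})

test_that("round trip with small noise stays near the noise floor", {
  truth <- fixture_models$MOPSH
  clean <- eval_component(truth, window)
  noise_rms <- 0.002 * max(clean)
  withr::with_seed(7, {
    y <- clean + rnorm(length(window), 0, noise_rms)
  })
  m <- fit_pure_component(raman_spectrum(window, y),
                          peak_fit_config(n_peaks = nrow(truth$peaks)), "x")
  resid <- eval_component(m, window) - clean
  expect_lt(sqrt(mean(resid^2)), 3 * noise_rms)
})

test_that("fit_pure_component rejects degenerate input", {
  expect_error(
    fit_pure_component(raman_spectrum(window, rep(0, length(window))),
                       peak_fit_config(), "x"),
    class = "goodph_validation_error")
})

test_that("CHM recovers a constructed solute and conserves the mixture", {
  grid <- default_grid()
  water <- fixture_models$water
  truth <- pure_component_model("sol", data.frame(
    height = c(0.5, 0.8), position = c(2850, 2950),
    fwhm = c(20, 15), eta = c(0.4, 0.6)))
  baseline <- 0.02 + 1e-5 * (grid - 2505)
  y <- eval_component(water, grid) + eval_component(truth, grid) + baseline
  bin <- raman_spectrum(grid, y)
  rec <- complemental_hard_modeling(bin, water,
                                    peak_fit_config(residual_threshold = 1e-7),
                                    "sol")
  # solute parameters within 1e-3 relative of the construction
  got <- rec$peaks[order(rec$peaks$position), ]
  want <- truth$peaks[order(truth$peaks$position), ]
  expect_true(all(abs(got$height / want$height - 1) < 1e-3))
  expect_true(all(abs(got$position - want$position) < 0.1))
  # conservation: known*weight + solute + baseline reproduces the input
  recon <- attr(rec, "known_weight") *
    eval_component_adjusted(water, attr(rec, "known_adjusted"), grid) +
    eval_component(rec, grid) +
    attr(rec, "baseline")[1] + attr(rec, "baseline")[2] * grid
  expect_lt(sqrt(mean((recon - y)^2)), 1e-6 * max(y))
})

test_that("CHM linearity: scaling the solute scales recovered heights", {
  grid <- default_grid()
  water <- fixture_models$water
  truth <- pure_component_model("sol", data.frame(
    height = c(0.5, 0.8), position = c(2850, 2950),
    fwhm = c(20, 15), eta = c(0.4, 0.6)))
  mk <- function(scale) {
    y <- eval_component(water, grid) + scale * eval_component(truth, grid) +
      0.02 + 1e-5 * (grid - 2505)
    complemental_hard_modeling(raman_spectrum(grid, y), water,
                               peak_fit_config(residual_threshold = 1e-7),
                               "sol")
  }
  r1 <- mk(1); r5 <- mk(5)
  o1 <- order(r1$peaks$position); o5 <- order(r5$peaks$position)
  expect_equal(r5$peaks$height[o5], 5 * r1$peaks$height[o1],
               tolerance = 1e-3)
  expect_lt(max(abs(r5$peaks$position[o5] - r1$peaks$position[o1])), 1e-4)
})

test_that("CHM flags a spectrum the known model already explains", {
  grid <- default_grid()
  water <- fixture_models$water
  y <- 2 * eval_component(water, grid) + 0.01
  expect_error(
    complemental_hard_modeling(raman_spectrum(grid, y), water,
                               peak_fit_config(), "x"),
    class = "goodph_degenerate_error")
})

test_that("protonation endpoints are pure enough for model building", {
  # frozen against a 30-digit evaluation of the speciation equations
  expect_equal(protonation_endpoint_check(2, "protonated", 308.15),
               0.999991334251, tolerance = 1e-9)
  expect_equal(protonation_endpoint_check(12, "deprotonated", 308.15),
               0.99998846055, tolerance = 1e-9)
  # equivalence point: both species at exactly one half
  pka <- pka_mops(308.15)
  expect_equal(protonation_endpoint_check(pka, "protonated", 308.15), 0.5)
  expect_equal(protonation_endpoint_check(pka, "deprotonated", 308.15), 0.5)
  # both endpoints exceed the 99.9% purity convention
  expect_gt(protonation_endpoint_check(2, "protonated", 308.15), 0.999)
  expect_gt(protonation_endpoint_check(12, "deprotonated", 308.15), 0.999)
})
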