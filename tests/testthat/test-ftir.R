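# FTIR melting curves, transition temperature, beta, band analysis

test_that("peak picking returns the grid coordinate of the relative maximum", {
  nu <- seq(2800, 2900, by = 1)
  sp <- ir_spectrum(nu, exp(-(nu - 2850.4)^2 / (2 * 25)))
  expect_identical(pick_peak(sp, c(2830, 2870)), 2850)
  # optional refinement moves off-grid
  expect_equal(pick_peak(sp, c(2830, 2870), refine = TRUE), 2850.4,
               tolerance = 0.05)
  # two local maxima: the taller one wins
  y2 <- exp(-(nu - 2852)^2 / 8) + 0.6 * exp(-(nu - 2840)^2 / 8)
  expect_identical(pick_peak(ir_spectrum(nu, y2), c(2830, 2870)), 2852)
  # monotone data in the window: the maximum sits on the edge
  expect_error(pick_peak(ir_spectrum(nu, nu * 1e-3), c(2830, 2870)),
               class = "flick_edge_peak_error")
})

test_that("descending wavenumber grids are normalized on input", {
  nu <- seq(2900, 2800, by = -1)
  sp <- ir_spectrum(nu, exp(-(nu - 2851)^2 / 8))
  expect_true(all(diff(sp$wavenumber) > 0))
  expect_identical(pick_peak(sp, c(2830, 2870)), 2851)
})

test_that("noisy bands are picked within one grid step almost always", {
  nu <- seq(2800, 2900, by = 1)
  clean <- exp(-(nu - 2851)^2 / (2 * 25))
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    sp <- ir_spectrum(nu, clean + rnorm(length(nu), 0, 0.005))
    pos <- tryCatch(pick_peak(sp, c(2830, 2870)), error = function(e) NA)
    if (!is.na(pos) && abs(pos - 2851) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("melting curves assemble sorted and drop failed picks", {
  spectra <- generate_melting_curve(tm = 27, noise_sd = 0, as_spectra = TRUE)
  spectra <- spectra[sample(length(spectra))]   # scrambled temperature order
  curve <- build_melting_curve(spectra)
  expect_s3_class(curve, "melting_curve")
  expect_true(!is.unsorted(curve$temperature, strictly = TRUE))
  expect_true(all(diff(curve$peak_position) >= -1))  # grid-quantized sigmoid

  # poison one spectrum so its peak leaves the window: it gets dropped
  bad <- spectra
  bad[[3]]$absorbance <- seq_along(bad[[3]]$wavenumber) * 1e-3
  expect_warning(curve2 <- build_melting_curve(bad), "dropped")
  expect_identical(nrow(curve2), nrow(curve) - 1L)
})

test_that("transition temperature is recovered from the derivative maximum", {
  # 27 C midpoint, 3 C width (binary-mixture-like conditions)
  mc <- generate_melting_curve(tm = 27, width = 3, noise_sd = 0)
  expect_equal(estimate_tm(mc), 27, tolerance = 0.2 / 27)
  # 33 C midpoint, widened transition (DMSO-like conditions)
  mc2 <- generate_melting_curve(tm = 33, width = 5, noise_sd = 0)
  expect_equal(estimate_tm(mc2), 33, tolerance = 0.3 / 33)
})

test_that("midpoints anywhere in the interior are recovered within 0.2 C", {
  for (tm in seq(15, 55, by = 10)) {
    mc <- generate_melting_curve(tm = tm, width = 3, noise_sd = 0)
    expect_lt(abs(estimate_tm(mc) - tm), 0.2)
  }
})

test_that("curves without a transition are rejected", {
  tt <- 5:70
  expect_error(estimate_tm(melting_curve(tt, 2850 + 0.01 * tt)),
               class = "flick_no_transition_error")
  expect_error(estimate_tm(generate_melting_curve(tm = 27, delta_nu = 0,
                                                  noise_sd = 0)),
               class = "flick_no_transition_error")
})

test_that("beta matches analytic derivatives", {
  tt <- 5:70
  # constant position: beta identically zero
  b0 <- compute_beta(melting_curve(tt, rep(2850, length(tt))))
  expect_lt(max(abs(b0$beta)), 1e-10)
  # linear trend: beta = slope / nu(T)
  bl <- compute_beta(melting_curve(tt, 2850 + 0.1 * tt))
  at25 <- bl$beta[bl$temperature == 25]
  expect_equal(at25, 0.1 / 2852.5, tolerance = 1e-6)
  # exponential trend: beta constant equal to the rate, within 1%
  ce <- 2e-4
  be <- compute_beta(melting_curve(tt, 2850 * exp(ce * tt)))
  expect_equal(be$beta, rep(ce, nrow(be)), tolerance = 0.01)
  # logistic melting curve: beta peaks at the transition
  mc <- generate_melting_curve(tm = 27, width = 3, noise_sd = 0)
  bm <- compute_beta(mc)
  expect_equal(bm$temperature[which.max(bm$beta)], 27, tolerance = 1 / 27)
})

test_that("band integration matches analytic Gaussian areas", {
  sp <- generate_co_band(areas = c(3 * sqrt(2 * pi), 0),
                         centers = c(1975, 1981), sigmas = c(3, 3))
  # amplitude 1, sigma 3 Gaussian fully inside the range: area 3 sqrt(2 pi)
  expect_equal(integrate_band(sp), 3 * sqrt(2 * pi), tolerance = 1e-3)
  # constant offset removed by the endpoint baseline
  sp_off <- ir_spectrum(sp$wavenumber, sp$absorbance + 0.2)
  expect_equal(integrate_band(sp_off), integrate_band(sp), tolerance = 1e-9)
  # two components with known areas, normalized
  sp2 <- generate_co_band(areas = c(2, 1))
  expect_equal(integrate_band(sp2, norm_ref = 4), 0.75, tolerance = 0.01)
  # additive over disjoint sub-ranges (no baseline inside a band)
  whole <- integrate_band(sp2, range = c(1960, 1990), baseline = FALSE)
  parts <- integrate_band(sp2, range = c(1960, 1978), baseline = FALSE) +
    integrate_band(sp2, range = c(1978, 1990), baseline = FALSE)
  expect_equal(parts, whole, tolerance = 1e-10)
})

test_that("two-Gaussian decomposition recovers known mixtures", {
  fit <- fit_two_gaussians(generate_co_band(areas = c(3, 1)))
  expect_equal(fit$f1, 0.75, tolerance = 0.01 / 0.75)
  expect_equal(fit$centers, c(1981, 1975), tolerance = 1e-2)
  expect_lt(fit$sigmas[1], fit$sigmas[2])   # core component narrower
  # vanishing second component: all area in component 1
  fit1 <- fit_two_gaussians(generate_co_band(areas = c(2, 0)))
  expect_gt(fit1$f1, 0.99)
  # vanishing first component
  fit0 <- fit_two_gaussians(generate_co_band(areas = c(0, 1)))
  expect_lt(fit0$f1, 0.01)
})

test_that("f1 is invariant to overall intensity scaling", {
  sp <- generate_co_band(areas = c(3, 1), noise_sd = 0)
  f_a <- fit_two_gaussians(sp)$f1
  sp$absorbance <- 37 * sp$absorbance
  f_b <- fit_two_gaussians(sp)$f1
  expect_equal(f_b, f_a, tolerance = 1e-6)
})

test_that("f1 recovery tolerates realistic noise (spot check)", {
  for (seed in 1:20) {
    sp <- generate_co_band(areas = c(3, 1), baseline = c(0.05, 1e-3),
                           noise_sd = 0.01 * max(1 / (1.5 * sqrt(2 * pi)) * 3),
                           seed = seed)
    fit <- fit_two_gaussians(sp)
    expect_lt(abs(fit$f1 - 0.75), 0.04)
  }
})
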