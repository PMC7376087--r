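# spectrum model fitting

test_that("noiseless free-spectrum fit is exact", {
  sp <- model_fluct_spectrum(44, n = 2:18)
  fit <- fit_bending_free(sp)
  expect_equal(fit$estimates$kappa_tilde, 44, tolerance = 1e-10)
  expect_equal(fit$n_range, c(5, 18))
})

test_that("noiseless tension fit recovers both parameters", {
  sp <- model_fluct_spectrum(30, 50, n = 2:18)
  fit <- fit_tension_model(sp)
  expect_equal(fit$estimates$kappa_tilde, 30, tolerance = 1e-6)
  expect_equal(fit$estimates$sigma_tilde, 50, tolerance = 1e-6)
})

test_that("noiseless confined fit recovers all three parameters", {
  sp <- model_fluct_spectrum(50, 40, 900, n = 3:18)
  fit <- fit_confined_model(sp)
  expect_equal(fit$estimates$kappa_tilde, 50, tolerance = 1e-4)
  expect_equal(fit$estimates$sigma_tilde, 40, tolerance = 1e-4)
  expect_equal(fit$estimates$gamma_tilde, 900, tolerance = 1e-4)
})

test_that("confined fit on unconfined data is consistent with the tension fit", {
  p <- spectrum_params(40, 20, mean_radius = 50)
  sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                               n_frames = 2000, seed = 8))
  ft <- fit_tension_model(sp, n_min = 3)
  fc <- fit_confined_model(sp, n_min = 3)
  expect_equal(fc$estimates$kappa_tilde, ft$estimates$kappa_tilde,
               tolerance = 0.02)
  # fitted confinement statistically consistent with zero
  expect_lt(fc$estimates$gamma_tilde,
            max(3 * fc$se$gamma_tilde, 1e-3 * 20^2, na.rm = TRUE))
})

test_that("sampled spectra recover generating tension-model parameters", {
  for (seed in 1:5) {
    p <- spectrum_params(30, 50, mean_radius = 50)
    sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                                 n_frames = 2000, seed = seed))
    fit <- fit_tension_model(sp)
    expect_equal(fit$estimates$kappa_tilde, 30, tolerance = 0.15)
    expect_equal(fit$estimates$sigma_tilde, 50, tolerance = 0.15)
  }
})

test_that("sampled confined spectra recover the bending modulus", {
  for (seed in 1:5) {
    p <- spectrum_params(50, 40, 900, mean_radius = 50)
    sp <- estimate_spectrum(sample_contour_modes(p, "confined",
                                                 n_frames = 2000, seed = seed))
    fit <- fit_confined_model(sp)
    expect_equal(fit$estimates$kappa_tilde, 50, tolerance = 0.20)
  }
})

test_that("high-mode-only fits leave a weak tension unidentified but pin kappa", {
  p <- spectrum_params(44, 0.01, mean_radius = 50)
  sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                               n_frames = 2000, seed = 12))
  fit <- fit_tension_model(sp, n_min = 5, n_max = 18)
  expect_equal(fit$estimates$kappa_tilde, 44, tolerance = 0.05)
  # tension either hits its floor or carries an se larger than the estimate
  sig_uninformative <- fit$estimates$sigma_tilde <= 1e-5 ||
    is.na(fit$se$sigma_tilde) ||
    fit$se$sigma_tilde > fit$estimates$sigma_tilde
  expect_true(sig_uninformative)
})

test_that("weighted fits are invariant to rescaling the standard errors", {
  p <- spectrum_params(44, 0.01, mean_radius = 50)
  sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                               n_frames = 2000, seed = 13))
  sp2 <- sp
  sp2$se <- 2 * sp$se
  f1 <- fit_bending_free(sp)
  f2 <- fit_bending_free(sp2)
  expect_equal(f2$estimates$kappa_tilde, f1$estimates$kappa_tilde,
               tolerance = 1e-12)
  expect_equal(f2$se$kappa_tilde, f1$se$kappa_tilde, tolerance = 1e-12)
})

test_that("quadrupling the frame count halves the kappa standard error", {
  p <- spectrum_params(44, 0.01, mean_radius = 50)
  se_at <- function(N) {
    mean(vapply(1:4, function(s) {
      sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                                   n_frames = N, seed = 100 + s))
      fit_bending_free(sp)$se$kappa_tilde
    }, numeric(1)))
  }
  ratio <- se_at(1000) / se_at(4000)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("baseline normalization behaves as a ratio", {
  out <- normalize_series(1:5, rep(7, 5), baseline = 7)
  expect_equal(out$kappa_ratio, rep(1, 5))
  expect_equal(normalize_series(0, 1.37 * 5, baseline = 5)$kappa_ratio, 1.37)
  expect_error(normalize_series(1, 1, baseline = 0), class = "flick_domain_error")

  # seven synthetic cells sharing a true ratio: mean within one se
  set.seed(31)
  true_ratio <- 1.4
  ratios <- vapply(1:7, function(i) {
    k0 <- runif(1, 4, 8)
    kt <- true_ratio * k0 * (1 + rnorm(1, 0, 0.05))
    normalize_series(30, kt, baseline = k0)$kappa_ratio
  }, numeric(1))
  se <- sd(ratios) / sqrt(7)
  expect_lt(abs(mean(ratios) - true_ratio), 2 * se + 1e-9)
})

test_that("insufficient usable modes raise an informative error", {
  sp <- model_fluct_spectrum(44, n = 2:6)
  expect_error(fit_bending_free(sp, n_min = 5, n_max = 18),
               class = "flick_insufficient_data")
})
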