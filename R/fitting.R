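#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# subset a fluct_spectrum to a mode range, with weights 1/se^2 (unit weights
# when any se is zero, i.e. noiseless synthetic spectra)
.fit_slice <- function(spectrum, n_min, n_max, min_modes = 4L) {
  stopifnot(inherits(spectrum, "fluct_spectrum"))
  keep <- spectrum$n >= n_min & spectrum$n <= n_max &
    is.finite(spectrum$delta2) & spectrum$delta2 > 0
  if (sum(keep) < min_modes) {
    .flick_error("flick_insufficient_data",
                 sprintf("only %d usable modes in n = %d..%d (need >= %d)",
                         sum(keep), n_min, n_max, min_modes))
  }
  n <- spectrum$n[keep]
  y <- spectrum$delta2[keep]
  se <- spectrum$se[keep]
  w <- if (any(se <= 0)) rep(1, length(y)) else 1 / se^2
  list(n = n, y = y, se = se, w = w)
}

.fit_result <- function(model, estimates, se, n_range, chi2_reduced,
                        spectrum, fit = NULL) {
  structure(list(model = model, estimates = estimates, se = se,
                 n_range = n_range, chi2_reduced = chi2_reduced,
                 mean_radius = spectrum$mean_radius,
                 frames = spectrum$frames, fit = fit),
            class = "flick_fit")
}

#' @export
print.flick_fit <- function(x, ...) {
  cat(sprintf("Membrane spectrum fit (%s model), modes %d..%d\n",
              x$model, x$n_range[1], x$n_range[2]))
  for (p in names(x$estimates)) {
    cat(sprintf("  %-12s %10.4g +/- %.3g\n", p, x$estimates[[p]], x$se[[p]]))
  }
  cat(sprintf("  reduced chi-squared: %.3g\n", x$chi2_reduced))
  invisible(x)
}

#' Fit the bending modulus from the high-mode spectrum
#'
#' Weighted least squares of `<delta_n^2>` against the tension-free model
#' `n^-3 / (2 pi kappa_tilde)` over modes `n_min..n_max` (default 5-18,
#' where tension and overall curvature no longer matter for quasispherical
#' vesicles). The model is linear in `1/kappa_tilde`, so the estimate is
#' closed form; weights are `1/se_n^2` (unit weights if the spectrum carries
#' no standard errors).
#'
#' @param spectrum a [estimate_spectrum()] result.
#' @param n_min,n_max fitted mode range.
#' @param weighted use `1/se^2` weights (default TRUE).
#' @return a `flick_fit` with the estimate `kappa_tilde`, its standard
#'   error, and the reduced chi-squared.
#' @examples
#' p <- spectrum_params(44, 0.01, mean_radius = 50)
#' sp <- estimate_spectrum(sample_contour_modes(p, "tension", n_frames = 2000, seed = 2))
#' fit_bending_free(sp)
#' @export
fit_bending_free <- function(spectrum, n_min = 5L, n_max = 18L,
                             weighted = TRUE) {
  s <- .fit_slice(spectrum, n_min, n_max)
  w <- if (weighted) s$w else rep(1, length(s$y))
  x <- 1 / (2 * pi * s$n^3)       # model: y = x / kappa_tilde
  sxx <- sum(w * x^2)
  inv_kappa <- sum(w * x * s$y) / sxx
  if (inv_kappa <= 0) {
    .flick_error("flick_fit_error", "fitted 1/kappa_tilde is non-positive")
  }
  kappa <- 1 / inv_kappa
  resid <- s$y - x * inv_kappa
  dof <- length(s$y) - 1L
  chi2r <- sum(w * resid^2) / dof
  # se of inv_kappa from the weighted normal equations, scaled by the
  # reduced chi-squared (the usual nls convention; invariant to rescaling
  # all weights by a common factor)
  se_inv <- sqrt(chi2r / sxx)
  se_kappa <- kappa^2 * se_inv
  .fit_result("free",
              estimates = list(kappa_tilde = kappa),
              se = list(kappa_tilde = se_kappa),
              n_range = c(n_min, n_max), chi2_reduced = chi2r,
              spectrum = spectrum)
}

# shared nonlinear fitting backend
.fit_nls <- function(spectrum, n_min, n_max, model, start, lower, upper) {
  s <- .fit_slice(spectrum, n_min, n_max, min_modes = length(start) + 1L)
  df <- data.frame(n = s$n, y = s$y)
  form <- switch(model,
    tension = y ~ eval_tension_spectrum(kappa_tilde, sigma_tilde, n),
    confined = y ~ eval_confined_spectrum(kappa_tilde, sigma_tilde, gamma_tilde, n)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      upper = upper, weights = s$w,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) {
      .flick_error("flick_fit_error",
                   paste0("spectrum fit did not converge: ", conditionMessage(e)))
    }
  )
  est <- as.list(coef(fit))
  se <- tryCatch(as.list(sqrt(diag(vcov(fit)))),
                 error = function(e) as.list(rep(NA_real_, length(est))))
  names(se) <- names(est)
  dof <- length(s$y) - length(est)
  chi2r <- sum(s$w * stats::resid(fit)^2) / dof
  .fit_result(model, est, se, c(n_min, n_max), chi2r, spectrum, fit = fit)
}

#' Fit bending modulus and reduced tension
#'
#' Nonlinear weighted least squares of the measured spectrum against the
#' tension-bending model over modes `n_min..n_max` (default 2-18).
#' `kappa_tilde` is initialized from [fit_bending_free()] on the high modes
#' and `sigma_tilde` at 1; parameters are box-bounded to
#' `kappa_tilde in (0, 1e4]`, `sigma_tilde in [1e-6, 1e6]`. With only high
#' modes in range the tension is weakly identified (its standard error will
#' exceed the estimate) while the bending modulus remains well determined.
#'
#' @inheritParams fit_bending_free
#' @return a `flick_fit` with `kappa_tilde` and `sigma_tilde`.
#' @export
fit_tension_model <- function(spectrum, n_min = 2L, n_max = 18L) {
  hi <- max(5L, n_min)
  k0 <- tryCatch(
    fit_bending_free(spectrum, n_min = hi, n_max = n_max)$estimates$kappa_tilde,
    flickspec_error = function(e) 10
  )
  .fit_nls(spectrum, n_min, n_max, "tension",
           start = list(kappa_tilde = k0, sigma_tilde = 1),
           lower = c(kappa_tilde = 1e-8, sigma_tilde = 1e-6),
           upper = c(kappa_tilde = 1e4, sigma_tilde = 1e6))
}

#' Fit the confined (red blood cell) spectrum model
#'
#' Nonlinear weighted least squares over bending modulus, reduced tension
#' and confinement strength, on modes `n_min..n_max` (default 3-18; mode 2
#' is excluded as shape/curvature dominated in discocytes). The confinement
#' is initialized at 0 so the fit starts from the nested tension model;
#' during the search the spectrum is evaluated on the principal complex
#' branch whenever `gamma_tilde > sigma_tilde^2`, which keeps the model
#' smooth across that boundary.
#'
#' @inheritParams fit_bending_free
#' @return a `flick_fit` with `kappa_tilde`, `sigma_tilde`, `gamma_tilde`.
#' @export
fit_confined_model <- function(spectrum, n_min = 3L, n_max = 18L) {
  hi <- max(5L, n_min)
  k0 <- tryCatch(
    fit_bending_free(spectrum, n_min = hi, n_max = n_max)$estimates$kappa_tilde,
    flickspec_error = function(e) 10
  )
  .fit_nls(spectrum, n_min, n_max, "confined",
           start = list(kappa_tilde = k0, sigma_tilde = 1, gamma_tilde = 0),
           lower = c(kappa_tilde = 1e-8, sigma_tilde = 1e-6, gamma_tilde = 0),
           upper = c(kappa_tilde = 1e4, sigma_tilde = 1e6, gamma_tilde = 1e12))
}

#' Normalize a bending-modulus time series to its baseline
#'
#' Used for per-cell time courses: each cell's moduli are divided by its own
#' pre-treatment baseline `kappa_0`, so the series starts at 1 and relative
#' stiffening/softening can be averaged across cells.
#'
#' @param time time points (any increasing unit).
#' @param kappa bending moduli (same length, kBT units).
#' @param baseline the cell's baseline modulus kappa_0, > 0.
#' @return a data frame with columns `time` and `kappa_ratio`.
#' @examples
#' normalize_series(c(0, 30, 60), c(5.0, 6.85, 7.1), baseline = 5.0)
#' @export
normalize_series <- function(time, kappa, baseline) {
  stopifnot(length(time) == length(kappa))
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0) {
    .flick_error("flick_domain_error", "`baseline` must be a single value > 0")
  }
  data.frame(time = time, kappa_ratio = kappa / baseline)
}
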