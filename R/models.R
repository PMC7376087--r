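#' Dimensionless membrane spectrum parameters
#'
#' Bundle of the dimensionless parameters entering the planar-membrane
#' fluctuation spectra: the bending modulus `kappa_tilde` = kappa/kBT, the
#' reduced tension `sigma_tilde` = sigma <R>^2 / (2 kappa), and the reduced
#' confinement strength `gamma_tilde` = gamma <R>^4 / kappa coupling a red
#' blood cell bilayer to its spectrin skeleton. `mean_radius` is the mean
#' equatorial contour radius <R> (metres or pixels, the caller's choice) and
#' `temperature` the absolute temperature; both are optional metadata until a
#' dimensional conversion is requested.
#'
#' @param kappa_tilde dimensionless bending modulus, > 0.
#' @param sigma_tilde dimensionless reduced tension, >= 0.
#' @param gamma_tilde dimensionless confinement strength, >= 0.
#' @param mean_radius mean contour radius (m or px), > 0 if given.
#' @param temperature absolute temperature (K), > 0 if given.
#' @return an object of class `spectrum_params`.
#' @seealso [eval_tension_spectrum()], [eval_confined_spectrum()],
#'   [to_dimensional()]
#' @examples
#' spectrum_params(kappa_tilde = 44, sigma_tilde = 0.01, mean_radius = 9e-6)
#' @export
spectrum_params <- function(kappa_tilde, sigma_tilde = 0, gamma_tilde = 0,
                            mean_radius = NA_real_, temperature = NA_real_) {
  stopifnot(is.numeric(kappa_tilde), length(kappa_tilde) == 1L,
            is.numeric(sigma_tilde), length(sigma_tilde) == 1L,
            is.numeric(gamma_tilde), length(gamma_tilde) == 1L)
  if (!is.finite(kappa_tilde) || kappa_tilde <= 0) {
    .flick_error("flick_domain_error", "`kappa_tilde` must be > 0")
  }
  if (sigma_tilde < 0) {
    .flick_error("flick_domain_error", "`sigma_tilde` must be >= 0")
  }
  if (gamma_tilde < 0) {
    .flick_error("flick_domain_error", "`gamma_tilde` must be >= 0")
  }
  if (!is.na(mean_radius) && mean_radius <= 0) {
    .flick_error("flick_domain_error", "`mean_radius` must be > 0")
  }
  if (!is.na(temperature) && temperature <= 0) {
    .flick_error("flick_domain_error", "`temperature` must be > 0 (kelvin)")
  }
  structure(
    list(kappa_tilde = kappa_tilde, sigma_tilde = sigma_tilde,
         gamma_tilde = gamma_tilde, mean_radius = mean_radius,
         temperature = temperature),
    class = "spectrum_params"
  )
}

#' @export
print.spectrum_params <- function(x, ...) {
  cat("Membrane spectrum parameters (dimensionless)\n")
  cat(sprintf("  kappa_tilde (kappa/kBT): %g\n", x$kappa_tilde))
  cat(sprintf("  sigma_tilde:             %g\n", x$sigma_tilde))
  cat(sprintf("  gamma_tilde:             %g\n", x$gamma_tilde))
  if (!is.na(x$mean_radius)) cat(sprintf("  mean radius <R>:         %g\n", x$mean_radius))
  if (!is.na(x$temperature)) cat(sprintf("  temperature:             %g K\n", x$temperature))
  invisible(x)
}

.check_modes <- function(n) {
  if (!is.numeric(n) || any(n < 2) || any(n != round(n))) {
    .flick_error("flick_domain_error", "mode numbers `n` must be integers >= 2")
  }
}

#' Tension-free fluctuation spectrum (high-mode limit)
#'
#' Mean-squared Fourier amplitude of mode `n` for a membrane whose short
#' wavelength undulations are controlled by bending elasticity alone:
#' `<delta_n^2> = n^-3 / (2 pi kappa_tilde)`. This is the limit of the
#' tension spectrum for `sigma_tilde -> 0` and is the model fitted to the
#' high modes (n = 5-18) of vesicle spectra to extract the bending modulus.
#'
#' @param kappa_tilde dimensionless bending modulus (> 0).
#' @param n integer mode number(s), >= 2.
#' @return mean-squared amplitude(s), dimensionless.
#' @examples
#' eval_free_spectrum(44, 5:18)
#' @export
eval_free_spectrum <- function(kappa_tilde, n) {
  if (!is.numeric(kappa_tilde) || kappa_tilde <= 0) {
    .flick_error("flick_domain_error", "`kappa_tilde` must be > 0")
  }
  .check_modes(n)
  1 / (2 * pi * kappa_tilde * n^3)
}

# Eq-1 bracket [1/n - (2*sigma + n^2)^(-1/2)] with a series fallback:
# for 2*sigma/n^2 below ~1e-8 the direct difference loses all significance,
# so switch to sigma/n^3 - (3/2) sigma^2/n^5.
.tension_bracket <- function(sigma_tilde, n) {
  x <- 2 * sigma_tilde / n^2
  direct <- 1 / n - 1 / sqrt(2 * sigma_tilde + n^2)
  series <- sigma_tilde / n^3 - 1.5 * sigma_tilde^2 / n^5
  ifelse(x < 1e-8, series, direct)
}

#' Tension-bending fluctuation spectrum
#'
#' Mean-squared Fourier amplitude of contour mode `n` for a planar membrane
#' under reduced tension `sigma_tilde`:
#' `<delta_n^2> = (1 / (2 pi kappa_tilde sigma_tilde)) *
#'   (1/n - (2 sigma_tilde + n^2)^(-1/2))`.
#' Tension suppresses the long-wavelength modes; for `sigma_tilde -> 0` the
#' expression reduces to [eval_free_spectrum()].
#'
#' @param kappa_tilde dimensionless bending modulus (> 0).
#' @param sigma_tilde dimensionless reduced tension (> 0; for the tensionless
#'   limit call [eval_free_spectrum()]).
#' @param n integer mode number(s), >= 2.
#' @return mean-squared amplitude(s), dimensionless.
#' @examples
#' eval_tension_spectrum(44, 0.01, 2:18)
#' @export
eval_tension_spectrum <- function(kappa_tilde, sigma_tilde, n) {
  if (!is.numeric(kappa_tilde) || kappa_tilde <= 0) {
    .flick_error("flick_domain_error", "`kappa_tilde` must be > 0")
  }
  if (!is.numeric(sigma_tilde) || sigma_tilde <= 0) {
    .flick_error(
      "flick_domain_error",
      "`sigma_tilde` must be > 0; use eval_free_spectrum() for the tensionless limit"
    )
  }
  .check_modes(n)
  .tension_bracket(sigma_tilde, n) / (2 * pi * kappa_tilde * sigma_tilde)
}

#' Confined fluctuation spectrum (red blood cell model)
#'
#' Mean-squared Fourier amplitude of contour mode `n` for a membrane coupled
#' harmonically to an elastic skeleton (confinement strength `gamma_tilde`):
#' with `s = sqrt(sigma_tilde^2 - gamma_tilde)`,
#' `<delta_n^2> = ((sigma + n^2 - s)^(-1/2) - (sigma + n^2 + s)^(-1/2)) /
#'  (2 pi kappa_tilde s)`.
#' At `gamma_tilde = 0` this reduces exactly to [eval_tension_spectrum()].
#' When `gamma_tilde > sigma_tilde^2` the square roots are complex, but the
#' two bracket terms are complex conjugates, so the spectrum is analytically
#' real; the evaluation uses principal-branch complex arithmetic and returns
#' the real part after checking that the imaginary residual is negligible.
#'
#' @param kappa_tilde dimensionless bending modulus (> 0).
#' @param sigma_tilde dimensionless reduced tension (> 0).
#' @param gamma_tilde dimensionless confinement strength (>= 0).
#' @param n integer mode number(s), >= 2.
#' @return mean-squared amplitude(s), dimensionless, real and positive.
#' @examples
#' eval_confined_spectrum(50, 40, 900, 3:18)
#' @export
eval_confined_spectrum <- function(kappa_tilde, sigma_tilde, gamma_tilde, n) {
  if (!is.numeric(kappa_tilde) || kappa_tilde <= 0) {
    .flick_error("flick_domain_error", "`kappa_tilde` must be > 0")
  }
  if (!is.numeric(sigma_tilde) || sigma_tilde <= 0) {
    .flick_error("flick_domain_error", "`sigma_tilde` must be > 0")
  }
  if (!is.numeric(gamma_tilde) || gamma_tilde < 0) {
    .flick_error("flick_domain_error", "`gamma_tilde` must be >= 0")
  }
  .check_modes(n)
  A <- sigma_tilde + n^2
  disc <- sigma_tilde^2 - gamma_tilde

  # nearly degenerate discriminant: bracket/s -> A^(-3/2) (1 + 5/8 t^2 + ...)
  # with t^2 = disc/A^2; series is exact enough for |t|^2 < 1e-10.
  t2 <- disc / A^2
  out <- numeric(length(n))
  small <- abs(t2) < 1e-10
  if (any(small)) {
    out[small] <- A[small]^(-1.5) * (1 + 0.625 * t2[small]) /
      (2 * pi * kappa_tilde)
  }
  if (any(!small)) {
    Ai <- A[!small]
    if (disc >= 0) {
      s <- sqrt(disc)
      if (any(Ai - s <= 0)) {
        .flick_error("flick_domain_error",
                     "sigma_tilde + n^2 - sqrt(sigma_tilde^2 - gamma_tilde) must be > 0")
      }
      out[!small] <- ((Ai - s)^(-0.5) - (Ai + s)^(-0.5)) /
        (2 * pi * kappa_tilde * s)
    } else {
      s <- sqrt(as.complex(disc))
      v <- ((Ai - s)^(-0.5) - (Ai + s)^(-0.5)) / (2 * pi * kappa_tilde * s)
      if (any(abs(Im(v)) > 1e-12 * abs(Re(v)))) {
        .flick_error("flick_numeric_error",
                     "complex-branch evaluation left a non-negligible imaginary part")
      }
      out[!small] <- Re(v)
    }
  }
  out
}

#' Evaluate a named spectrum model
#'
#' Dispatcher used by the fitting and synthetic modules.
#'
#' @param params a [spectrum_params()] object.
#' @param n integer mode number(s) >= 2.
#' @param model `"free"` (bending only), `"tension"` (bending + tension) or
#'   `"confined"` (bending + tension + skeleton confinement).
#' @return mean-squared amplitude(s).
#' @export
model_spectrum <- function(params, n, model = c("tension", "free", "confined")) {
  stopifnot(inherits(params, "spectrum_params"))
  model <- match.arg(model)
  switch(model,
    free = eval_free_spectrum(params$kappa_tilde, n),
    tension = eval_tension_spectrum(params$kappa_tilde, params$sigma_tilde, n),
    confined = eval_confined_spectrum(params$kappa_tilde, params$sigma_tilde,
                                      params$gamma_tilde, n)
  )
}

#' Convert dimensionless membrane parameters to dimensional ones
#'
#' kappa = kappa_tilde * kBT; sigma = 2 kappa sigma_tilde / <R>^2;
#' gamma = gamma_tilde * kappa / <R>^4. The mean radius must be in metres for
#' SI output. If `kBT` is omitted it is computed from the `temperature`
#' stored in `params`.
#'
#' @param params a [spectrum_params()] with `mean_radius` set (metres).
#' @param kBT thermal energy in joules (default from `params$temperature`).
#' @return a list of class `dimensional_params` with elements `kappa` (J),
#'   `sigma` (N/m), `gamma` (J/m^4) and `kBT` (J).
#' @examples
#' p <- spectrum_params(44, 0.01, 0, mean_radius = 9e-6)
#' to_dimensional(p, kBT = 4.11e-21)
#' @export
to_dimensional <- function(params, kBT = NULL) {
  stopifnot(inherits(params, "spectrum_params"))
  if (is.null(kBT)) {
    if (is.na(params$temperature)) {
      .flick_error("flick_domain_error",
                   "supply `kBT` or set `temperature` in the parameters")
    }
    kBT <- thermal_energy(params$temperature)
  }
  if (kBT <= 0) .flick_error("flick_domain_error", "`kBT` must be > 0")
  R <- params$mean_radius
  needs_R <- params$sigma_tilde != 0 || params$gamma_tilde != 0
  if (needs_R && (is.na(R) || R <= 0)) {
    .flick_error("flick_domain_error",
                 "`mean_radius` must be set and > 0 to convert tension/confinement")
  }
  kappa <- params$kappa_tilde * kBT
  sigma <- if (params$sigma_tilde == 0) 0 else 2 * kappa * params$sigma_tilde / R^2
  gamma <- if (params$gamma_tilde == 0) 0 else params$gamma_tilde * kappa / R^4
  structure(list(kappa = kappa, sigma = sigma, gamma = gamma, kBT = kBT),
            class = "dimensional_params")
}

#' Convert dimensional membrane parameters to dimensionless ones
#'
#' Inverse of [to_dimensional()]: kappa_tilde = kappa/kBT,
#' sigma_tilde = sigma <R>^2 / (2 kappa), gamma_tilde = gamma <R>^4 / kappa.
#'
#' @param kappa bending modulus (J), > 0.
#' @param sigma membrane tension (N/m), >= 0.
#' @param gamma confinement strength (J/m^4), >= 0.
#' @param mean_radius mean contour radius (m), > 0.
#' @param kBT thermal energy (J), > 0.
#' @return a [spectrum_params()] object.
#' @export
to_dimensionless <- function(kappa, sigma = 0, gamma = 0, mean_radius, kBT) {
  if (kappa <= 0 || kBT <= 0) {
    .flick_error("flick_domain_error", "`kappa` and `kBT` must be > 0")
  }
  if (mean_radius <= 0) {
    .flick_error("flick_domain_error", "`mean_radius` must be > 0")
  }
  spectrum_params(
    kappa_tilde = kappa / kBT,
    sigma_tilde = sigma * mean_radius^2 / (2 * kappa),
    gamma_tilde = gamma * mean_radius^4 / kappa,
    mean_radius = mean_radius
  )
}
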