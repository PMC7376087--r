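#' Infrared absorbance spectrum
#'
#' One absorbance spectrum on a monotonic wavenumber grid, with the sample
#' temperature carried as metadata. Descending grids (as often exported by
#' spectrometer software) are reversed to ascending on construction.
#'
#' @param wavenumber grid in cm^-1, strictly monotonic, >= 16 points.
#' @param absorbance absorbance values (AU), same length, finite.
#' @param temperature sample temperature in degrees C (metadata).
#' @return an object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, temperature = NA_real_) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance),
            length(wavenumber) == length(absorbance))
  if (length(wavenumber) < 16L) {
    .flick_error("flick_domain_error", "spectrum needs at least 16 points")
  }
  if (any(!is.finite(wavenumber)) || any(!is.finite(absorbance))) {
    .flick_error("flick_domain_error", "spectrum values must be finite")
  }
  d <- diff(wavenumber)
  if (all(d < 0)) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    .flick_error("flick_domain_error", "wavenumber grid must be strictly monotonic")
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance),
                 temperature = temperature),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("IR spectrum: %d points, %.1f-%.1f cm^-1%s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (is.na(x$temperature)) "" else sprintf(", T = %g C", x$temperature)))
  invisible(x)
}

.window_idx <- function(spectrum, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  idx <- which(spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2])
  if (length(idx) < 3L) {
    .flick_error("flick_range_error",
                 sprintf("window %g-%g cm^-1 contains fewer than 3 grid points",
                         window[1], window[2]))
  }
  idx
}

#' Locate a band position by peak picking
#'
#' Returns the wavenumber of the highest relative (local) maximum inside the
#' window — the "standard mode" band-position evaluation: the x-coordinate
#' of the grid maximum, with no interpolation, so positions are quantized to
#' the grid step. Optional three-point quadratic refinement is available but
#' off by default.
#'
#' @param spectrum an [ir_spectrum()].
#' @param window numeric (lo, hi) in cm^-1, inside the grid.
#' @param refine quadratic subgrid refinement of the maximum (default FALSE).
#' @return peak position in cm^-1.
#' @examples
#' nu <- seq(2800, 2900, by = 1)
#' sp <- ir_spectrum(nu, exp(-(nu - 2850.4)^2 / 50))
#' pick_peak(sp, c(2830, 2870))
#' @export
pick_peak <- function(spectrum, window, refine = FALSE) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  idx <- .window_idx(spectrum, window)
  y <- spectrum$absorbance[idx]
  x <- spectrum$wavenumber[idx]
  m <- length(y)
  # relative maxima: strictly above the left neighbour, at least equal to
  # the right (tolerates flat-topped digitized peaks)
  interior <- which(y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m]) + 1L
  if (!length(interior)) {
    .flick_error("flick_edge_peak_error",
                 "no relative maximum inside the window (peak on window edge?)")
  }
  best <- interior[which.max(y[interior])]
  if (!refine) return(x[best])
  off <- .parabolic_offset(y[best - 1L], y[best], y[best + 1L])
  # local grid step (grid may be non-uniform)
  x[best] + off * (x[best + 1L] - x[best - 1L]) / 2
}

#' Melting curve: band position versus temperature
#'
#' Applies [pick_peak()] to each spectrum of a temperature series and
#' assembles the positions, sorted by ascending temperature. Spectra on
#' which peak picking fails are dropped with a warning.
#'
#' @param series list of [ir_spectrum()] with temperatures set; >= 5.
#' @param window peak-search window in cm^-1 (default 2840-2860,
#'   bracketing the CH2 symmetric stretch).
#' @param refine passed to [pick_peak()].
#' @return an object of class `melting_curve`: a data frame with columns
#'   `temperature` (degrees C) and `peak_position` (cm^-1).
#' @export
build_melting_curve <- function(series, window = c(2840, 2860), refine = FALSE) {
  stopifnot(is.list(series))
  if (length(series) < 5L) {
    .flick_error("flick_domain_error", "at least 5 temperatures are required")
  }
  temps <- vapply(series, function(s) s$temperature, numeric(1))
  if (any(is.na(temps))) {
    .flick_error("flick_domain_error", "every spectrum needs a temperature")
  }
  pos <- vapply(series, function(s) {
    tryCatch(pick_peak(s, window, refine = refine),
             flickspec_error = function(e) NA_real_)
  }, numeric(1))
  if (any(is.na(pos))) {
    warning(sprintf("peak picking failed at T = %s C; entries dropped",
                    paste(temps[is.na(pos)], collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(pos)
  o <- order(temps[keep])
  melting_curve(temps[keep][o], pos[keep][o])
}

#' Construct a melting curve directly
#'
#' @param temperature temperatures in degrees C, strictly increasing.
#' @param peak_position band positions in cm^-1, same length.
#' @return a `melting_curve` data frame.
#' @export
melting_curve <- function(temperature, peak_position) {
  stopifnot(length(temperature) == length(peak_position))
  if (is.unsorted(temperature, strictly = TRUE)) {
    .flick_error("flick_domain_error", "temperatures must be strictly increasing")
  }
  structure(data.frame(temperature = temperature, peak_position = peak_position),
            class = c("melting_curve", "data.frame"))
}

# Savitzky-Golay smoothed values and derivative of a melting curve.
# The filter assumes a uniform temperature grid; mildly non-uniform series
# are resampled by linear interpolation onto a uniform grid of the same
# length before filtering.
.smooth_deriv <- function(curve, window = 7L, order = 2L) {
  tt <- curve$temperature
  nu <- curve$peak_position
  m <- length(tt)
  if (m < window) {
    .flick_error("flick_domain_error",
                 sprintf("need at least %d points for the smoothing window", window))
  }
  steps <- diff(tt)
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    grid <- seq(tt[1], tt[m], length.out = m)
    nu <- stats::approx(tt, nu, xout = grid)$y
    tt <- grid
  }
  sm <- signal::sgolayfilt(nu, p = order, n = window)
  # centered finite differences on the smoothed curve (one-sided at ends)
  d <- numeric(m)
  d[2:(m - 1)] <- (sm[3:m] - sm[1:(m - 2)]) / (tt[3:m] - tt[1:(m - 2)])
  d[1] <- (sm[2] - sm[1]) / (tt[2] - tt[1])
  d[m] <- (sm[m] - sm[m - 1]) / (tt[m] - tt[m - 1])
  list(temperature = tt, smoothed = sm, deriv = d)
}

#' Main transition temperature from the derivative maximum
#'
#' Smooths the melting curve (Savitzky-Golay, window 7, polynomial order 2),
#' differentiates it by centered finite differences, and returns the
#' temperature of the derivative maximum. The maximum is refined by the
#' vertex of a quadratic fitted over the derivative peak's half-maximum
#' region, so the refinement support scales with the transition width; for a
#' noiseless symmetric transition this reproduces the midpoint exactly. A
#' derivative maximum sitting on the edge of the temperature range — as for
#' a flat or purely linear curve — means no transition was captured and
#' raises an error.
#'
#' @param curve a [melting_curve()] with >= 7 points spanning the
#'   transition.
#' @param window,order Savitzky-Golay smoothing parameters.
#' @return the transition temperature Tm in degrees C.
#' @examples
#' mc <- generate_melting_curve(tm = 27, width = 3, noise_sd = 0)
#' estimate_tm(mc)
#' @export
estimate_tm <- function(curve, window = 7L, order = 2L) {
  stopifnot(inherits(curve, "melting_curve"))
  sd <- .smooth_deriv(curve, window, order)
  d <- sd$deriv
  tt <- sd$temperature
  m <- length(d)
  # interior maximum only; an edge maximum signals no captured transition
  imax <- which.max(d)
  guard <- max(2L, (window + 1L) %/% 2L)
  if (imax <= guard || imax >= m - guard + 1L) {
    .flick_error("flick_no_transition_error",
                 "derivative maximum at the edge of the temperature range; no transition detected")
  }
  # refine by the vertex of a quadratic fitted over the derivative peak's
  # half-maximum region: the refinement support scales with the transition
  # width, which keeps the estimate stable when the derivative peak is flat
  # and noisy (wide transitions), and is exact for noiseless peaks
  half <- (d[imax] + min(d)) / 2
  i0 <- imax
  while (i0 > 2L && d[i0 - 1L] > half) i0 <- i0 - 1L
  i1 <- imax
  while (i1 < m - 1L && d[i1 + 1L] > half) i1 <- i1 + 1L
  if (i1 - i0 < 4L) {
    i0 <- max(2L, imax - 2L)
    i1 <- min(m - 1L, imax + 2L)
  }
  w <- i0:i1
  cf <- stats::coef(stats::lm(d[w] ~ tt[w] + I(tt[w]^2)))
  vertex <- -cf[[2]] / (2 * cf[[3]])
  if (!is.finite(vertex) || cf[[3]] >= 0 || vertex < tt[i0] || vertex > tt[i1]) {
    # degenerate curvature: fall back to a 3-point parabolic refinement
    off <- .parabolic_offset(d[imax - 1L], d[imax], d[imax + 1L])
    vertex <- tt[imax] + off * (tt[imax + 1L] - tt[imax - 1L]) / 2
  }
  vertex
}

#' Thermal-expansivity proxy beta(T)
#'
#' beta(T) = (d nu_s / dT) / nu_s(T), computed from the Savitzky-Golay
#' smoothed melting curve (same smoothing as [estimate_tm()]). By analogy
#' with the volumetric thermal expansion coefficient (dV/dT)/V, beta serves
#' as a spectroscopic proxy for membrane thermal expansivity; it peaks in
#' the melting range where conformational disorder grows fastest.
#'
#' @inheritParams estimate_tm
#' @return a data frame with columns `temperature` and `beta` (per degree C)
#'   at the interior points of the curve.
#' @export
compute_beta <- function(curve, window = 7L, order = 2L) {
  stopifnot(inherits(curve, "melting_curve"))
  if (nrow(curve) < 5L) {
    .flick_error("flick_domain_error", "at least 5 points are required")
  }
  sd <- .smooth_deriv(curve, window = min(window, nrow(curve) - (1 - nrow(curve) %% 2)),
                      order = order)
  if (any(sd$smoothed == 0)) {
    .flick_error("flick_domain_error", "band position of zero is unphysical")
  }
  m <- length(sd$deriv)
  keep <- 2:(m - 1)
  data.frame(temperature = sd$temperature[keep],
             beta = sd$deriv[keep] / sd$smoothed[keep])
}

#' Integrated band area with linear baseline subtraction
#'
#' Subtracts the straight line through the two endpoints of the integration
#' range and integrates the remainder by the trapezoidal rule — the standard
#' treatment for an isolated band such as the carbonyl stretch of
#' membrane-solubilized W(CO)6 at 1960-1990 cm^-1. The area may be
#' normalized by a reference intensity (e.g. the CH2 stretching peak height
#' at 25 C) to compare samples.
#'
#' @param spectrum an [ir_spectrum()].
#' @param range numeric (lo, hi) integration limits in cm^-1.
#' @param norm_ref positive reference intensity to divide by (optional).
#' @param baseline subtract the endpoint-anchored linear baseline
#'   (default TRUE).
#' @return integrated area (AU cm^-1, divided by `norm_ref` if given).
#' @export
integrate_band <- function(spectrum, range = c(1960, 1990), norm_ref = NULL,
                           baseline = TRUE) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  idx <- .window_idx(spectrum, range)
  x <- spectrum$wavenumber[idx]
  y <- spectrum$absorbance[idx]
  if (baseline) {
    m <- length(x)
    base <- y[1] + (y[m] - y[1]) * (x - x[1]) / (x[m] - x[1])
    y <- y - base
  }
  area <- pracma::trapz(x, y)
  gross <- pracma::trapz(x, abs(y))
  if (area < -0.01 * gross) {
    warning("net band area is negative; baseline anchoring may have failed",
            call. = FALSE)
  }
  if (!is.null(norm_ref)) {
    if (norm_ref <= 0) {
      .flick_error("flick_domain_error", "`norm_ref` must be > 0")
    }
    area <- area / norm_ref
  }
  area
}

#' Two-Gaussian decomposition of the carbonyl band
#'
#' Least-squares fit of a linear baseline plus two Gaussian components to
#' the C-O antisymmetric stretching band of membrane-solubilized W(CO)6.
#' The component positions — 1981 cm^-1 (probe deep in the hydrophobic
#' core; narrow, homogeneous environment) and 1975 cm^-1 (probe at the
#' interfacial region; wider) — are vibrational constants of the probe and
#' are held fixed by default: refloating them per spectrum adds more
#' variance to the area fraction than a single noisy band can support.
#' Set `center_tol > 0` to let each center float inside a box of that
#' half-width. The core component is constrained to be the narrower one.
#' The reported `f1 = area1 / (area1 + area2)` is the core-localized area
#' fraction.
#'
#' @param spectrum an [ir_spectrum()] covering the band.
#' @param range fit range in cm^-1 (default 1960-1990).
#' @param centers component centers, core first (cm^-1).
#' @param center_tol box half-width on the centers (cm^-1); 0 (default)
#'   fixes them.
#' @return an object of class `band_fit` with fields `centers`, `sigmas`
#'   (Gaussian SDs, cm^-1), `areas` (amplitude * sigma * sqrt(2 pi)), `f1`,
#'   `rss` and `fitted` values.
#' @examples
#' sp <- generate_co_band(areas = c(3, 1), noise_sd = 0)
#' fit_two_gaussians(sp)$f1
#' @export
fit_two_gaussians <- function(spectrum, range = c(1960, 1990),
                              centers = c(1981, 1975), center_tol = 0) {
  stopifnot(inherits(spectrum, "ir_spectrum"), length(centers) == 2L)
  idx <- .window_idx(spectrum, range)
  x <- spectrum$wavenumber[idx]
  y <- spectrum$absorbance[idx]
  grid_step <- stats::median(diff(x))
  m <- length(x)
  # starting values: endpoint chord as baseline, residual heights at the
  # centers (floored at 5% of the band so a vanishing component still has a
  # non-degenerate gradient)
  b1_0 <- (y[m] - y[1]) / (x[m] - x[1])
  b0_0 <- y[1] - b1_0 * x[1]
  resid0 <- y - (b0_0 + b1_0 * x)
  h <- function(cc) max(resid0[which.min(abs(x - cc))], 0.05 * max(resid0), 1e-6)
  df <- data.frame(x = x, y = y)
  # width constraint (core narrower): sigma1 = wfrac * sigma2, wfrac in (0, 1]
  start <- list(b0 = b0_0, b1 = b1_0, A1 = h(centers[1]), A2 = h(centers[2]),
                s2 = 3, wfrac = 0.5)
  lower <- c(b0 = -Inf, b1 = -Inf, A1 = 0, A2 = 0, s2 = grid_step / 2,
             wfrac = 0.02)
  upper <- c(b0 = Inf, b1 = Inf, A1 = Inf, A2 = Inf, s2 = 15, wfrac = 1)
  if (center_tol > 0) {
    start <- c(start, list(c1 = centers[1], c2 = centers[2]))
    lower <- c(lower, c1 = centers[1] - center_tol, c2 = centers[2] - center_tol)
    upper <- c(upper, c1 = centers[1] + center_tol, c2 = centers[2] + center_tol)
  }
  band_model <- function(par) {
    c1 <- if (center_tol > 0) par[["c1"]] else centers[1]
    c2 <- if (center_tol > 0) par[["c2"]] else centers[2]
    par[["b0"]] + par[["b1"]] * x +
      par[["A1"]] * exp(-(x - c1)^2 / (2 * (par[["wfrac"]] * par[["s2"]])^2)) +
      par[["A2"]] * exp(-(x - c2)^2 / (2 * par[["s2"]]^2))
  }
  # nls.lm rather than a formula interface: a vanished component makes the
  # width parameters jointly unidentified (a benign ridge), which the
  # Levenberg-Marquardt iteration handles but a post-hoc nls object refuses
  out <- minpack.lm::nls.lm(
    par = unlist(start), lower = lower, upper = upper,
    fn = function(par) y - band_model(par),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (out$info == 0 || out$info == 9) {
    .flick_error("flick_fit_error",
                 paste0("two-Gaussian band fit failed: ", out$message))
  }
  p <- as.list(out$par)
  p$c1 <- if (center_tol > 0) p$c1 else centers[1]
  p$c2 <- if (center_tol > 0) p$c2 else centers[2]
  s1 <- p$wfrac * p$s2
  if (min(s1, p$s2) < grid_step) {
    .flick_error("flick_degeneracy_error",
                 "a fitted component collapsed below the grid step")
  }
  areas <- c(p$A1 * s1, p$A2 * p$s2) * sqrt(2 * pi)
  f1 <- if (sum(areas) > 0) areas[1] / sum(areas) else NA_real_
  fitted_vals <- band_model(out$par)
  structure(list(centers = c(p$c1, p$c2), sigmas = c(s1, p$s2),
                 areas = areas, f1 = f1,
                 rss = sum((y - fitted_vals)^2),
                 fitted = fitted_vals, wavenumber = x),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat("Two-Gaussian carbonyl band decomposition\n")
  cat(sprintf("  component 1 (core):       center %.2f cm^-1, sigma %.2f, area %.4g\n",
              x$centers[1], x$sigmas[1], x$areas[1]))
  cat(sprintf("  component 2 (interface):  center %.2f cm^-1, sigma %.2f, area %.4g\n",
              x$centers[2], x$sigmas[2], x$areas[2]))
  cat(sprintf("  f1 (core area fraction):  %.4f\n", x$f1))
  invisible(x)
}
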