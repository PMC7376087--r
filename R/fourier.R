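#' Polar contour of an equatorial membrane section
#'
#' A closed contour sampled in polar coordinates about `center`: angles
#' `theta` (radians, one period) and radial distances `radius` (pixels or
#' metres). Angles need not start at zero but must cover essentially the full
#' circle for the Fourier decomposition to be meaningful.
#'
#' @param theta angles in radians, same length as `radius`.
#' @param radius radial distances, all > 0.
#' @param center numeric length-2, (x, y) position of the polar origin.
#' @return an object of class `flick_contour`.
#' @export
contour_polar <- function(theta, radius, center = c(0, 0)) {
  stopifnot(is.numeric(theta), is.numeric(radius),
            length(theta) == length(radius),
            is.numeric(center), length(center) == 2L)
  if (any(!is.finite(theta)) || any(!is.finite(radius))) {
    .flick_error("flick_domain_error", "contour samples must be finite")
  }
  if (any(radius <= 0)) {
    .flick_error("flick_domain_error", "all contour radii must be > 0")
  }
  structure(list(theta = as.numeric(theta), radius = as.numeric(radius),
                 center = as.numeric(center)),
            class = "flick_contour")
}

#' @export
print.flick_contour <- function(x, ...) {
  cat(sprintf("Polar contour: %d samples, mean radius %.3f, center (%.2f, %.2f)\n",
              length(x$theta), mean(x$radius), x$center[1], x$center[2]))
  invisible(x)
}

# sort angles into [0, 2pi) and check angular coverage
.order_contour <- function(contour, min_coverage = 0.95) {
  th <- contour$theta %% (2 * pi)
  o <- order(th)
  th <- th[o]
  r <- contour$radius[o]
  if (anyDuplicated(th)) {
    keep <- !duplicated(th)
    th <- th[keep]
    r <- r[keep]
  }
  gaps <- diff(c(th, th[1] + 2 * pi))
  coverage <- 1 - (max(gaps) - mean(gaps)) / (2 * pi)
  if (coverage < min_coverage) {
    .flick_error("flick_resolution_error",
                 sprintf("contour covers only ~%.0f%% of the circle", 100 * coverage))
  }
  list(theta = th, radius = r)
}

# periodic trapezoidal quadrature of f over one closed period
.periodic_trapz <- function(theta, f) {
  th <- c(theta, theta[1] + 2 * pi)
  ff <- c(f, f[1])
  sum(diff(th) * (head(ff, -1) + tail(ff, -1)) / 2)
}

#' Fourier modes of a single contour
#'
#' Per-frame mean radius and Fourier coefficients of the relative radial
#' displacement, from the representation
#' `r(theta) = R (1 + sum_n (a_n cos(n theta) + b_n sin(n theta)))`.
#'
#' @param mean_radius per-frame mean radius R.
#' @param a cosine coefficients a_n, n = 1..n_max.
#' @param b sine coefficients b_n, same length.
#' @return an object of class `contour_modes`.
#' @export
contour_modes <- function(mean_radius, a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2L, is.numeric(mean_radius), mean_radius > 0)
  structure(list(mean_radius = mean_radius, a = as.numeric(a),
                 b = as.numeric(b), n_max = length(a)),
            class = "contour_modes")
}

#' Decompose a polar contour into Fourier modes
#'
#' Computes `R = (1/2pi) integral r dtheta` and, for n = 1..n_max,
#' `a_n = (1/(pi R)) integral r cos(n theta) dtheta` and
#' `b_n = (1/(pi R)) integral r sin(n theta) dtheta`, using periodic
#' trapezoidal quadrature after sorting the angles into one period.
#' Trapezoidal quadrature on a closed period is spectrally accurate for
#' smooth contours, so round-tripping through [reconstruct_contour()]
#' recovers coefficients essentially to machine precision on uniform grids.
#'
#' @param contour a [contour_polar()] object with at least 64 samples.
#' @param n_max highest mode to compute; at most `floor(samples/4)`.
#' @return a [contour_modes()] object.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' cm <- decompose_contour(contour_polar(th, 50 * (1 + 0.01 * cos(3 * th))), 10)
#' cm$a[3]
#' @export
decompose_contour <- function(contour, n_max = 18L) {
  stopifnot(inherits(contour, "flick_contour"))
  ns <- length(contour$theta)
  if (ns < 64L) {
    .flick_error("flick_resolution_error",
                 sprintf("contour has %d samples; at least 64 required", ns))
  }
  if (n_max < 2L || n_max > floor(ns / 4)) {
    .flick_error("flick_resolution_error",
                 sprintf("n_max = %d outside 2..floor(samples/4) = %d", n_max, floor(ns / 4)))
  }
  oc <- .order_contour(contour)
  th <- oc$theta
  r <- oc$radius
  R <- .periodic_trapz(th, r) / (2 * pi)
  a <- b <- numeric(n_max)
  for (n in seq_len(n_max)) {
    a[n] <- .periodic_trapz(th, r * cos(n * th)) / (pi * R)
    b[n] <- .periodic_trapz(th, r * sin(n * th)) / (pi * R)
  }
  contour_modes(R, a, b)
}

#' Reconstruct a contour from its Fourier modes
#'
#' Evaluates `r(theta) = R (1 + sum_n (a_n cos(n theta) + b_n sin(n theta)))`
#' on the supplied angular grid.
#'
#' @param modes a [contour_modes()] object.
#' @param theta_grid angles (radians) at which to evaluate.
#' @param center polar origin passed through to the contour.
#' @return a [contour_polar()] object.
#' @export
reconstruct_contour <- function(modes, theta_grid, center = c(0, 0)) {
  stopifnot(inherits(modes, "contour_modes"), is.numeric(theta_grid))
  n <- seq_len(modes$n_max)
  # outer(theta, n) keeps this vectorized for dense grids
  C <- cos(outer(theta_grid, n))
  S <- sin(outer(theta_grid, n))
  r <- modes$mean_radius * (1 + as.vector(C %*% modes$a + S %*% modes$b))
  contour_polar(theta_grid, r, center = center)
}

#' Stack per-frame Fourier modes into a series
#'
#' @param modes_list a list of [contour_modes()] objects with identical
#'   `n_max`.
#' @return an object of class `mode_series` holding frame-by-mode coefficient
#'   matrices `a` and `b` and the per-frame mean radii.
#' @export
as_mode_series <- function(modes_list) {
  if (inherits(modes_list, "mode_series")) return(modes_list)
  stopifnot(is.list(modes_list), length(modes_list) >= 1L)
  nmax <- vapply(modes_list, function(m) m$n_max, integer(1))
  if (length(unique(nmax)) != 1L) {
    .flick_error("flick_shape_error", "all frames must share the same n_max")
  }
  structure(list(
    a = do.call(rbind, lapply(modes_list, `[[`, "a")),
    b = do.call(rbind, lapply(modes_list, `[[`, "b")),
    mean_radius = vapply(modes_list, `[[`, numeric(1), "mean_radius"),
    n_max = nmax[1]
  ), class = "mode_series")
}

#' Fluctuation spectrum across frames
#'
#' Per-mode mean-squared fluctuation amplitude
#' `<delta_n^2> = (<a_n^2> - <a_n>^2) + (<b_n^2> - <b_n>^2)` over frames,
#' using population moments (divide by N), with standard error
#' `se_n = <delta_n^2> sqrt(2/N)` from Gaussian-amplitude theory for
#' independent frames. Mode 1 (rigid translation, absorbed by per-frame
#' centering) is computed upstream but excluded from the spectrum, which
#' starts at n = 2.
#'
#' @param series a `mode_series` or list of [contour_modes()] with >= 2
#'   frames.
#' @return an object of class `fluct_spectrum` with fields `n`, `delta2`,
#'   `se`, `frames` and `mean_radius` (the across-frame average of per-frame
#'   R, which is what enters the reduced tension and confinement).
#' @examples
#' p <- spectrum_params(44, 0.01, mean_radius = 50)
#' ms <- sample_contour_modes(p, model = "tension", n_frames = 2000, seed = 1)
#' sp <- estimate_spectrum(ms)
#' head(as.data.frame(sp))
#' @export
estimate_spectrum <- function(series) {
  ms <- as_mode_series(series)
  N <- nrow(ms$a)
  if (N < 2L) {
    .flick_error("flick_shape_error", "at least 2 frames are required")
  }
  pop_var <- function(m) colMeans(m^2) - colMeans(m)^2
  delta2 <- pop_var(ms$a) + pop_var(ms$b)
  n <- 2:ms$n_max
  delta2 <- delta2[n]
  structure(list(
    n = n,
    delta2 = delta2,
    se = delta2 * sqrt(2 / N),
    frames = N,
    mean_radius = mean(ms$mean_radius)
  ), class = "fluct_spectrum")
}

#' @export
print.fluct_spectrum <- function(x, ...) {
  cat(sprintf("Fluctuation spectrum: modes %d..%d, %d frames, <R> = %.3f\n",
              min(x$n), max(x$n), x$frames, x$mean_radius))
  print(utils::head(as.data.frame(x), 5))
  if (length(x$n) > 5) cat(sprintf("  ... %d more modes\n", length(x$n) - 5))
  invisible(x)
}

#' @export
as.data.frame.fluct_spectrum <- function(x, ...) {
  data.frame(n = x$n, delta2 = x$delta2, se = x$se,
             frames = x$frames, mean_radius = x$mean_radius)
}
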