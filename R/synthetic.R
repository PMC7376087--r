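# Synthetic inputs for every stage of the pipeline. Each generator is a
# pure function of its parameters and an explicit seed, so fixtures are
# reproduced bit-identically at test time instead of being stored.

#' Sample Fourier mode amplitudes from a spectrum model
#'
#' Draws per-frame mode amplitudes a_n, b_n independently from zero-mean
#' normal distributions with Var(a_n) = Var(b_n) = `<delta_n^2>`/2, so that
#' their summed variance matches the model spectrum — the equipartition
#' statistics of independent harmonic modes, which is all the amplitude
#' analysis assumes. Frames are temporally independent (mode relaxation
#' dynamics are not modelled). Mode 1 is set to zero, mirroring the
#' translation mode removed by per-frame centering.
#'
#' @param params a [spectrum_params()] with `mean_radius` set (used as the
#'   per-frame radius R).
#' @param model `"tension"` (vesicle) or `"confined"` (red blood cell);
#'   `"free"` also accepted.
#' @param n_max highest mode (default 18).
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed; the output is bit-identical for equal inputs.
#' @return a `mode_series` (see [as_mode_series()]).
#' @examples
#' p <- spectrum_params(44, 0.01, mean_radius = 50)
#' ms <- sample_contour_modes(p, "tension", n_frames = 1000, seed = 42)
#' estimate_spectrum(ms)
#' @export
sample_contour_modes <- function(params, model = c("tension", "confined", "free"),
                                 n_max = 18L, n_frames, seed) {
  stopifnot(inherits(params, "spectrum_params"), n_frames >= 1L, n_max >= 2L)
  if (is.na(params$mean_radius)) {
    .flick_error("flick_domain_error", "`params$mean_radius` must be set")
  }
  model <- match.arg(model)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n <- 2:n_max
  sd_coef <- sqrt(model_spectrum(params, n, model = model) / 2)
  set.seed(as.integer(seed))
  za <- matrix(rnorm(n_frames * length(n)), nrow = n_frames)
  zb <- matrix(rnorm(n_frames * length(n)), nrow = n_frames)
  a <- cbind(0, sweep(za, 2L, sd_coef, `*`))
  b <- cbind(0, sweep(zb, 2L, sd_coef, `*`))
  structure(list(a = a, b = b,
                 mean_radius = rep(params$mean_radius, n_frames),
                 n_max = as.integer(n_max)),
            class = "mode_series")
}

#' Rendering parameters for synthetic microscopy frames
#'
#' @param image_size image side length in pixels (square frames).
#' @param ring_sigma Gaussian cross-section SD of the membrane ring (px).
#' @param peak_intensity ring amplitude above background (AU).
#' @param background background level (AU).
#' @param noise_sd additive Gaussian noise SD (AU); the signal-to-noise
#'   ratio is `peak_intensity / noise_sd`.
#' @param noise_model `"gaussian"` (additive) or `"poisson"` (intensity
#'   values used as Poisson means).
#' @param invert render a dark ring on a bright background
#'   (phase-contrast-like) instead of a bright ring (fluorescence-like).
#' @return an object of class `render_params`.
#' @export
render_params <- function(image_size = 128L, ring_sigma = 2, peak_intensity = 200,
                          background = 20, noise_sd = 0,
                          noise_model = c("gaussian", "poisson"),
                          invert = FALSE) {
  stopifnot(image_size >= 64L, ring_sigma > 0, peak_intensity >= 0,
            background >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size), ring_sigma = ring_sigma,
                 peak_intensity = peak_intensity, background = background,
                 noise_sd = noise_sd, noise_model = match.arg(noise_model),
                 invert = invert),
            class = "render_params")
}

#' Render a contour as a synthetic microscopy frame
#'
#' Produces `intensity(x, y) = background + peak * exp(-d^2 / (2 sigma^2))`
#' where `d` is the signed radial distance from the pixel to the contour at
#' the pixel's polar angle — a fluorescent membrane ring with Gaussian
#' cross-section. With `invert = TRUE` the ring is dark on a bright
#' background. Noise is applied per the noise model.
#'
#' @param contour a [contour_polar()]; its center is used as the ring
#'   center in image coordinates.
#' @param rp a [render_params()].
#' @param seed integer seed for the noise (only needed when noise is on).
#' @return numeric image matrix (rows = y, columns = x).
#' @export
render_frame <- function(contour, rp = render_params(), seed = NULL) {
  stopifnot(inherits(contour, "flick_contour"), inherits(rp, "render_params"))
  half <- rp$image_size / 2
  if (max(contour$radius) + 3 * rp$ring_sigma >= half) {
    .flick_error("flick_geometry_error",
                 "contour plus 3 ring sigmas exceeds the image half-size")
  }
  oc <- .order_contour(contour)
  cx <- contour$center[1]
  cy <- contour$center[2]
  xs <- seq_len(rp$image_size)
  dx <- matrix(xs, rp$image_size, rp$image_size, byrow = TRUE) - cx
  dy <- matrix(xs, rp$image_size, rp$image_size) - cy
  ang <- atan2(dy, dx) %% (2 * pi)
  rpix <- sqrt(dx^2 + dy^2)
  # contour radius at each pixel angle, linear interpolation with wraparound
  th <- c(oc$theta[length(oc$theta)] - 2 * pi, oc$theta, oc$theta[1] + 2 * pi)
  rr <- c(oc$radius[length(oc$radius)], oc$radius, oc$radius[1])
  r0 <- matrix(stats::approx(th, rr, xout = as.vector(ang))$y,
               rp$image_size, rp$image_size)
  ring <- exp(-(rpix - r0)^2 / (2 * rp$ring_sigma^2))
  img <- if (rp$invert) {
    rp$background + rp$peak_intensity * (1 - ring)
  } else {
    rp$background + rp$peak_intensity * ring
  }
  if (rp$noise_model == "poisson") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img)) * 1.0
  } else if (rp$noise_sd > 0) {
    if (is.null(seed)) {
      .flick_error("flick_domain_error", "`seed` is required when noise is on")
    }
    set.seed(as.integer(seed))
    img <- img + matrix(rnorm(length(img), 0, rp$noise_sd), nrow(img), ncol(img))
  }
  img
}

#' Simulate a full video stack of a fluctuating vesicle or cell
#'
#' Samples `n_frames` of mode amplitudes from the model spectrum, evaluates
#' each contour on a dense angular grid, and renders each frame. The
#' generating contours are returned alongside the frames so detection
#' accuracy can be scored against ground truth.
#'
#' @inheritParams sample_contour_modes
#' @param rp a [render_params()].
#' @param center ring center in image coordinates (x, y); defaults to the
#'   image center.
#' @param theta_points angular samples per rendered contour.
#' @return a list with `frames` (list of matrices), `contours` (ground
#'   truth), and `modes` (the sampled `mode_series`).
#' @export
simulate_stack <- function(params, model = "tension", n_max = 18L, n_frames,
                           rp = render_params(), center = NULL,
                           theta_points = 720L, seed) {
  ms <- sample_contour_modes(params, model = model, n_max = n_max,
                             n_frames = n_frames, seed = seed)
  if (is.null(center)) center <- rep((rp$image_size + 1) / 2, 2)
  th <- seq(0, 2 * pi, length.out = theta_points + 1L)[-(theta_points + 1L)]
  frames <- vector("list", n_frames)
  contours <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    cm <- contour_modes(ms$mean_radius[i], ms$a[i, ], ms$b[i, ])
    contours[[i]] <- reconstruct_contour(cm, th, center = center)
    frames[[i]] <- render_frame(contours[[i]], rp, seed = seed + i)
  }
  list(frames = frames, contours = contours, modes = ms)
}

#' Generate a synthetic sigmoidal melting curve
#'
#' Band position versus temperature follows a logistic transition
#' `nu(T) = nu_gel + delta_nu / (1 + exp(-(T - tm) / width))` plus optional
#' Gaussian noise — the shape of CH2 symmetric-stretch melting curves, where
#' the band position steps up by ~2-3 cm^-1 across the gel-to-fluid
#' transition.
#'
#' @param tm transition midpoint (degrees C).
#' @param width transition width (degrees C), > 0.
#' @param nu_gel low-temperature band position (cm^-1).
#' @param delta_nu transition amplitude (cm^-1).
#' @param t_range numeric (lo, hi, step) temperature grid in degrees C.
#' @param noise_sd Gaussian noise SD on the positions (cm^-1).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param as_spectra if TRUE, wrap each position into a full synthetic
#'   Gaussian band spectrum (2800-2900 cm^-1, 1 cm^-1 grid) so the
#'   peak-picking stage is exercised; returns a list of [ir_spectrum()].
#' @return a [melting_curve()], or a list of [ir_spectrum()] when
#'   `as_spectra = TRUE`.
#' @examples
#' estimate_tm(generate_melting_curve(tm = 27, noise_sd = 0.05, seed = 7))
#' @export
generate_melting_curve <- function(tm, width = 3, nu_gel = 2850.5,
                                   delta_nu = 2.5, t_range = c(5, 70, 1),
                                   noise_sd = 0, seed = NULL,
                                   as_spectra = FALSE) {
  stopifnot(width > 0, length(t_range) == 3L, t_range[3] > 0, noise_sd >= 0)
  tt <- seq(t_range[1], t_range[2], by = t_range[3])
  nu <- nu_gel + delta_nu / (1 + exp(-(tt - tm) / width))
  if (noise_sd > 0) {
    if (is.null(seed)) {
      .flick_error("flick_domain_error", "`seed` is required when noise is on")
    }
    set.seed(as.integer(seed))
    nu <- nu + rnorm(length(nu), 0, noise_sd)
  }
  if (!as_spectra) return(melting_curve(tt, nu))
  grid <- seq(2800, 2900, by = 1)
  lapply(seq_along(tt), function(i) {
    ir_spectrum(grid, exp(-(grid - nu[i])^2 / (2 * 6^2)), temperature = tt[i])
  })
}

#' Generate a synthetic two-component carbonyl band
#'
#' Sum of two Gaussians (given integrated areas, centers and SDs) plus a
#' linear baseline and optional noise, on a 0.5 cm^-1 grid over 1950-2000
#' cm^-1 — the profile of the C-O antisymmetric stretch of
#' membrane-solubilized W(CO)6 with its core (1981 cm^-1, narrow) and
#' interfacial (1975 cm^-1, wide) components.
#'
#' @param areas numeric (A1, A2): integrated areas of the two components,
#'   >= 0 (core first).
#' @param centers component centers (cm^-1).
#' @param sigmas component Gaussian SDs (cm^-1).
#' @param baseline numeric (intercept, slope): baseline
#'   `b0 + b1 * (nu - 1975)` in AU.
#' @param noise_sd Gaussian noise SD (AU).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param temperature carried into the spectrum metadata.
#' @return an [ir_spectrum()].
#' @examples
#' fit_two_gaussians(generate_co_band(areas = c(3, 1)))$f1
#' @export
generate_co_band <- function(areas, centers = c(1981, 1975),
                             sigmas = c(1.5, 3.0), baseline = c(0, 0),
                             noise_sd = 0, seed = NULL,
                             temperature = NA_real_) {
  stopifnot(length(areas) == 2L, all(areas >= 0), all(sigmas > 0))
  grid <- seq(1950, 2000, by = 0.5)
  amp <- areas / (sigmas * sqrt(2 * pi))
  y <- baseline[1] + baseline[2] * (grid - 1975) +
    amp[1] * exp(-(grid - centers[1])^2 / (2 * sigmas[1]^2)) +
    amp[2] * exp(-(grid - centers[2])^2 / (2 * sigmas[2]^2))
  if (noise_sd > 0) {
    if (is.null(seed)) {
      .flick_error("flick_domain_error", "`seed` is required when noise is on")
    }
    set.seed(as.integer(seed))
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  ir_spectrum(grid, y, temperature = temperature)
}
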