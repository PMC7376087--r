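# shared fixtures built in code

# noiseless fluctuation spectrum evaluated straight from a model
model_fluct_spectrum <- function(kappa_tilde, sigma_tilde = 0, gamma_tilde = 0,
                                 n = 2:18, frames = 1000L, mean_radius = 50,
                                 se = 0) {
  p <- spectrum_params(kappa_tilde, sigma_tilde, gamma_tilde,
                       mean_radius = mean_radius)
  model <- if (gamma_tilde > 0) "confined" else if (sigma_tilde > 0) "tension" else "free"
  d2 <- model_spectrum(p, n, model = model)
  structure(list(n = n, delta2 = d2,
                 se = if (length(se) == 1L) rep(se, length(n)) else se,
                 frames = frames, mean_radius = mean_radius),
            class = "fluct_spectrum")
}

# uniform angular grid with m points (no duplicated endpoint)
theta_grid <- function(m) seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]

# independent slow oracle for Fourier coefficients: Riemann/trapezoid sums
# on a 10x denser uniform resampling of the contour
dense_grid_modes <- function(rfun, n_max, m = 7200L) {
  th <- theta_grid(m)
  r <- rfun(th)
  h <- 2 * pi / m
  R <- sum(r) * h / (2 * pi)
  a <- vapply(seq_len(n_max), function(n) sum(r * cos(n * th)) * h / (pi * R),
              numeric(1))
  b <- vapply(seq_len(n_max), function(n) sum(r * sin(n * th)) * h / (pi * R),
              numeric(1))
  list(mean_radius = R, a = a, b = b)
}

# analytic radius function of an origin-centered ellipse
ellipse_radius <- function(theta, a, b) a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
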