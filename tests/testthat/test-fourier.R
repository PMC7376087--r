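# contour Fourier decomposition and spectrum estimation

test_that("a perfect circle decomposes to its radius and zero coefficients", {
  th <- theta_grid(360)
  cm <- decompose_contour(contour_polar(th, rep(50, 360)), 18)
  expect_equal(cm$mean_radius, 50, tolerance = 1e-12)
  expect_lt(max(abs(c(cm$a, cm$b))), 1e-12)
})

test_that("single-mode contours recover their coefficient by orthogonality", {
  th <- theta_grid(360)
  cm <- decompose_contour(contour_polar(th, 50 * (1 + 0.01 * cos(3 * th))), 10)
  expect_equal(cm$a[3], 0.01, tolerance = 1e-10)
  expect_lt(max(abs(c(cm$a[-3], cm$b))), 1e-10)
})

test_that("mixed-mode contours agree with a dense-grid quadrature oracle", {
  rfun <- function(th) 50 * (1 + 0.004 * sin(7 * th) + 0.002 * cos(2 * th))
  th <- theta_grid(720)
  cm <- decompose_contour(contour_polar(th, rfun(th)), 10)
  oracle <- dense_grid_modes(rfun, 10)
  expect_equal(cm$b[7], 0.004, tolerance = 1e-9)
  expect_equal(cm$a[2], 0.002, tolerance = 1e-9)
  expect_equal(cm$a, oracle$a, tolerance = 1e-8)
  expect_equal(cm$b, oracle$b, tolerance = 1e-8)
  expect_equal(cm$mean_radius, oracle$mean_radius, tolerance = 1e-8)
})

test_that("decomposition works on shuffled and offset angle samples", {
  rfun <- function(th) 40 * (1 + 0.02 * cos(4 * th))
  th <- (theta_grid(500) + 1.3)    # starts mid-period, exceeds 2*pi
  idx <- sample(length(th))        # unordered input
  cm <- decompose_contour(contour_polar(th[idx], rfun(th[idx])), 8)
  expect_equal(cm$a[4], 0.02, tolerance = 1e-8)
})

test_that("reconstruct is the inverse of decompose", {
  set.seed(11)
  for (rep in 1:5) {
    n_max <- sample(5:18, 1)
    a <- runif(n_max, -0.05, 0.05)
    b <- runif(n_max, -0.05, 0.05)
    modes <- contour_modes(50, a, b)
    th <- theta_grid(max(64L, 8L * n_max))
    back <- decompose_contour(reconstruct_contour(modes, th), n_max)
    expect_equal(back$a, a, tolerance = 1e-8)
    expect_equal(back$b, b, tolerance = 1e-8)
    expect_equal(back$mean_radius, 50, tolerance = 1e-8)
  }
})

test_that("a single cosine mode peaks at its expected angles", {
  modes <- contour_modes(50, c(0, 0, 0, 0, 0.05), rep(0, 5))
  th <- theta_grid(1000)
  cont <- reconstruct_contour(modes, th)
  peaks_at <- th[which(diff(sign(diff(cont$radius))) == -2) + 1]
  expect_equal(peaks_at[1:2], c(2 * pi / 5, 4 * pi / 5), tolerance = 0.01)
  expect_equal(max(cont$radius), cont$radius[1], tolerance = 1e-10)
})

test_that("spectrum estimation uses population moments", {
  m0 <- contour_modes(50, rep(0, 10), rep(0, 10))
  # identical frames -> zero variance
  sp <- estimate_spectrum(list(m0, m0, m0))
  expect_true(all(sp$delta2 == 0))
  expect_equal(sp$n, 2:10)
  expect_equal(sp$frames, 3L)
  # two frames with a_3 = +/- 0.02: population variance 4e-4 exactly
  a <- rep(0, 10)
  ap <- a; ap[3] <- 0.02
  am <- a; am[3] <- -0.02
  sp2 <- estimate_spectrum(list(contour_modes(50, ap, a),
                                contour_modes(50, am, a)))
  expect_identical(sp2$delta2[sp2$n == 3], 4e-4)
  expect_equal(sp2$se[sp2$n == 3], 4e-4 * sqrt(2 / 2))
})

test_that("spectrum is invariant to rigid rotation of all contours", {
  p <- spectrum_params(44, 0.01, mean_radius = 50)
  ms <- sample_contour_modes(p, "tension", n_frames = 50, seed = 3)
  th <- theta_grid(256)
  rot <- 0.7
  sp0 <- estimate_spectrum(lapply(1:50, function(i) {
    decompose_contour(reconstruct_contour(
      contour_modes(50, ms$a[i, ], ms$b[i, ]), th), 18)
  }))
  sp1 <- estimate_spectrum(lapply(1:50, function(i) {
    cont <- reconstruct_contour(contour_modes(50, ms$a[i, ], ms$b[i, ]), th)
    decompose_contour(contour_polar(cont$theta + rot, cont$radius), 18)
  }))
  expect_equal(sp1$delta2, sp0$delta2, tolerance = 1e-10)
})

test_that("sample variance converges to the model variance at the 1/sqrt(N) rate", {
  p <- spectrum_params(44, 0.01, mean_radius = 50)
  model <- eval_tension_spectrum(44, 0.01, 2:18)
  for (N in c(1e3, 1e4)) {
    sp <- estimate_spectrum(sample_contour_modes(p, "tension",
                                                 n_frames = N, seed = 99))
    z <- abs(sp$delta2 - model) / (model * sqrt(2 / N))
    expect_lt(max(z), 4)
  }
})

test_that("shape and resolution errors are raised", {
  th <- theta_grid(64)
  expect_error(decompose_contour(contour_polar(theta_grid(32), rep(5, 32)), 5),
               class = "flick_resolution_error")
  expect_error(decompose_contour(contour_polar(th, rep(5, 64)), 20),
               class = "flick_resolution_error")
  # half-circle coverage
  expect_error(decompose_contour(contour_polar(seq(0, pi, length.out = 100),
                                               rep(5, 100)), 5),
               class = "flick_resolution_error")
  # inconsistent n_max across frames
  expect_error(estimate_spectrum(list(contour_modes(50, rep(0, 5), rep(0, 5)),
                                      contour_modes(50, rep(0, 6), rep(0, 6)))),
               class = "flick_shape_error")
  expect_error(estimate_spectrum(list(contour_modes(50, rep(0, 5), rep(0, 5)))),
               class = "flick_shape_error")
})
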