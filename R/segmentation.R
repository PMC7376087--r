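# Images are plain numeric matrices indexed [row, col]; positions are given
# in (x, y) = (col, row) order with the origin at pixel (1, 1), so x runs
# along columns and y down rows. All segmentation routines follow this
# convention to avoid axis mix-ups between image and contour space.

# bilinear interpolation of image at fractional (x, y); points outside the
# image are clamped to the border pixel
.bilinear <- function(image, x, y) {
  nr <- nrow(image)
  nc <- ncol(image)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1L)]
  i10 <- image[cbind(y0 + 1L, x0)]
  i11 <- image[cbind(y0 + 1L, x0 + 1L)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

# 3-point parabolic refinement of a discrete peak; returns offset in samples
.parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  off <- ifelse(abs(denom) < .Machine$double.eps * (abs(y0) + 1),
                0, 0.5 * (ym1 - yp1) / denom)
  pmin(pmax(off, -0.5), 0.5)
}

#' Detect an equatorial membrane contour by radial intensity search
#'
#' Casts `n_rays` uniformly spaced rays from `center` and, along each ray,
#' samples the image by bilinear interpolation over the radial search window,
#' locates the intensity maximum and refines it to subpixel precision with a
#' three-point parabolic fit. Phase-contrast-style dark rings are handled by
#' `invert = TRUE`, which searches for the intensity minimum instead.
#'
#' @param image numeric matrix (rows = y, columns = x), at least 64 x 64.
#' @param center numeric (x, y) starting center, inside the image.
#' @param r_range numeric (min, max) radial search window in pixels.
#' @param n_rays number of rays (default 360, supporting modes up to ~18
#'   with >= 8 samples per period of the highest mode).
#' @param invert search for a dark ring instead of a bright one.
#' @param step radial sampling step in pixels.
#' @param profile_smooth SD (px) of a Gaussian kernel applied to each radial
#'   intensity profile before peak location. Correlating the profile with a
#'   kernel matched to the membrane cross-section (default 2 px) is the
#'   matched-filter peak estimate: it suppresses pixel-noise jitter without
#'   biasing symmetric profiles. Set to 0 to disable.
#' @param max_edge_frac error out if more than this fraction of rays peak on
#'   the window edge (detection failure).
#' @return a [contour_polar()] in the ray angles, centered on `center`.
#' @examples
#' p <- spectrum_params(44, 0.01, mean_radius = 40)
#' ms <- sample_contour_modes(p, model = "tension", n_frames = 1, seed = 1)
#' cont <- reconstruct_contour(
#'   contour_modes(40, ms$a[1, ], ms$b[1, ]),
#'   seq(0, 2 * pi, length.out = 721)[-721], center = c(64.5, 64.5)
#' )
#' img <- render_frame(cont, render_params(image_size = 128))
#' detect_contour(img, center = c(64.5, 64.5), r_range = c(28, 52))
#' @export
detect_contour <- function(image, center, r_range, n_rays = 360L,
                           invert = FALSE, step = 0.5,
                           profile_smooth = 2, max_edge_frac = 0.1) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 64L || ncol(image) < 64L) {
    .flick_error("flick_domain_error", "image must be at least 64 x 64 pixels")
  }
  if (any(!is.finite(image))) {
    .flick_error("flick_domain_error", "image intensities must be finite")
  }
  stopifnot(length(center) == 2L, length(r_range) == 2L, r_range[1] < r_range[2])
  if (center[1] < 1 || center[1] > ncol(image) ||
      center[2] < 1 || center[2] > nrow(image)) {
    .flick_error("flick_domain_error", "`center` must lie inside the image")
  }
  theta <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  radii <- seq(r_range[1], r_range[2], by = step)
  ns <- length(radii)
  if (ns < 5L) {
    .flick_error("flick_domain_error", "radial search window too narrow")
  }
  # sample all rays at once: (n_rays x ns) grids of x, y
  X <- center[1] + outer(cos(theta), radii)
  Y <- center[2] + outer(sin(theta), radii)
  I <- matrix(.bilinear(image, as.vector(X), as.vector(Y)), nrow = n_rays)
  if (invert) I <- -I
  if (profile_smooth > 0) {
    # Gaussian smoothing along the radial axis only (never across angles,
    # which would attenuate high contour modes); edge-replicated convolution
    ks <- profile_smooth / step
    half_k <- max(1L, ceiling(3 * ks))
    kern <- exp(-((-half_k):half_k)^2 / (2 * ks^2))
    kern <- kern / sum(kern)
    Ipad <- cbind(I[, rep(1L, half_k), drop = FALSE], I,
                  I[, rep(ns, half_k), drop = FALSE])
    # banded convolution as one matrix product over all rays
    K <- matrix(0, ncol(Ipad), ns)
    for (j in seq_len(ns)) K[j:(j + 2L * half_k), j] <- kern
    I <- Ipad %*% K
  }
  idx <- max.col(I, ties.method = "first")
  on_edge <- idx == 1L | idx == ns
  if (mean(on_edge) > max_edge_frac) {
    .flick_error("flick_detection_error",
                 sprintf("radial maximum on search-window edge for %.0f%% of rays",
                         100 * mean(on_edge)))
  }
  # parabolic subpixel refinement on interior peaks
  idx_c <- pmin(pmax(idx, 2L), ns - 1L)
  rows <- seq_len(n_rays)
  off <- .parabolic_offset(I[cbind(rows, idx_c - 1L)],
                           I[cbind(rows, idx_c)],
                           I[cbind(rows, idx_c + 1L)])
  r <- radii[idx_c] + off * step
  contour_polar(theta, r, center = center)
}

#' Iteratively refine the contour center
#'
#' The polar origin must sit at the contour center for the Fourier analysis
#' (otherwise mode 1 absorbs the offset and leaks into neighbours). Starting
#' from `center`, the contour is detected, the center moved to the centroid
#' of the contour points, and detection repeated until the shift falls below
#' `tol` or `max_iter` is reached. On convergence the mode-1 amplitudes
#' |a_1|, |b_1| are driven below ~1e-3.
#'
#' @inheritParams detect_contour
#' @param max_iter maximum center updates (default 20).
#' @param tol convergence threshold on the center shift in pixels
#'   (default 0.01).
#' @param ... further arguments passed to [detect_contour()].
#' @return a list with `center` (x, y), `contour` (detected at the final
#'   center), `iterations`, and `converged` (FALSE triggers a warning and
#'   returns the last iterate).
#' @export
refine_center <- function(image, center, r_range, n_rays = 360L,
                          invert = FALSE, max_iter = 20L, tol = 0.01, ...) {
  cont <- detect_contour(image, center, r_range, n_rays = n_rays,
                         invert = invert, ...)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    shift <- c(mean(cont$radius * cos(cont$theta)),
               mean(cont$radius * sin(cont$theta)))
    if (sqrt(sum(shift^2)) < tol) {
      converged <- TRUE
      break
    }
    center <- center + shift
    # recentre the search annulus on the current mean radius
    rm <- mean(cont$radius)
    r_range <- c(max(1, rm - 0.3 * rm), rm + 0.3 * rm)
    cont <- detect_contour(image, center, r_range, n_rays = n_rays,
                           invert = invert, ...)
  }
  if (!converged) {
    warning("center refinement did not converge; returning last iterate",
            call. = FALSE)
  }
  list(center = center, contour = cont, iterations = iter,
       converged = converged)
}

#' Track a contour through a frame sequence
#'
#' Applies [detect_contour()] + [refine_center()] to every frame, seeding
#' each frame's center (and search annulus) with the previous frame's
#' result. Frames on which detection fails are dropped and their indices
#' recorded; if more than `max_drop_frac` of the frames fail, the sequence
#' is rejected.
#'
#' @param stack list of image matrices (or a 3D array, frames along the
#'   third dimension), >= 2 frames.
#' @param center numeric (x, y) center guess for the first frame.
#' @param r_range radial search window for the first frame (px).
#' @param n_rays,invert passed to [detect_contour()].
#' @param max_drop_frac maximum tolerated fraction of dropped frames.
#' @param refine run center refinement on every frame (default TRUE).
#' @param ... further arguments passed to [detect_contour()].
#' @return a list with `contours` (list of [contour_polar()]), `dropped`
#'   (integer indices of failed frames) and `centers` (matrix of per-frame
#'   centers).
#' @export
track_sequence <- function(stack, center, r_range, n_rays = 360L,
                           invert = FALSE, max_drop_frac = 0.2,
                           refine = TRUE, ...) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  stopifnot(is.list(stack))
  if (length(stack) < 2L) {
    .flick_error("flick_shape_error", "at least 2 frames are required")
  }
  contours <- vector("list", length(stack))
  centers <- matrix(NA_real_, nrow = length(stack), ncol = 2L)
  dropped <- integer(0)
  for (i in seq_along(stack)) {
    res <- tryCatch({
      if (refine) {
        refine_center(stack[[i]], center, r_range, n_rays = n_rays,
                      invert = invert, ...)
      } else {
        list(center = center,
             contour = detect_contour(stack[[i]], center, r_range,
                                      n_rays = n_rays, invert = invert, ...))
      }
    }, flickspec_error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- c(dropped, i)
      next
    }
    contours[[i]] <- res$contour
    centers[i, ] <- res$center
    # seed the next frame from this one
    center <- res$center
    rm <- mean(res$contour$radius)
    r_range <- c(max(1, rm - 0.3 * rm), rm + 0.3 * rm)
  }
  if (length(dropped) > max_drop_frac * length(stack)) {
    .flick_error("flick_sequence_error",
                 sprintf("%d of %d frames failed contour detection",
                         length(dropped), length(stack)))
  }
  if (length(dropped)) {
    message(sprintf("dropped %d frame(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  }
  list(contours = contours[!vapply(contours, is.null, logical(1))],
       dropped = dropped,
       centers = centers[setdiff(seq_along(stack), dropped), , drop = FALSE])
}
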