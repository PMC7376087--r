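# Readers, writers and the two pipeline drivers. Conventions: angles are
# stored in radians; contour tables are long-format CSV (frame, theta_rad,
# r_px); results are JSON with the resolved configuration and seed embedded
# for provenance.

#' Default pipeline configuration
#'
#' All stage parameters in one overridable list. Values can also be loaded
#' from a YAML file with [read_pipeline_config()].
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `flicker_config`.
#' @export
flicker_config <- function(...) {
  cfg <- list(
    n_rays = 360L,
    n_max = 18L,
    invert = FALSE,
    r_search_frac = 0.3,
    model = "free",
    n_min_fit = 5L,
    n_max_fit = 18L,
    peak_window = c(2840, 2860),
    peak_refine = FALSE,
    band_range = c(1960, 1990),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    .flick_error("flick_config_error",
                 paste0("unknown configuration field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "flicker_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the [flicker_config()] fields.
#' @return a `flicker_config` list with the file's values merged over the
#'   defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    .flick_error("flick_io_error", paste0("config file not found: ", path))
  }
  do.call(flicker_config, yaml::read_yaml(path))
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file; 8/16-bit grayscale or RGB (channels averaged).
#' @return list of numeric image matrices.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) {
    .flick_error("flick_io_error", paste0("file not found: ", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p
  })
}

#' Write a frame stack as a multi-page TIFF
#'
#' Intensities are rescaled to the unit range expected by the TIFF writer.
#'
#' @param frames list of numeric matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path) {
  rng <- range(unlist(lapply(frames, range)))
  scaled <- lapply(frames, function(f) {
    (f - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read contour tables
#'
#' Long-format CSV with columns `frame`, `theta_rad`, `r_px`.
#'
#' @param contours list of [contour_polar()] objects.
#' @param path CSV file path.
#' @return `write_contours_csv()` returns `path` invisibly;
#'   `read_contours_csv()` returns a list of contours.
#' @export
write_contours_csv <- function(contours, path) {
  df <- do.call(rbind, lapply(seq_along(contours), function(i) {
    data.frame(frame = i, theta_rad = contours[[i]]$theta,
               r_px = contours[[i]]$radius)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  if (!file.exists(path)) {
    .flick_error("flick_io_error", paste0("file not found: ", path))
  }
  df <- read.csv(path)
  need <- c("frame", "theta_rad", "r_px")
  if (!all(need %in% names(df))) {
    .flick_error("flick_io_error",
                 "contour CSV must have columns frame, theta_rad, r_px")
  }
  # split() would order frames lexicographically; keep numeric frame order
  frames <- sort(unique(df$frame))
  lapply(frames, function(f) {
    d <- df[df$frame == f, , drop = FALSE]
    contour_polar(d$theta_rad, d$r_px)
  })
}

#' Write / read a fluctuation spectrum
#'
#' CSV with columns `n`, `delta2`, `se`, `frames`, `mean_radius_px`.
#'
#' @param spectrum a `fluct_spectrum`.
#' @param path CSV file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- as.data.frame(spectrum)
  names(df)[names(df) == "mean_radius"] <- "mean_radius_px"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) {
    .flick_error("flick_io_error", paste0("file not found: ", path))
  }
  df <- read.csv(path)
  structure(list(n = df$n, delta2 = df$delta2, se = df$se,
                 frames = df$frames[1], mean_radius = df$mean_radius_px[1]),
            class = "fluct_spectrum")
}

#' Read a two-column infrared spectrum CSV
#'
#' @param path CSV with columns `wavenumber_cm.1` (or first column) and
#'   `absorbance` (or second column).
#' @param temperature temperature metadata (degrees C).
#' @return an [ir_spectrum()].
#' @export
read_ftir_csv <- function(path, temperature = NA_real_) {
  if (!file.exists(path)) {
    .flick_error("flick_io_error", paste0("file not found: ", path))
  }
  df <- read.csv(path)
  ir_spectrum(df[[1]], df[[2]], temperature = temperature)
}

#' Serialize a fit result to JSON
#'
#' The JSON embeds the resolved configuration and seed so a result file is
#' self-describing.
#'
#' @param fit a `flick_fit` or `band_fit`.
#' @param path output JSON file.
#' @param config the `flicker_config` used.
#' @param input description of the input data (path or label).
#' @export
write_fit_json <- function(fit, path, config = flicker_config(),
                           input = NA_character_) {
  payload <- if (inherits(fit, "flick_fit")) {
    list(model = fit$model, n_range = fit$n_range,
         estimates = fit$estimates, se = fit$se,
         chi2_reduced = fit$chi2_reduced, mean_radius = fit$mean_radius,
         frames = fit$frames)
  } else if (inherits(fit, "band_fit")) {
    list(model = "two_gaussian_band", centers = fit$centers,
         sigmas = fit$sigmas, areas = fit$areas, f1 = fit$f1, rss = fit$rss)
  } else {
    .flick_error("flick_io_error", "unsupported fit object")
  }
  payload$provenance <- list(
    input = input,
    seed = config$seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("flickspec"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full flicker-spectroscopy pipeline
#'
#' From a TIFF stack (segmentation -> Fourier -> fit), a contour CSV
#' (Fourier -> fit), an in-memory list of image matrices, or an in-memory
#' list of contours, to a fitted spectrum. Artifacts (spectrum CSV, fit
#' JSON) are written when `out_dir` is given.
#'
#' @param input path to a `.tif`/`.tiff` stack or a contour `.csv`, or a
#'   list of image matrices / [contour_polar()] objects.
#' @param center (x, y) center guess for segmentation (required for image
#'   input).
#' @param radius approximate ring radius in px (required for image input;
#'   the search annulus is `radius * (1 +/- r_search_frac)`).
#' @param config a [flicker_config()]; `config$model` selects the spectrum
#'   model (`"free"`, `"tension"` or `"confined"`).
#' @param out_dir directory for artifacts (created if missing); NULL for
#'   none.
#' @return a list with `fit`, `spectrum`, and `dropped` frame indices.
#' @export
run_flicker <- function(input, center = NULL, radius = NULL,
                        config = flicker_config(), out_dir = NULL) {
  dropped <- integer(0)
  if (is.character(input)) {
    if (!file.exists(input)) {
      .flick_error("flick_io_error", paste0("input file not found: ", input))
    }
    if (grepl("\\.csv$", input, ignore.case = TRUE)) {
      contours <- read_contours_csv(input)
    } else {
      stack <- read_tiff_stack(input)
      if (is.null(center) || is.null(radius)) {
        .flick_error("flick_config_error",
                     "`center` and `radius` are required for image input")
      }
      tr <- track_sequence(stack, center = center,
                           r_range = radius * c(1 - config$r_search_frac,
                                                1 + config$r_search_frac),
                           n_rays = config$n_rays, invert = config$invert)
      contours <- tr$contours
      dropped <- tr$dropped
    }
  } else if (is.list(input) && length(input) && is.matrix(input[[1]])) {
    if (is.null(center) || is.null(radius)) {
      .flick_error("flick_config_error",
                   "`center` and `radius` are required for image input")
    }
    tr <- track_sequence(input, center = center,
                         r_range = radius * c(1 - config$r_search_frac,
                                              1 + config$r_search_frac),
                         n_rays = config$n_rays, invert = config$invert)
    contours <- tr$contours
    dropped <- tr$dropped
  } else if (is.list(input) && length(input) && inherits(input[[1]], "flick_contour")) {
    contours <- input
  } else {
    .flick_error("flick_io_error", "unrecognized input type")
  }
  modes <- lapply(contours, decompose_contour, n_max = config$n_max)
  spectrum <- estimate_spectrum(modes)
  fit <- switch(config$model,
    free = fit_bending_free(spectrum, config$n_min_fit, config$n_max_fit),
    tension = fit_tension_model(spectrum, config$n_min_fit, config$n_max_fit),
    confined = fit_confined_model(spectrum, config$n_min_fit, config$n_max_fit),
    .flick_error("flick_config_error",
                 paste0("unknown model: ", config$model))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spectrum_csv(spectrum, file.path(out_dir, "spectrum.csv"))
    write_fit_json(fit, file.path(out_dir, "fit.json"), config = config,
                   input = if (is.character(input)) input else "in-memory")
    if (length(dropped)) {
      writeLines(sprintf("dropped frame %d", dropped),
                 file.path(out_dir, "dropped_frames.log"))
    }
  }
  list(fit = fit, spectrum = spectrum, dropped = dropped)
}

#' Run the FTIR analysis pipeline
#'
#' Reads a manifest (CSV with columns `file`, `temperature_C`, paths
#' relative to the manifest), builds the melting curve, estimates the
#' transition temperature and the expansivity proxy beta, and optionally
#' fits the carbonyl band of each spectrum.
#'
#' @param manifest path to the manifest CSV, or a list of [ir_spectrum()]
#'   objects with temperatures set.
#' @param config a [flicker_config()] (uses `peak_window`, `band_range`).
#' @param fit_bands also run [fit_two_gaussians()] per temperature.
#' @param out_dir directory for artifacts; NULL for none.
#' @return a list with `melting_curve`, `tm`, `beta`, and (optionally)
#'   `band_fits`.
#' @export
run_ftir <- function(manifest, config = flicker_config(), fit_bands = FALSE,
                     out_dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      .flick_error("flick_io_error", paste0("manifest not found: ", manifest))
    }
    mf <- read.csv(manifest)
    if (!all(c("file", "temperature_C") %in% names(mf))) {
      .flick_error("flick_io_error",
                   "manifest must have columns file, temperature_C")
    }
    base <- dirname(manifest)
    spectra <- lapply(seq_len(nrow(mf)), function(i) {
      read_ftir_csv(file.path(base, mf$file[i]), temperature = mf$temperature_C[i])
    })
  } else {
    spectra <- manifest
  }
  if (length(spectra) < 5L) {
    .flick_error("flick_domain_error", "at least 5 temperatures are required")
  }
  curve <- build_melting_curve(spectra, window = config$peak_window,
                               refine = config$peak_refine)
  tm <- tryCatch(estimate_tm(curve), flickspec_error = function(e) NA_real_)
  beta <- compute_beta(curve)
  band_fits <- NULL
  if (fit_bands) {
    band_fits <- lapply(spectra, function(s) {
      tryCatch(fit_two_gaussians(s, range = config$band_range),
               flickspec_error = function(e) NULL)
    })
    failed <- sum(vapply(band_fits, is.null, logical(1)))
    if (failed > 0.2 * length(spectra)) {
      .flick_error("flick_sequence_error",
                   sprintf("%d of %d band fits failed", failed, length(spectra)))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(curve), file.path(out_dir, "melting_curve.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(tm_C = tm, beta = beta,
           provenance = list(seed = config$seed, config = unclass(config))),
      file.path(out_dir, "ftir_results.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")
  }
  list(melting_curve = curve, tm = tm, beta = beta, band_fits = band_fits)
}
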