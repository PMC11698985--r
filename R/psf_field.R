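#' Fit a spatio-spectral PSF field to a hyperspectral cube
#'
#' The package's central fitting function.  Zernike wavefront
#' coefficients are estimated by simulated annealing at nine key patches
#' of each key frame (deconvolution-quality objective against the
#' ground-truth template), then low-order polynomial models of every
#' coefficient are fitted across patch position and wavelength.  The
#' returned model evaluates a wavefront — and hence a noise-free PSF —
#' at any patch and wavelength of the cube, for use in
#' [deconvolve_cube()].
#'
#' @param cube a [hyper_cube()], spatially aligned with `template`.
#' @param template ground-truth image (frame-sized matrix, or a path to
#'   a PNG/TIFF grayscale file).
#' @param patch,border patch geometry in pixels (defaults 80 and 10).
#' @param key_frames 1-based band indices to optimize; default
#'   [key_frame_indices()] over 550-950 nm every 50 nm.
#' @param initial starting [wavefront_spec()] for the central patch of
#'   the first key frame.
#' @param anneal an [anneal_config()], or a list of them for staged
#'   annealing (see [estimate_key_patches()]).
#' @param deconv a [deconv_config()] (or stage list) used inside the
#'   annealing loop.
#' @param warm_anneal,warm_deconv optional configuration for
#'   warm-started patches, see [estimate_key_patches()].
#' @param psf a [psf_options()].
#' @param spatial_order,spectral_order polynomial orders for the
#'   coefficient field (see [fit_coefficient_field()]).
#' @param seed integer seed governing all stochastic stages.
#' @param verbose print per-patch progress.
#' @return An object of class `psf_field` with components `field` (the
#'   fitted [fit_coefficient_field()] model), `knots`, `traces`, the
#'   configurations and the call.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @examples
#' \donttest{
#' spec <- scene_spec("small", seed = 7)
#' sim <- forward_blur_cube(spec)
#' fit <- estimate_psf_field(sim$cube, sim$template, patch = 40,
#'                           key_frames = key_frame_indices(sim$cube$wavelengths,
#'                                                          550, 950, 100),
#'                           anneal = anneal_config(alpha = 0.97),
#'                           deconv = deconv_config(iterations = 24),
#'                           seed = 7)
#' print(fit)
#' psf_700 <- predict(fit, wavelength = 700, patch_row = 1, patch_col = 1,
#'                    what = "psf")
#' }
#' @export
estimate_psf_field <- function(cube, template, patch = 80, border = 10,
                               key_frames = NULL,
                               initial = NULL,
                               anneal = anneal_config(),
                               deconv = deconv_config(),
                               warm_anneal = NULL, warm_deconv = NULL,
                               psf = psf_options(),
                               spatial_order = 3, spectral_order = 3,
                               seed = 1, verbose = FALSE) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (is.character(template)) template <- read_gray_image(template)
  template <- as.matrix(template)
  d <- dim(cube$data)
  if (nrow(template) != d[1] || ncol(template) != d[2])
    stop("template dimensions must match the cube frames")
  grid <- patch_grid(d[2], d[1], patch, border)
  if (is.null(key_frames))
    key_frames <- key_frame_indices(cube$wavelengths)
  if (is.null(initial)) {
    cfg1 <- if (inherits(anneal, "anneal_config")) anneal else anneal[[1]]
    initial <- wavefront_spec(numeric(7), 2:8,
                              defocus_constrained = cfg1$defocus_constrained)
  }

  est <- estimate_key_patches(cube, template, grid, key_frames,
                              initial = initial, config = anneal,
                              deconv = deconv, warm_config = warm_anneal,
                              warm_deconv = warm_deconv, psf = psf,
                              seed = seed, verbose = verbose)
  field <- fit_coefficient_field(est$knots, grid, spatial_order,
                                 spectral_order)
  structure(list(field = field, knots = est$knots, traces = est$traces,
                 grid = grid, key_frames = key_frames,
                 wavelengths = cube$wavelengths,
                 anneal = anneal, deconv = deconv, psf = psf,
                 seed = seed, call = match.call()),
            class = "psf_field")
}

read_gray_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
         else stop("unsupported template image format: ", path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @export
print.psf_field <- function(x, ...) {
  cat("Spatio-spectral PSF field\n")
  cat(sprintf("  %d key frames x %d key patches = %d annealed knots\n",
              length(x$key_frames), nrow(key_patch_indices(x$grid)),
              nrow(x$knots)))
  print(x$grid)
  print(x$field)
  invisible(x)
}

#' @export
summary.psf_field <- function(object, ...) {
  best <- vapply(object$traces, function(tr) -min(tr$best_cost) / 100,
                 numeric(1))
  out <- list(n_knots = nrow(object$knots),
              key_frames = object$key_frames,
              knot_ncc = summary(best),
              field_rms_residual = sqrt(mean(object$field$residuals^2)),
              coefficient_range = apply(
                object$knots[, grep("^z", names(object$knots))], 2, range))
  class(out) <- "summary.psf_field"
  out
}

#' @export
print.summary.psf_field <- function(x, ...) {
  cat("PSF field summary\n")
  cat(sprintf("  annealed knots: %d; deconvolution NCC at knots:\n", x$n_knots))
  print(x$knot_ncc)
  cat(sprintf("  coefficient-field RMS residual: %.3e rad\n",
              x$field_rms_residual))
  cat("  knot coefficient ranges (rad):\n")
  print(round(x$coefficient_range, 3))
  invisible(x)
}

#' @export
coef.psf_field <- function(object, ...) object$knots

#' @export
residuals.psf_field <- function(object, ...) object$field$residuals

#' Predict wavefront coefficients or PSF kernels from a fitted field
#'
#' @param object a `psf_field`.
#' @param wavelength wavelength in nm (scalar).
#' @param patch_row,patch_col 0-based patch indices (scalars).
#' @param what `"coefficients"` (a [wavefront_spec()]), `"psf"` (a
#'   kernel), or `"wavefront"` (a `wavefront_map`).
#' @param extrapolate passed to [eval_field()].
#' @param ... unused.
#' @export
predict.psf_field <- function(object, wavelength, patch_row, patch_col,
                              what = c("coefficients", "psf", "wavefront"),
                              extrapolate = "silent", ...) {
  what <- match.arg(what)
  spec <- eval_field(object$field, wavelength, patch_row, patch_col,
                     extrapolate = extrapolate)
  if (what == "coefficients") return(spec)
  wf <- compose_wavefront(spec, object$psf$grid_size,
                          object$psf$aperture_radius_fraction)
  if (what == "wavefront") return(wf)
  psf_from_pupil(build_pupil(wf), object$psf$out_size,
                 wavelength = wavelength)
}

#' Plot a fitted PSF field
#'
#' `type = "trace"` shows annealing cost traces of the knots;
#' `type = "coefficients"` shows each Zernike coefficient at the knots
#' against wavelength; `type = "psf"` images a grid of interpolated
#' PSFs across the field of view at one wavelength.
#'
#' @param x a `psf_field`.
#' @param type plot flavor.
#' @param wavelength wavelength for `type = "psf"` (defaults to the
#'   middle of the fitted range).
#' @param ... unused.
#' @export
plot.psf_field <- function(x, type = c("trace", "coefficients", "psf"),
                           wavelength = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    first <- x$traces[[1]]
    plot(first$iteration, first$best_cost, type = "n",
         ylim = range(vapply(x$traces, function(tr) range(tr$best_cost),
                             numeric(2))),
         xlab = "iteration", ylab = "best cost (-100 x NCC)",
         main = "Annealing traces at key patches")
    for (tr in x$traces) lines(tr$iteration, tr$best_cost,
                               col = gray(0.3, 0.5))
  } else if (type == "coefficients") {
    zc <- grep("^z", names(x$knots), value = TRUE)
    op <- par(mfrow = c(ceiling(length(zc) / 3), 3), mar = c(4, 4, 2, 1))
    on.exit(par(op))
    for (col in zc) {
      plot(x$knots$wavelength_nm, x$knots[[col]], xlab = "wavelength (nm)",
           ylab = "rad", main = col)
    }
  } else {
    if (is.null(wavelength)) wavelength <- mean(x$field$wavelength_range)
    op <- par(mfrow = c(x$grid$rows, x$grid$cols), mar = c(0.2, 0.2, 0.2, 0.2))
    on.exit(par(op))
    for (r in seq_len(x$grid$rows) - 1) {
      for (c in seq_len(x$grid$cols) - 1) {
        k <- predict(x, wavelength, r, c, what = "psf")
        image(t(unclass(k))[, rev(seq_len(nrow(k)))], axes = FALSE,
              col = gray(seq(0, 1, length.out = 64)))
      }
    }
  }
  invisible(x)
}
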