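#' Build the complex pupil function from a wavefront
#'
#' The pupil function is \eqn{P = A \exp(-iW)} where the amplitude mask
#' \eqn{A} is 1 inside the circular aperture and 0 outside.
#'
#' @param wavefront a `wavefront_map` from [compose_wavefront()].
#' @param aperture_radius_fraction optional override of the aperture
#'   radius (fraction of the grid half-width).  By default the radius
#'   stored in the wavefront map is used; a smaller value stops the
#'   aperture down without re-normalizing the Zernike coordinates.
#' @return An object of class `pupil_function`: complex matrix `values`,
#'   binary `amplitude` mask, and geometry.
#' @export
build_pupil <- function(wavefront, aperture_radius_fraction = NULL) {
  stopifnot(inherits(wavefront, "wavefront_map"))
  phase <- wavefront$phase
  if (nrow(phase) != ncol(phase)) stop("wavefront grid must be square")
  mask <- wavefront$mask
  frac <- wavefront$aperture_radius_fraction
  if (!is.null(aperture_radius_fraction)) {
    if (aperture_radius_fraction <= 0 || aperture_radius_fraction > 1)
      stop("aperture_radius_fraction must be in (0, 1]")
    geo <- pupil_coords(nrow(phase), aperture_radius_fraction)
    mask <- mask & geo$mask
    frac <- aperture_radius_fraction
  }
  values <- matrix(0 + 0i, nrow(phase), ncol(phase))
  values[mask] <- exp(-1i * phase[mask])
  structure(list(values = values, amplitude = mask,
                 aperture_radius_fraction = frac,
                 grid_size = nrow(phase)),
            class = "pupil_function")
}

#' Compute a PSF kernel from a pupil function
#'
#' The incoherent PSF is the squared modulus of the Fourier transform of
#' the pupil function.  The zero frequency is shifted to the center of
#' the grid, the intensity is cropped to `out_size` around that center
#' pixel, and the crop is normalized to unit sum.
#'
#' @param pupil a `pupil_function` from [build_pupil()].
#' @param out_size odd kernel side length (default 21), at most the
#'   pupil grid size.
#' @param wavelength,patch optional tags carried on the kernel.
#' @return A `psf_kernel`: non-negative numeric matrix of odd side with
#'   unit sum; attributes `center` (1-based index of the optical-axis
#'   pixel), `wavelength`, `patch`.
#' @export
psf_from_pupil <- function(pupil, out_size = 21, wavelength = NULL,
                           patch = NULL) {
  stopifnot(inherits(pupil, "pupil_function"))
  if (out_size %% 2 != 1) stop("out_size must be odd (a center pixel must exist)")
  n <- pupil$grid_size
  if (out_size > n) stop("out_size exceeds the pupil grid size")
  inten <- pupil_intensity_cpp(pupil$values)
  ctr <- n / 2 + 1
  h <- (out_size - 1) / 2
  kern <- inten[(ctr - h):(ctr + h), (ctr - h):(ctr + h)]
  s <- sum(kern)
  if (s <= 0) stop("degenerate pupil: PSF has zero energy")
  kern <- kern / s
  structure(kern, center = c(h + 1, h + 1), wavelength = wavelength,
            patch = patch, class = c("psf_kernel", "matrix"))
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat("PSF kernel ", nrow(x), "x", ncol(x), sep = "")
  wl <- attr(x, "wavelength")
  if (!is.null(wl)) cat(" @", wl, "nm")
  cat(", sum =", format(sum(x)), "\n")
  invisible(x)
}

#' Wavefront specification straight to PSF kernel
#'
#' Convenience chain [compose_wavefront()] -> [build_pupil()] ->
#' [psf_from_pupil()].
#'
#' @inheritParams compose_wavefront
#' @inheritParams psf_from_pupil
#' @export
psf_from_spec <- function(spec, grid_size = 256,
                          aperture_radius_fraction = 0.5, out_size = 21,
                          wavelength = NULL, patch = NULL) {
  psf_from_pupil(build_pupil(compose_wavefront(spec, grid_size,
                                               aperture_radius_fraction)),
                 out_size, wavelength = wavelength, patch = patch)
}

# Fast kernel evaluation used in hot loops: basis + raw coefficients,
# skipping S3 construction of intermediates.
psf_from_coefficients <- function(basis, coefficients, out_size) {
  n <- basis$grid_size
  values <- matrix(0 + 0i, n, n)
  phase <- as.vector(basis$basis %*% coefficients)
  values[basis$mask_index] <- exp(-1i * phase)
  inten <- pupil_intensity_cpp(values)
  ctr <- n / 2 + 1
  h <- (out_size - 1) / 2
  kern <- inten[(ctr - h):(ctr + h), (ctr - h):(ctr + h)]
  kern / sum(kern)
}

#' Evaluate a PSF kernel for every patch and wavelength of a field
#'
#' Batch wrapper turning a fitted coefficient field into the full grid
#' of PSF kernels used by [deconvolve_cube()].
#'
#' @param field a `coefficient_field` (see [fit_coefficient_field()]) or
#'   a fitted `psf_field` model.
#' @param wavelengths numeric vector of wavelengths (nm), one per frame.
#' @param grid a [patch_grid()].
#' @param grid_size,aperture_radius_fraction,out_size PSF geometry, as
#'   in [psf_from_spec()].
#' @param extrapolate `"warn"` (default), `"error"`, or `"silent"` for
#'   wavelengths outside the fitted spectral range.
#' @return List of length `length(wavelengths)`; element `f` is a list of
#'   `grid$n_patches` kernels in row-major patch order.
#' @export
psf_field_from_coefficients <- function(field, wavelengths, grid,
                                        grid_size = 64,
                                        aperture_radius_fraction = 0.5,
                                        out_size = 21,
                                        extrapolate = c("warn", "error",
                                                        "silent")) {
  extrapolate <- match.arg(extrapolate)
  if (inherits(field, "psf_field")) field <- field$field
  stopifnot(inherits(field, "coefficient_field"))
  rng <- field$wavelength_range
  outside <- wavelengths < rng[1] | wavelengths > rng[2]
  if (any(outside)) {
    msg <- sprintf("%d wavelength(s) outside the fitted range [%g, %g] nm: spectral extrapolation",
                   sum(outside), rng[1], rng[2])
    if (extrapolate == "error") stop(msg)
    if (extrapolate == "warn") warning(msg)
  }
  basis <- zernike_basis(field$noll_indices, grid_size,
                         aperture_radius_fraction)
  centers <- patch_centers(grid)
  lapply(seq_along(wavelengths), function(f) {
    cf <- predict_field_coefficients(field, wavelengths[f],
                                     centers$y, centers$x)
    lapply(seq_len(grid$n_patches), function(p) {
      kern <- psf_from_coefficients(basis, cf[p, ], out_size)
      structure(kern, center = c((out_size + 1) / 2, (out_size + 1) / 2),
                wavelength = wavelengths[f], patch = p,
                class = c("psf_kernel", "matrix"))
    })
  })
}
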