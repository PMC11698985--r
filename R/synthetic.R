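# Synthetic push-broom hyperspectral scenes with known, smoothly varying
# optical blur.  The generator is the package's validation instrument:
# it produces a high-contrast template, a ground-truth Zernike
# coefficient field, the exact PSF kernels derived from it, and a
# forward-blurred noisy cube, so estimation and deconvolution can be
# verified without any instrument data.

#' Specify a synthetic acquisition
#'
#' The default `"small"` preset is a scaled-down push-broom instrument:
#' 160 x 120 frames, 40-px patches (4 x 3 grid), 41 bands over
#' 550-950 nm at 10 nm, with additive Gaussian reflectance noise that
#' grows quadratically from sigma = 0.002 mid-band to 0.05 at the
#' spectral-range edges (the regime in which real band-edge frames are
#' too noisy to use).  The `"instrument"` preset reproduces full
#' 640 x 480 x 501 geometry over 500-1000 nm.
#'
#' The true coefficient field is polynomial in standardized
#' (x, y, lambda): a wavelength ramp on tip/tilt models the systematic
#' lateral shift of a push-broom spectrometer, defocus is everywhere
#' negative and grows toward the band edges and field corners, and
#' astigmatism/coma vary gently across the field.
#'
#' @param preset `"small"` or `"instrument"`.
#' @param width,height,patch,border,wavelengths geometry overrides.
#' @param sigma_mid,sigma_edge noise levels (reflectance units).
#' @param field_fun optional `function(noll, x, y, l)` (standardized
#'   coordinates in `[-1, 1]`) returning the true coefficient (radians).
#' @param tip_ramp peak tip coefficient at the spectral edges (radians);
#'   sets the size of the wavelength-dependent lateral shift.
#' @param noll_indices Zernike modes carried by the true field.
#' @param seed integer seed; everything derived from the spec is
#'   reproducible from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(preset = c("small", "instrument"), width = NULL,
                       height = NULL, patch = NULL, border = 10,
                       wavelengths = NULL, sigma_mid = 0.002,
                       sigma_edge = 0.05, field_fun = NULL, tip_ramp = 1.0,
                       noll_indices = 2:8, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "small") {
    if (is.null(width)) width <- 160
    if (is.null(height)) height <- 120
    if (is.null(patch)) patch <- 40
    if (is.null(wavelengths)) wavelengths <- seq(550, 950, 10)
  } else {
    if (is.null(width)) width <- 640
    if (is.null(height)) height <- 480
    if (is.null(patch)) patch <- 80
    if (is.null(wavelengths)) wavelengths <- seq(500, 1000, 1)
  }
  if (is.null(field_fun)) field_fun <- default_field_fun(tip_ramp)
  structure(list(width = width, height = height, patch = patch,
                 border = border, wavelengths = wavelengths,
                 sigma_mid = sigma_mid, sigma_edge = sigma_edge,
                 field_fun = field_fun, noll_indices = as.integer(noll_indices),
                 seed = as.integer(seed),
                 grid = patch_grid(width, height, patch, border)),
            class = "scene_spec")
}

# Smooth ground-truth coefficient surfaces; x, y, l standardized.
default_field_fun <- function(tip_ramp = 1.0) {
  function(noll, x, y, l) {
    switch(as.character(noll),
      "2" = tip_ramp * l + 0.15 * x,
      "3" = 0.3 * tip_ramp * l + 0.1 * y,
      "4" = -(1.1 + 0.35 * l + 0.25 * l^2 + 0.2 * x^2 + 0.15 * y^2),
      "5" = 0.35 * x * y + 0.1 * l,
      "6" = 0.3 * (x^2 - y^2) + 0.15 * l,
      "7" = 0.25 * y - 0.1 * l,
      "8" = 0.25 * x + 0.1 * l,
      0)
  }
}

# Per-band noise sigma: quadratic in standardized wavelength, largest at
# the spectral-range edges.
noise_sigma <- function(spec) {
  l <- standardize(spec$wavelengths)$z
  spec$sigma_mid + (spec$sigma_edge - spec$sigma_mid) * l^2
}

# True coefficient matrix for all patches of one band.
true_coefficients <- function(spec, band) {
  grid <- spec$grid
  ctr <- patch_centers(grid)
  sx <- standardize(c(0, spec$width - 1))
  sy <- standardize(c(0, spec$height - 1))
  sl <- standardize(range(spec$wavelengths))
  x <- (ctr$x - sx$center) / sx$scale
  y <- (ctr$y - sy$center) / sy$scale
  l <- (spec$wavelengths[band] - sl$center) / sl$scale
  out <- vapply(spec$noll_indices, function(nl)
    vapply(seq_along(x), function(k) spec$field_fun(nl, x[k], y[k], l),
           numeric(1)),
    numeric(length(x)))
  colnames(out) <- paste0("z", spec$noll_indices)
  out
}

#' Generate a high-contrast ground-truth template
#'
#' Procedural glyph-like strokes — oriented bars at every 22.5 degrees,
#' rings, and seeded random rectangles — dark on a light background, so
#' strong edges occur in all orientation octants (the property a text
#' page provides for real acquisitions).  Contrast spans at least 80 %
#' of the [0, 1] dynamic range.
#'
#' @param spec a [scene_spec()].
#' @return `height x width` matrix in `[0, 1]`.
#' @export
make_template <- function(spec) {
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  img <- matrix(0.95, h, w)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  draw_bar <- function(cx, cy, len, wid, angle) {
    ca <- cos(angle); sa <- sin(angle)
    u <- (xg - cx) * ca + (yg - cy) * sa
    v <- -(xg - cx) * sa + (yg - cy) * ca
    img[abs(u) <= len / 2 & abs(v) <= wid / 2] <<- 0.05
  }
  draw_ring <- function(cx, cy, r, wid) {
    d <- sqrt((xg - cx)^2 + (yg - cy)^2)
    img[abs(d - r) <= wid / 2] <<- 0.05
  }
  # deterministic oriented bars covering all octants
  angles <- seq(0, pi - pi / 8, pi / 8)
  nx <- ceiling(sqrt(length(angles)))
  for (i in seq_along(angles)) {
    gx <- ((i - 1) %% nx + 0.5) / nx * w
    gy <- ((i - 1) %/% nx + 0.5) / nx * h
    draw_bar(gx, gy, min(h, w) * 0.22, max(2, round(min(h, w) / 40)),
             angles[i])
  }
  # seeded random strokes and rings for texture
  n_extra <- max(12, round(h * w / 1500))
  for (i in seq_len(n_extra)) {
    if (runif(1) < 0.75)
      draw_bar(runif(1, 1, w), runif(1, 1, h), runif(1, 6, min(h, w) / 4),
               runif(1, 2, 5), runif(1, 0, pi))
    else
      draw_ring(runif(1, 1, w), runif(1, 1, h), runif(1, 4, min(h, w) / 6),
                runif(1, 2, 4))
  }
  # every patch cell must carry structure (a flat patch cannot anchor
  # PSF estimation): fill quiet cells with an oriented stroke
  g <- spec$grid
  for (r in seq_len(g$rows) - 1) {
    for (c in seq_len(g$cols) - 1) {
      cell <- img[(r * g$patch + 1):((r + 1) * g$patch),
                  (c * g$patch + 1):((c + 1) * g$patch)]
      if (sd(cell) < 0.1) {
        draw_bar(c * g$patch + g$patch / 2, r * g$patch + g$patch / 2,
                 g$patch * 0.6, max(2, round(g$patch / 12)),
                 (r * g$cols + c) * pi / 8)
        draw_ring(c * g$patch + g$patch / 2, r * g$patch + g$patch / 2,
                  g$patch * 0.3, 2)
      }
    }
  }
  img
}

#' Forward-simulate a blurred, noisy hyperspectral cube
#'
#' For every band and patch the template's border-extended patch is
#' convolved with the true PSF of that (patch, band) — including the
#' tip/tilt wavelength ramp — cropped back and reassembled; band-wise
#' Gaussian noise is then added and the result clipped to non-negative
#' reflectance.
#'
#' @param template frame-sized matrix (defaults to
#'   [make_template()] of the spec).
#' @param spec a [scene_spec()].
#' @param psf a [psf_options()] controlling the true kernels.
#' @param noise logical; disable to obtain the noise-free forward model.
#' @return List: `cube` (a [hyper_cube()]), `psfs` (true kernels, one
#'   list per band in row-major patch order), `coefficients` (list of
#'   true per-band coefficient matrices), `template`, `spec`.
#' @export
forward_blur_cube <- function(spec, template = NULL, psf = psf_options(),
                              noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(template)) template <- make_template(spec)
  grid <- spec$grid
  basis <- zernike_basis(spec$noll_indices, psf$grid_size,
                         psf$aperture_radius_fraction)
  sig <- noise_sigma(spec)
  set.seed(spec$seed + 1L)
  tmpl_patches <- tile_frame(template, grid)
  nb <- length(spec$wavelengths)
  data <- array(0, c(spec$height, spec$width, nb))
  psfs <- vector("list", nb)
  coefs <- vector("list", nb)
  for (b in seq_len(nb)) {
    cf <- true_coefficients(spec, b)
    coefs[[b]] <- cf
    kerns <- lapply(seq_len(grid$n_patches), function(p) {
      k <- psf_from_coefficients(basis, cf[p, ], psf$out_size)
      structure(k, center = c((psf$out_size + 1) / 2, (psf$out_size + 1) / 2),
                wavelength = spec$wavelengths[b], patch = p,
                class = c("psf_kernel", "matrix"))
    })
    blurred <- lapply(seq_len(grid$n_patches), function(p)
      conv2_reflect_cpp(tmpl_patches[[p]], unclass(kerns[[p]])))
    frame <- assemble_frame(blurred, grid)
    if (noise) frame <- frame + matrix(rnorm(length(frame), 0, sig[b]),
                                       nrow(frame), ncol(frame))
    data[, , b] <- pmax(frame, 0)
    psfs[[b]] <- kerns
  }
  list(cube = hyper_cube(data, spec$wavelengths,
                         metadata = list(synthetic = TRUE, seed = spec$seed)),
       psfs = psfs, coefficients = coefs, template = template, spec = spec)
}

#' Simulate an array of point-like sources imaged through the true field
#'
#' The simulated analogue of a fiber-based point-source array: one
#' sub-pixel source at each patch center (a 6 x 8 grid on instrument
#' geometry gives 48 sources), blurred by the true PSF of its patch, so
#' "measured-PSF" style validation can run entirely in simulation.
#'
#' @param spec a [scene_spec()].
#' @param amplitude source amplitude (reflectance units).
#' @inheritParams forward_blur_cube
#' @return List: `cube`, `psfs`, `centers` (0-based source pixel
#'   coordinates).
#' @export
point_source_cube <- function(spec, amplitude = 1, psf = psf_options(),
                              noise = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  grid <- spec$grid
  ctr <- patch_centers(grid)
  src <- matrix(0, spec$height, spec$width)
  src[cbind(round(ctr$y) + 1, round(ctr$x) + 1)] <- amplitude
  basis <- zernike_basis(spec$noll_indices, psf$grid_size,
                         psf$aperture_radius_fraction)
  sig <- noise_sigma(spec)
  set.seed(spec$seed + 2L)
  nb <- length(spec$wavelengths)
  data <- array(0, c(spec$height, spec$width, nb))
  psfs <- vector("list", nb)
  src_patches <- tile_frame(src, grid)
  for (b in seq_len(nb)) {
    cf <- true_coefficients(spec, b)
    kerns <- lapply(seq_len(grid$n_patches), function(p)
      psf_from_coefficients(basis, cf[p, ], psf$out_size))
    blurred <- lapply(seq_len(grid$n_patches), function(p)
      conv2_reflect_cpp(src_patches[[p]], kerns[[p]]))
    frame <- assemble_frame(blurred, grid)
    if (noise) frame <- frame + matrix(rnorm(length(frame), 0, sig[b]),
                                       nrow(frame), ncol(frame))
    data[, , b] <- pmax(frame, 0)
    psfs[[b]] <- kerns
  }
  list(cube = hyper_cube(data, spec$wavelengths,
                         metadata = list(synthetic = TRUE, sources = "patch centers")),
       psfs = psfs,
       centers = data.frame(row = round(ctr$y), col = round(ctr$x)))
}

#' Extract a kernel-sized window around a point source
#'
#' @param frame image matrix.
#' @param row,col 0-based center pixel.
#' @param size odd window side.
#' @export
extract_kernel <- function(frame, row, col, size = 21) {
  h <- (size - 1) / 2
  r <- (row + 1 - h):(row + 1 + h)
  c <- (col + 1 - h):(col + 1 + h)
  if (min(r) < 1 || max(r) > nrow(frame) || min(c) < 1 || max(c) > ncol(frame))
    stop("window extends beyond the frame")
  frame[r, c]
}

#' Centroid of a frame region (intensity-weighted)
#'
#' Used to track the wavelength-dependent lateral shift of a fiducial
#' point source through a cube.
#'
#' @param frame image matrix.
#' @param row,col,size optional 0-based window (defaults to the whole
#'   frame).
#' @return Numeric `c(row, col)`, 0-based, sub-pixel.
#' @export
centroid <- function(frame, row = NULL, col = NULL, size = NULL) {
  if (!is.null(row)) frame <- extract_kernel(frame, row, col, size)
  tot <- sum(frame)
  if (tot <= 0) stop("cannot compute centroid of a non-positive frame")
  rows <- seq_len(nrow(frame)) - 1
  cols <- seq_len(ncol(frame)) - 1
  out <- c(sum(rowSums(frame) * rows), sum(colSums(frame) * cols)) / tot
  if (!is.null(row)) out <- out + c(row - (size - 1) / 2, col - (size - 1) / 2)
  out
}
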