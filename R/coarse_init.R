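#' Coarse initial wavefront from a defocus scan
#'
#' Scores a one-dimensional grid of pure-defocus wavefronts by
#' deconvolution NCC and returns the best as a starting solution for
#' [anneal()].  This is the automated analogue of pre-adjusting defocus
#' by eye before optimization: defocus dominates the blur budget of
#' typical camera optics, and starting the annealer inside the right
#' defocus basin removes the main multi-modality of the objective.
#'
#' @param patch observed border-extended patch.
#' @param template matching template patch (extended or interior size).
#' @param noll_indices mode set of the returned spec.
#' @param defocus_grid candidate defocus coefficients (radians,
#'   non-positive).
#' @param deconv a [deconv_config()] for the scoring deconvolutions.
#' @param psf a [psf_options()].
#' @param border border cropped before scoring.
#' @return A [wavefront_spec()] with the winning defocus and zeros
#'   elsewhere; attribute `scores` holds the scanned NCC values.
#' @export
coarse_initial <- function(patch, template, noll_indices = 2:8,
                           defocus_grid = seq(-3, 0, by = 0.25),
                           deconv = deconv_config(iterations = 24),
                           psf = psf_options(), border = 10) {
  if (any(defocus_grid > 0)) stop("defocus candidates must be <= 0")
  patch <- as.matrix(patch)
  template <- as.matrix(template)
  interior <- function(m) {
    if (border > 0 && all(dim(m) == dim(patch)))
      m[(border + 1):(nrow(m) - border), (border + 1):(ncol(m) - border)]
    else m
  }
  tmpl_int <- interior(template)
  basis <- zernike_basis(noll_indices, psf$grid_size,
                         psf$aperture_radius_fraction)
  i4 <- match(4L, noll_indices)
  if (is.na(i4)) stop("mode set must include defocus (Noll 4)")
  scores <- vapply(defocus_grid, function(d) {
    cf <- numeric(length(noll_indices))
    cf[i4] <- d
    kern <- psf_from_coefficients(basis, cf, psf$out_size)
    dec <- rl_deconv_cpp(patch, kern, deconv$iterations)
    dint <- if (border > 0)
      dec[(border + 1):(nrow(dec) - border), (border + 1):(ncol(dec) - border)]
    else dec
    if (sd(dint) == 0) return(-1)
    ncc(dint, tmpl_int)
  }, numeric(1))
  cf <- numeric(length(noll_indices))
  cf[i4] <- defocus_grid[which.max(scores)]
  out <- wavefront_spec(cf, noll_indices)
  attr(out, "scores") <- data.frame(defocus = defocus_grid, ncc = scores)
  out
}
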