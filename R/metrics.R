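#' Normalized cross-correlation between two images
#'
#' \deqn{\mathrm{NCC}(I_1, I_2) = \frac{\sum_{x,y} (I_1 - \bar I_1)(I_2 -
#' \bar I_2)}{\sqrt{\sum (I_1 - \bar I_1)^2 \sum (I_2 - \bar I_2)^2}}}
#'
#' Invariant under adding a constant to either image and under positive
#' rescaling; 1 means identical up to a positive affine intensity map.
#' A constant image has undefined NCC and raises an error rather than
#' returning 0 — in this package a constant deconvolved patch signals a
#' failed deconvolution, not a neutral score.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("images must be finite")
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da * da); vb <- sum(db * db)
  if (va == 0 || vb == 0)
    stop("NCC undefined for a constant image (zero variance)")
  sum(da * db) / sqrt(va * vb)
}

#' Annealer cost: NCC scaled to a minimization objective
#'
#' The optimizer minimizes \eqn{-100 \times \mathrm{NCC}}, so a perfect
#' match scores -100 and anticorrelation +100.  The scaling puts the
#' objective on a convenient percent-like range and makes the acceptance
#' rule \eqn{\exp((Q - Q')/T)} operate on cost-like quantities.
#'
#' @inheritParams ncc
#' @export
anneal_cost <- function(a, b) -100 * ncc(a, b)

#' Normalized difference vegetation index
#'
#' Elementwise \eqn{(\mathrm{NIR} - \mathrm{red}) / (\mathrm{NIR} +
#' \mathrm{red})}; pixels whose denominator is (near) zero are masked
#' to `NA`.
#'
#' @param red,nir reflectance matrices of identical dimensions.
#' @param eps denominator threshold below which the index is masked.
#' @return Matrix in `[-1, 1]` (with `NA` where masked).
#' @export
ndvi <- function(red, nir, eps = 1e-9) {
  red <- as.matrix(red); nir <- as.matrix(nir)
  if (!all(dim(red) == dim(nir))) stop("bands must have identical dimensions")
  denom <- nir + red
  out <- (nir - red) / denom
  out[abs(denom) < eps] <- NA_real_
  out
}

#' NDVI from a hyperspectral cube
#'
#' Averages reflectance over a band window around the red and
#' near-infrared anchor wavelengths before forming the index.  Defaults
#' follow common vegetation-analysis practice for leaf reflectance:
#' 680 nm (red absorption) and 750 nm (NIR plateau) with a +/- 25 nm
#' (50 nm bandwidth) averaging window.
#'
#' @param cube a [hyper_cube()].
#' @param red_nm,nir_nm anchor wavelengths (nm).
#' @param window half-width of the averaging window (nm).
#' @inheritParams ndvi
#' @export
ndvi_from_cube <- function(cube, red_nm = 680, nir_nm = 750, window = 25,
                           eps = 1e-9) {
  stopifnot(inherits(cube, "hyper_cube"))
  band_mean <- function(center) {
    sel <- which(abs(cube$wavelengths - center) <= window)
    if (length(sel) == 0) sel <- which.min(abs(cube$wavelengths - center))
    apply(cube$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  ndvi(band_mean(red_nm), band_mean(nir_nm), eps = eps)
}
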