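#' Convert a Noll index to Zernike radial degree and azimuthal order
#'
#' The Noll single-index scheme orders Zernike modes by radial degree
#' \eqn{n}, then by increasing azimuthal frequency \eqn{|m|}; within a
#' degenerate \eqn{(n, |m|)} pair the even index is assigned to the
#' cosine (non-negative \eqn{m}) mode and the odd index to the sine
#' (negative \eqn{m}) mode.
#'
#' @param noll vector of positive integer Noll indices.
#' @return A two-column integer matrix with columns `n` (radial degree)
#'   and `m` (signed azimuthal order), one row per input index.
#' @examples
#' noll_to_nm(1:8)
#' @seealso [nm_to_noll()], [zernike_eval()]
#' @export
noll_to_nm <- function(noll) {
  if (length(noll) == 0L) stop("empty Noll index vector")
  if (any(!is.finite(noll)) || any(noll < 1) || any(noll != round(noll)))
    stop("Noll indices must be positive integers")
  out <- t(vapply(as.integer(noll), function(j) {
    n <- 0L
    while (j > (n + 1L) * (n + 2L) / 2L) n <- n + 1L
    i <- j - (n * (n + 1L)) %/% 2L  # 1-based position within the degree-n row
    m_abs <- if (n %% 2L == 0L) 2L * (i %/% 2L) else 2L * ((i - 1L) %/% 2L) + 1L
    m <- if (m_abs == 0L) 0L else if (j %% 2L == 0L) m_abs else -m_abs
    c(n = n, m = m)
  }, integer(2)))
  colnames(out) <- c("n", "m")
  out
}

#' Convert radial degree and azimuthal order to a Noll index
#'
#' Inverse of [noll_to_nm()].
#'
#' @param n radial degree (non-negative integer).
#' @param m signed azimuthal order; `abs(m) <= n` and `n - abs(m)` even.
#' @return Positive integer Noll index.
#' @export
nm_to_noll <- function(n, m) {
  if (length(n) != length(m)) stop("n and m must have equal length")
  mapply(function(n, m) {
    if (n < 0 || abs(m) > n || (n - abs(m)) %% 2 != 0)
      stop(sprintf("invalid Zernike mode (n = %d, m = %d)", n, m))
    row_start <- n * (n + 1) / 2
    for (j in (row_start + 1):(row_start + n + 1)) {
      nm <- noll_to_nm(j)
      if (nm[1, "n"] == n && nm[1, "m"] == m) return(as.integer(j))
    }
    stop("Noll index not found")  # unreachable for valid (n, m)
  }, n, m)
}

# Radial Zernike polynomial R_n^{|m|}(rho); finite everywhere incl. rho = 0.
zernike_radial <- function(n, m_abs, rho) {
  k <- 0:((n - m_abs) / 2)
  coefs <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k))
  powers <- n - 2 * k
  out <- numeric(length(rho))
  for (i in seq_along(k)) out <- out + coefs[i] * rho^powers[i]
  out
}

#' Evaluate a Noll-normalized Zernike polynomial
#'
#' Modes are normalized to unit variance over the unit disk (the Noll
#' convention): \eqn{\sqrt{n+1}\,R_n^0} for rotationally symmetric modes
#' and \eqn{\sqrt{2(n+1)}\,R_n^{|m|}} times \eqn{\cos(m\theta)}
#' (\eqn{m > 0}) or \eqn{\sin(|m|\theta)} (\eqn{m < 0}) otherwise.
#'
#' @param noll single positive integer Noll index.
#' @param rho radial coordinate(s) in `[0, 1]`.
#' @param theta azimuthal angle(s) in radians (recycled against `rho`).
#' @return Numeric vector of polynomial values.
#' @examples
#' zernike_eval(4, 0, 0)   # defocus at the pupil center: -sqrt(3)
#' @export
zernike_eval <- function(noll, rho, theta) {
  if (length(noll) != 1L) stop("noll must be a single index")
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("rho must lie in [0, 1]")
  nm <- noll_to_nm(noll)
  n <- unname(nm[1, "n"]); m <- unname(nm[1, "m"])
  r <- zernike_radial(n, abs(m), rho)
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  if (m == 0) norm * r
  else if (m > 0) norm * r * cos(m * theta)
  else norm * r * sin(abs(m) * theta)
}

#' Construct a wavefront specification
#'
#' A wavefront specification pairs an ordered set of Noll indices with
#' phase coefficients (radians of optical phase at the pupil).  The
#' default mode set, Noll 2 to 8, spans tip, tilt, defocus, oblique and
#' vertical primary astigmatism, and vertical and horizontal coma — the
#' aberrations that dominate conventional camera optics.
#'
#' @param coefficients numeric coefficient vector (radians).
#' @param noll_indices ordered integer Noll indices, same length.
#' @param defocus_constrained if `TRUE`, the defocus (Noll 4)
#'   coefficient must be non-positive.  Defocus of either sign yields
#'   the same PSF magnitude when paired with sign-flipped companions, so
#'   pinning its sign removes a wavefront ambiguity that would otherwise
#'   corrupt interpolation between neighboring patches.
#' @param unit either `"radians"` (default) or `"waves"`; coefficients
#'   given in waves are converted by \eqn{2\pi}.
#' @return An object of class `wavefront_spec`.
#' @export
wavefront_spec <- function(coefficients, noll_indices = 2:8,
                           defocus_constrained = TRUE,
                           unit = c("radians", "waves")) {
  unit <- match.arg(unit)
  if (length(coefficients) != length(noll_indices))
    stop("coefficients and noll_indices must have the same length")
  noll_to_nm(noll_indices)  # validates
  if (unit == "waves") coefficients <- coefficients * 2 * pi
  if (defocus_constrained && 4L %in% noll_indices &&
      coefficients[match(4L, noll_indices)] > 0)
    stop("defocus coefficient must be <= 0 when defocus_constrained")
  structure(list(noll_indices = as.integer(noll_indices),
                 coefficients = as.numeric(coefficients),
                 defocus_constrained = isTRUE(defocus_constrained)),
            class = "wavefront_spec")
}

#' @export
print.wavefront_spec <- function(x, ...) {
  cat("Wavefront specification (", length(x$noll_indices), " Zernike modes)\n",
      sep = "")
  print(setNames(round(x$coefficients, 4), paste0("Z", x$noll_indices)))
  invisible(x)
}

# Pupil-grid geometry: an even N x N grid whose FFT-center pixel
# (row N/2 + 1, col N/2 + 1, 1-based) sits at the origin.  The aperture
# has radius r0 = aperture_radius_fraction * N/2 pixels, and Zernike
# coordinates are normalized to that radius so the unit disk IS the
# aperture.
pupil_coords <- function(grid_size, aperture_radius_fraction) {
  ax <- (seq_len(grid_size) - 1) - grid_size / 2
  x <- matrix(ax, grid_size, grid_size, byrow = TRUE)
  y <- matrix(ax, grid_size, grid_size)
  r0 <- aperture_radius_fraction * grid_size / 2
  rho <- sqrt(x^2 + y^2) / r0
  list(rho = rho, theta = atan2(y, x), mask = rho <= 1)
}

#' Precompute a Zernike basis on a pupil grid
#'
#' Returns the masked basis matrix used to evaluate many wavefronts with
#' a single matrix-vector product (the annealer's hot path).
#'
#' @inheritParams compose_wavefront
#' @return List with the pixel-by-mode basis matrix (masked pixels only),
#'   the logical aperture mask, and the grid geometry.
#' @export
zernike_basis <- function(noll_indices = 2:8, grid_size = 256,
                          aperture_radius_fraction = 0.5) {
  geo <- pupil_coords(grid_size, aperture_radius_fraction)
  idx <- which(geo$mask)
  basis <- vapply(noll_indices, function(nl)
    zernike_eval(nl, geo$rho[idx], geo$theta[idx]),
    numeric(length(idx)))
  list(basis = basis, mask = geo$mask, mask_index = idx,
       noll_indices = as.integer(noll_indices), grid_size = grid_size,
       aperture_radius_fraction = aperture_radius_fraction)
}

#' Compose a computed wavefront from Zernike coefficients
#'
#' Evaluates \eqn{W(\rho, \theta) = \sum_n c_n Z_n(\rho, \theta)} on a
#' square pupil grid.  The sum is exactly linear in the coefficients.
#'
#' @param spec a [wavefront_spec()].
#' @param grid_size even integer side length of the pupil grid
#'   (default 256).
#' @param aperture_radius_fraction aperture radius as a fraction of the
#'   grid half-width; the default 0.5 embeds the aperture in a twofold
#'   zero-padded grid so the PSF is Nyquist-sampled.
#' @return An object of class `wavefront_map`: list with `phase` (the
#'   grid, radians; zero outside the aperture), `mask`, and geometry.
#' @export
compose_wavefront <- function(spec, grid_size = 256,
                              aperture_radius_fraction = 0.5) {
  stopifnot(inherits(spec, "wavefront_spec"))
  if (grid_size < 16) stop("grid_size must be >= 16")
  if (grid_size %% 2 != 0) stop("grid_size must be even")
  if (aperture_radius_fraction <= 0 || aperture_radius_fraction > 1)
    stop("aperture_radius_fraction must be in (0, 1]")
  basis <- zernike_basis(spec$noll_indices, grid_size, aperture_radius_fraction)
  wavefront_from_basis(basis, spec$coefficients)
}

# Fast path: wavefront map from a precomputed basis and a raw
# coefficient vector.
wavefront_from_basis <- function(basis, coefficients) {
  phase <- matrix(0, basis$grid_size, basis$grid_size)
  phase[basis$mask_index] <- as.vector(basis$basis %*% coefficients)
  structure(list(phase = phase, mask = basis$mask,
                 grid_size = basis$grid_size,
                 aperture_radius_fraction = basis$aperture_radius_fraction),
            class = "wavefront_map")
}
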