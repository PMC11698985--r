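# Shared fixtures, generated in code.

# A small, deterministic, textured non-negative image.
fixture_image <- function(nr = 40, nc = 40, seed = 11) {
  set.seed(seed)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  img <- 0.5 + 0.3 * sin(x / 3) * cos(y / 4) + 0.1 * sin((x + y) / 5)
  img + matrix(runif(nr * nc, 0, 0.05), nr, nc)
}

# Discrete delta kernel of odd side k.
fixture_delta <- function(k = 21) {
  d <- matrix(0, k, k)
  d[(k + 1) / 2, (k + 1) / 2] <- 1
  d
}

# A moderately aberrated wavefront used across tests.
fixture_spec <- function() {
  wavefront_spec(c(0.4, -0.2, -1.5, 0.5, 0.8, 0.15, -0.2))
}

# Numerical quadrature of the product of two Noll modes over the unit
# disk (independent orthogonality oracle).  Gauss-Legendre in radius is
# exact for the polynomial radial part; a uniform azimuthal grid is
# exact for the trigonometric part.
disk_inner_product <- function(noll_a, noll_b, n_r = 32, n_t = 64) {
  gl <- pracma::gaussLegendre(n_r, 0, 1)
  t_mid <- (seq_len(n_t) - 0.5) * 2 * pi / n_t
  dt <- 2 * pi / n_t
  total <- 0
  for (th in t_mid) {
    za <- zernike_eval(noll_a, gl$x, th)
    zb <- zernike_eval(noll_b, gl$x, th)
    total <- total + sum(gl$w * za * zb * gl$x) * dt
  }
  total / pi   # disk-average (area pi)
}
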