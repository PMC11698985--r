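# Coefficient-field fitting: low-order polynomial models of each
# Zernike coefficient over (patch-x, patch-y, wavelength).

# Polynomial term exponents: per-axis caps plus a total-degree cap, so
# the default model is a joint third-order polynomial in (x, y, lambda)
# rather than a full tensor product (whose term count would leave a
# nine-point key scheme with almost no residual degrees of freedom).
poly_terms <- function(ox, oy, ol, total = max(ox, oy, ol)) {
  g <- expand.grid(i = 0:ox, j = 0:oy, k = 0:ol)
  g <- g[g$i + g$j + g$k <= total, , drop = FALSE]
  g[order(g$i + g$j + g$k, g$i, g$j, g$k), , drop = FALSE]
}

# Design matrix for standardized coordinates.
poly_design <- function(x, y, l, terms) {
  m <- matrix(1, length(x), nrow(terms))
  for (t in seq_len(nrow(terms)))
    m[, t] <- x^terms$i[t] * y^terms$j[t] * l^terms$k[t]
  m
}

standardize <- function(v) {
  ctr <- mean(range(v))
  scl <- diff(range(v)) / 2
  if (scl == 0) scl <- 1
  list(center = ctr, scale = scl, z = (v - ctr) / scl)
}

#' Fit polynomial coefficient models across space and wavelength
#'
#' For every Zernike coefficient a least-squares polynomial in
#' (patch-center x, patch-center y, wavelength) is fitted to the key
#' knots, with tensor-product terms of per-axis order
#' `min(order, distinct positions - 1)`.  With the nine-point key-patch
#' scheme there are only three distinct positions per spatial axis, so
#' the spatial order reduces to 2 while the full third order is kept
#' spectrally whenever enough key frames support it.  Coordinates are
#' centered and scaled to `[-1, 1]` before fitting for conditioning.
#' A rank-deficient system triggers an automatic order reduction with a
#' warning.
#'
#' Fitting is robust by default: iteratively reweighted least squares
#' with Huber weights (tuning constant 1.345 x MAD) down-weights
#' outlier knots.  Individual annealed knots can fail — typically
#' frame-corner patches at noisy bands, where the deconvolution
#' objective is least informative — and a plain least-squares fit lets
#' one such knot bend the whole surface.  When the residuals are
#' (numerically) zero the weights stay at one, so exact polynomial
#' inputs are still reproduced to machine precision.
#'
#' @param knots data frame with columns `wavelength_nm`, `patch_row`,
#'   `patch_col` and one `z<noll>` column per coefficient (the layout of
#'   [write_coef_table()]).
#' @param grid a [patch_grid()] used to convert patch indices to
#'   patch-center pixel coordinates.
#' @param spatial_order,spectral_order maximum polynomial orders
#'   (default 3).
#' @param robust use Huber IRLS (default) instead of plain least
#'   squares.
#' @return An object of class `coefficient_field`: per-coefficient
#'   models, standardization constants, fitted residuals, robustness
#'   weights and the knot table.
#' @export
fit_coefficient_field <- function(knots, grid, spatial_order = 3,
                                  spectral_order = 3, robust = TRUE) {
  zc <- grep("^z[0-9]+$", names(knots), value = TRUE)
  if (length(zc) == 0) stop("knot table has no z<noll> coefficient columns")
  noll <- as.integer(sub("^z", "", zc))
  if (length(unique(knots$wavelength_nm)) < 2)
    stop("need at least 2 key frames")
  if (nrow(unique(knots[, c("patch_row", "patch_col")])) < 4)
    stop("need at least 4 key patches per frame")

  # knot coordinates: explicit window centers when recorded (key windows
  # shift inward at frame edges), else patch centers
  if (all(c("x_px", "y_px") %in% names(knots))) {
    x_px <- knots$x_px
    y_px <- knots$y_px
  } else {
    x_px <- knots$patch_col * grid$patch + (grid$patch - 1) / 2
    y_px <- knots$patch_row * grid$patch + (grid$patch - 1) / 2
  }
  sx <- standardize(x_px); sy <- standardize(y_px)
  sl <- standardize(knots$wavelength_nm)
  ox <- min(spatial_order, length(unique(x_px)) - 1)
  oy <- min(spatial_order, length(unique(y_px)) - 1)
  ol <- min(spectral_order, length(unique(knots$wavelength_nm)) - 1)

  irls <- function(X, yvals) {
    w <- rep(1, length(yvals))
    fit <- lm.fit(X, yvals)
    if (robust) {
      for (it in 1:10) {
        s <- stats::mad(fit$residuals, center = 0)
        if (s < 1e-10) break
        w_new <- pmin(1, 1.345 * s / pmax(abs(fit$residuals), 1e-300))
        fit <- stats::lm.wfit(X, yvals, w_new)
        if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
        w <- w_new
      }
      fit$residuals <- yvals - as.vector(X %*% ifelse(is.na(fit$coefficients),
                                                      0, fit$coefficients))
    }
    list(fit = fit, weights = w)
  }
  fit_one <- function(yvals, ox, oy, ol) {
    repeat {
      terms <- poly_terms(ox, oy, ol)
      X <- poly_design(sx$z, sy$z, sl$z, terms)
      res <- irls(X, yvals)
      if (res$fit$rank == ncol(X))
        return(list(terms = terms, beta = res$fit$coefficients,
                    residuals = res$fit$residuals, weights = res$weights,
                    orders = c(x = ox, y = oy, lambda = ol)))
      warning(sprintf("rank-deficient fit at orders (%d,%d,%d); reducing",
                      ox, oy, ol))
      mx <- which.max(c(ox, oy, ol))
      if (mx == 1) ox <- ox - 1 else if (mx == 2) oy <- oy - 1 else ol <- ol - 1
      if (ox < 0 || oy < 0 || ol < 0) stop("cannot fit coefficient field")
    }
  }
  models <- lapply(zc, function(col) fit_one(knots[[col]], ox, oy, ol))
  names(models) <- zc
  res <- vapply(models, function(m) m$residuals, numeric(nrow(knots)))
  structure(list(models = models, noll_indices = noll,
                 standardization = list(x = sx[c("center", "scale")],
                                        y = sy[c("center", "scale")],
                                        lambda = sl[c("center", "scale")]),
                 wavelength_range = range(knots$wavelength_nm),
                 spatial_range = list(x = range(x_px), y = range(y_px)),
                 knots = knots, residuals = res, grid = grid),
            class = "coefficient_field")
}

#' @export
print.coefficient_field <- function(x, ...) {
  ords <- x$models[[1]]$orders
  cat(sprintf("Coefficient field: %d Zernike modes, %d knots, orders (x=%d, y=%d, lambda=%d)\n",
              length(x$noll_indices), nrow(x$knots), ords[1], ords[2], ords[3]))
  cat(sprintf("  spectral range %g-%g nm, RMS residual %.2e rad\n",
              x$wavelength_range[1], x$wavelength_range[2],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

# Coefficient matrix (positions x modes) at pixel coordinates.
# Spatial coordinates are clamped to the knot hull: key windows sit at
# most half a patch inside the frame-edge patch centers, and evaluating
# the polynomial a few pixels beyond its support trades a negligible
# coefficient gradient for unbounded extrapolation error.
predict_field_coefficients <- function(field, wavelength, y_px, x_px) {
  n <- max(length(wavelength), length(y_px), length(x_px))
  wavelength <- rep_len(wavelength, n)
  y_px <- rep_len(y_px, n); x_px <- rep_len(x_px, n)
  if (!is.null(field$spatial_range)) {
    x_px <- pmin(pmax(x_px, field$spatial_range$x[1]), field$spatial_range$x[2])
    y_px <- pmin(pmax(y_px, field$spatial_range$y[1]), field$spatial_range$y[2])
  }
  s <- field$standardization
  xz <- (x_px - s$x$center) / s$x$scale
  yz <- (y_px - s$y$center) / s$y$scale
  lz <- (wavelength - s$lambda$center) / s$lambda$scale
  out <- vapply(field$models, function(m)
    as.vector(poly_design(xz, yz, lz, m$terms) %*% m$beta), numeric(n))
  matrix(out, nrow = n,
         dimnames = list(NULL, paste0("z", field$noll_indices)))
}

#' Evaluate a fitted coefficient field at one patch and wavelength
#'
#' @param field a `coefficient_field`.
#' @param wavelength wavelength (nm).
#' @param patch_row,patch_col 0-based patch indices.
#' @param extrapolate behavior outside the fitted spectral range:
#'   `"warn"` (default), `"error"`, `"silent"`, or `"clamp"` (evaluate
#'   at the nearest key wavelength instead of extrapolating).
#' @return A [wavefront_spec()].
#' @export
eval_field <- function(field, wavelength, patch_row, patch_col,
                       extrapolate = c("warn", "error", "silent", "clamp")) {
  extrapolate <- match.arg(extrapolate)
  stopifnot(inherits(field, "coefficient_field"))
  rng <- field$wavelength_range
  if (wavelength < rng[1] || wavelength > rng[2]) {
    if (extrapolate == "error")
      stop(sprintf("wavelength %g nm outside fitted range [%g, %g]",
                   wavelength, rng[1], rng[2]))
    if (extrapolate == "warn")
      warning(sprintf("wavelength %g nm outside fitted range [%g, %g]: extrapolating",
                      wavelength, rng[1], rng[2]))
    if (extrapolate == "clamp")
      wavelength <- min(max(wavelength, rng[1]), rng[2])
  }
  grid <- field$grid
  cf <- predict_field_coefficients(field, wavelength,
                                   patch_row * grid$patch + (grid$patch - 1) / 2,
                                   patch_col * grid$patch + (grid$patch - 1) / 2)
  # interpolated defocus may round to a tiny positive value; clamp rather
  # than reject so the sign convention survives interpolation
  cfv <- as.numeric(cf[1, ])
  i4 <- match(4L, field$noll_indices)
  constrained <- !is.na(i4)
  if (constrained) cfv[i4] <- min(cfv[i4], 0)
  wavefront_spec(cfv, field$noll_indices, defocus_constrained = constrained)
}

#' Serialize / restore a coefficient field
#'
#' JSON round trip (fit orders, standardization constants, polynomial
#' coefficients and the knot table) that restores the field bit-exactly.
#'
#' @param field a `coefficient_field`.
#' @param path JSON path.
#' @export
write_field <- function(field, path) {
  # model coefficients and standardization constants are written as C99
  # hex doubles so evaluation after a round trip is bit-identical
  payload <- list(
    noll_indices = field$noll_indices,
    wavelength_range = field$wavelength_range,
    standardization = rapply(field$standardization, function(v)
      sprintf("%a", v), how = "replace"),
    spatial_range = rapply(field$spatial_range, function(v)
      sprintf("%a", v), how = "replace"),
    grid = unclass(field$grid),
    models = lapply(field$models, function(m)
      list(orders = as.list(m$orders), terms = m$terms,
           beta = sprintf("%a", as.numeric(m$beta)))),
    knots = field$knots)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- structure(as.list(p$grid), class = "patch_grid")
  p$standardization <- rapply(p$standardization, as.numeric, how = "replace")
  p$spatial_range <- rapply(p$spatial_range, as.numeric, how = "replace")
  models <- lapply(p$models, function(m)
    list(terms = as.data.frame(m$terms), beta = as.numeric(m$beta),
         orders = unlist(m$orders)))
  knots <- as.data.frame(p$knots)
  kx <- if ("x_px" %in% names(knots)) knots$x_px
        else knots$patch_col * grid$patch + (grid$patch - 1) / 2
  ky <- if ("y_px" %in% names(knots)) knots$y_px
        else knots$patch_row * grid$patch + (grid$patch - 1) / 2
  res <- vapply(seq_along(models), function(i) {
    col <- names(models)[i]
    s <- p$standardization
    X <- poly_design((kx - s$x$center) / s$x$scale,
                     (ky - s$y$center) / s$y$scale,
                     (knots$wavelength_nm - s$lambda$center) / s$lambda$scale,
                     models[[i]]$terms)
    knots[[col]] - as.vector(X %*% models[[i]]$beta)
  }, numeric(nrow(knots)))
  colnames(res) <- names(models)
  structure(list(models = models, noll_indices = as.integer(p$noll_indices),
                 standardization = p$standardization,
                 wavelength_range = as.numeric(p$wavelength_range),
                 spatial_range = p$spatial_range,
                 knots = knots, residuals = res, grid = grid),
            class = "coefficient_field")
}
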