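# Helper: knot table from a generator function over the nine-point
# scheme and a set of key wavelengths.
make_knots <- function(grid, wavelengths, gen) {
  keys <- key_patch_indices(grid)
  out <- NULL
  for (wl in wavelengths) {
    for (i in seq_len(nrow(keys))) {
      x <- keys$col[i] * grid$patch + (grid$patch - 1) / 2
      y <- keys$row[i] * grid$patch + (grid$patch - 1) / 2
      cf <- gen(x, y, wl)
      out <- rbind(out, cbind(
        data.frame(frame = match(wl, wavelengths) - 1L, wavelength_nm = wl,
                   patch_row = keys$row[i], patch_col = keys$col[i]),
        as.data.frame(as.list(setNames(cf, paste0("z", seq_along(cf) + 1))))))
    }
  }
  out
}

test_that("a cubic spectral generator is reproduced exactly at and between knots", {
  g <- patch_grid(160, 120, 40, 10)
  wls <- seq(550, 950, 100)
  gen <- function(x, y, wl) {
    l <- (wl - 750) / 200
    c(0.5 * l^3 - 0.2 * l, 0.1, -1 - 0.3 * l^2, 0.2 * l, 0, 0.05, -0.1 * l^3)
  }
  field <- fit_coefficient_field(make_knots(g, wls, gen), g)
  for (wl in c(575, 700, 812.5, 950)) {
    got <- eval_field(field, wl, 1, 2, extrapolate = "silent")
    expect_equal(got$coefficients, gen(NA, NA, wl), tolerance = 1e-9)
  }
})

test_that("a quadratic spatial generator is reproduced at off-key patches", {
  g <- patch_grid(160, 120, 40, 10)
  wls <- c(600, 750, 900)
  gen <- function(x, y, wl) {
    xs <- (x - 80) / 80; ys <- (y - 60) / 60
    c(0.3 * xs, 0.2 * ys, -1 - 0.4 * xs^2 - 0.2 * ys^2 - 0.1 * xs * ys,
      0.15 * xs * ys, 0.1 * (xs^2 - ys^2), 0, 0)
  }
  field <- fit_coefficient_field(make_knots(g, wls, gen), g)
  # patch (1, 2) is not a key patch on the 3 x 4 grid
  x <- 2 * 40 + 19.5; y <- 1 * 40 + 19.5
  got <- eval_field(field, 675, 1, 2, extrapolate = "silent")
  expect_equal(got$coefficients, gen(x, y, 675), tolerance = 1e-9)
})

test_that("constant knots give a constant field", {
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) c(0.3, -0.1, -0.8, 0.2, 0, 0.1, -0.05)
  field <- fit_coefficient_field(make_knots(g, c(600, 750, 900), gen), g)
  a <- eval_field(field, 623, 0, 0, extrapolate = "silent")
  b <- eval_field(field, 877, 2, 3, extrapolate = "silent")
  expect_equal(a$coefficients, gen(0, 0, 0), tolerance = 1e-9)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
})

test_that("evaluation at a knot stays within the fit residual", {
  set.seed(41)
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) {
    l <- (wl - 750) / 200
    base <- c(0.4 * l, 0.1, -1 - 0.3 * l^2, 0.1 * l, 0, 0, 0)
    base + rnorm(7, sd = 0.02)
  }
  knots <- make_knots(g, seq(550, 950, 100), gen)
  field <- fit_coefficient_field(knots, g)
  k <- 17
  got <- eval_field(field, knots$wavelength_nm[k], knots$patch_row[k],
                    knots$patch_col[k], extrapolate = "silent")
  stored <- as.numeric(knots[k, grep("^z", names(knots))])
  resid <- unname(field$residuals[k, ])
  expect_equal(got$coefficients, stored - resid, tolerance = 1e-8)
})

test_that("fitting a noisy quadratic beats nearest-knot lookup", {
  set.seed(42)
  g <- patch_grid(160, 120, 40, 10)
  truth <- function(x, y, wl) {
    l <- (wl - 750) / 200
    -1 - 0.5 * l^2 - 0.3 * ((x - 80) / 80)^2
  }
  gen <- function(x, y, wl) {
    c(0, 0, truth(x, y, wl) + rnorm(1, sd = 0.05), 0, 0, 0, 0)
  }
  wls <- seq(550, 950, 100)
  knots <- make_knots(g, wls, gen)
  field <- fit_coefficient_field(knots, g)
  # evaluation points off the knot lattice
  test_pts <- expand.grid(wl = c(620, 700, 840), row = 0:2, col = 0:3)
  err_fit <- err_nn <- numeric(nrow(test_pts))
  for (i in seq_len(nrow(test_pts))) {
    p <- test_pts[i, ]
    x <- p$col * 40 + 19.5; y <- p$row * 40 + 19.5
    tv <- truth(x, y, p$wl)
    got <- eval_field(field, p$wl, p$row, p$col, extrapolate = "silent")
    err_fit[i] <- got$coefficients[3] - tv
    d <- (knots$patch_col * 40 + 19.5 - x)^2 +
      (knots$patch_row * 40 + 19.5 - y)^2 + (knots$wavelength_nm - p$wl)^2
    err_nn[i] <- knots$z4[which.min(d)] - tv
  }
  expect_lt(sqrt(mean(err_fit^2)), sqrt(mean(err_nn^2)))
})

test_that("a monotone knot ramp evaluates monotonically between knots", {
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) c(0, 0, -0.5 - 0.002 * (wl - 550), 0, 0, 0, 0)
  field <- fit_coefficient_field(make_knots(g, seq(550, 950, 100), gen), g)
  wl_seq <- seq(550, 950, 20)
  vals <- vapply(wl_seq, function(wl)
    eval_field(field, wl, 1, 1, extrapolate = "silent")$coefficients[3],
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("spectral extrapolation is flagged and clamping is available", {
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) c(0, 0, -1 - 0.001 * (wl - 550), 0, 0, 0, 0)
  field <- fit_coefficient_field(make_knots(g, c(600, 750, 900), gen), g)
  expect_warning(eval_field(field, 500, 0, 0), "extrapolat")
  expect_error(eval_field(field, 500, 0, 0, extrapolate = "error"), "outside")
  clamped <- eval_field(field, 500, 0, 0, extrapolate = "clamp")
  at_edge <- eval_field(field, 600, 0, 0, extrapolate = "silent")
  expect_equal(clamped$coefficients, at_edge$coefficients, tolerance = 1e-9)
})

test_that("insufficient knots are rejected", {
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) numeric(7)
  one_frame <- make_knots(g, 750, gen)
  expect_error(fit_coefficient_field(one_frame, g), "2 key frames")
})

test_that("a field round-trips exactly through its JSON serialization", {
  set.seed(43)
  g <- patch_grid(160, 120, 40, 10)
  gen <- function(x, y, wl) {
    l <- (wl - 750) / 200
    c(0.4 * l, 0.1, -1 - 0.3 * l^2, 0.1 * l, 0, 0, 0) + rnorm(7, sd = 0.01)
  }
  field <- fit_coefficient_field(make_knots(g, seq(550, 950, 100), gen), g)
  path <- file.path(tempdir(), "field.json")
  write_field(field, path)
  back <- read_field(path)
  a <- eval_field(field, 687, 1, 2, extrapolate = "silent")
  b <- eval_field(back, 687, 1, 2, extrapolate = "silent")
  expect_identical(a$coefficients, b$coefficients)
})
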