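test_that("patch grid reproduces the instrument tiling counts", {
  g <- patch_grid(640, 480, 80, 10)
  expect_equal(g$cols, 8)
  expect_equal(g$rows, 6)
  expect_equal(g$n_patches, 48)
  expect_error(patch_grid(641, 480, 80), "multiple")
  expect_error(patch_grid(640, 470, 80), "multiple")
})

test_that("tiling produces border-extended patches and round-trips exactly", {
  set.seed(2)
  frame <- matrix(runif(120 * 160), 120, 160)
  g <- patch_grid(160, 120, 40, 10)
  patches <- tile_frame(frame, g)
  expect_length(patches, 12)
  expect_true(all(vapply(patches, function(p) all(dim(p) == 60), logical(1))))
  # interior of an interior patch matches the frame directly
  p <- patches[[6]]   # row 1, col 1 (0-based), fully interior
  expect_equal(p[11:50, 11:50], frame[41:80, 41:80])
  # extended border of an interior patch comes from the frame, not reflection
  expect_equal(p, frame[31:90, 31:90])
  expect_equal(assemble_frame(patches, g), frame)
  expect_error(tile_frame(frame[1:100, ], g), "expects")
})

test_that("full instrument geometry tiles into 100 x 100 extended patches", {
  frame <- matrix(0.5, 480, 640)
  frame[1, 1] <- 1
  g <- patch_grid(640, 480, 80, 10)
  patches <- tile_frame(frame, g)
  expect_length(patches, 48)
  expect_equal(dim(patches[[1]]), c(100, 100))
  expect_equal(assemble_frame(patches, g), frame)
})

test_that("Richardson-Lucy honors the delta fixed point and non-negativity", {
  img <- fixture_image(60, 60)
  delta <- fixture_delta(21)
  for (iters in c(1, 16, 128)) {
    out <- richardson_lucy(img, delta, iters)
    expect_equal(out, img, tolerance = 1e-12)
  }
  kern <- psf_from_spec(fixture_spec(), 64, 0.5, 21)
  blurred <- pmax(wavepsf:::conv2_reflect_cpp(img, unclass(kern)), 0)
  out <- richardson_lucy(blurred, kern, 64)
  expect_true(all(out >= 0))
  expect_error(richardson_lucy(img - 1, delta, 8), "non-negative")
  expect_error(richardson_lucy(img, unclass(kern) * 2, 8), "unit sum")
})

test_that("Richardson-Lucy sharpens a blurred patch toward the truth", {
  set.seed(6)
  truth <- fixture_image(60, 60)
  kern <- psf_from_spec(fixture_spec(), 64, 0.5, 21)
  blurred <- pmax(wavepsf:::conv2_reflect_cpp(truth, unclass(kern)) +
                    matrix(rnorm(3600, 0, 0.003), 60, 60), 0)
  dec <- richardson_lucy(blurred, kern, 128)
  int <- function(m) m[11:50, 11:50]
  expect_gt(ncc(int(dec), int(truth)), ncc(int(blurred), int(truth)))
})

test_that("Richardson-Lucy approximately conserves flux on interior-supported scenes", {
  # content confined to the interior so reflective boundaries carry
  # negligible flux in or out
  img <- matrix(1e-4, 80, 80)
  xg <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  yg <- matrix(seq_len(80), 80, 80)
  img <- img + exp(-((xg - 40)^2 + (yg - 42)^2) / 30) +
    0.5 * exp(-((xg - 35)^2 + (yg - 38)^2) / 12)
  kern <- psf_from_spec(fixture_spec(), 64, 0.5, 21)
  blurred <- pmax(wavepsf:::conv2_reflect_cpp(img, unclass(kern)), 0)
  dec <- richardson_lucy(blurred, kern, 128)
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 1e-3)
})

test_that("Wiener deconvolution limits behave as expected", {
  img <- fixture_image(48, 48)
  delta <- fixture_delta(15)
  out <- wiener(img, delta, 1e-12)
  expect_equal(out, img, tolerance = 1e-6)
  # huge regularization damps the output toward zero
  damped <- wiener(img, delta, 1e6)
  expect_lt(max(abs(damped)), 1e-3)
  # forward-model residual comparable to Richardson-Lucy on the same input
  kern <- psf_from_spec(fixture_spec(), 64, 0.5, 21)
  blurred <- pmax(wavepsf:::conv2_reflect_cpp(img, unclass(kern)), 0)
  resid <- function(est) {
    refit <- wavepsf:::conv2_reflect_cpp(est, unclass(kern))
    sqrt(mean((refit - blurred)^2))
  }
  r_wiener <- resid(pmax(wiener(blurred, kern, 1e-3), 0))
  r_rl <- resid(richardson_lucy(blurred, kern, 128))
  r_baseline <- sqrt(mean((blurred - mean(blurred))^2))
  expect_lt(r_wiener, r_baseline)
  expect_lt(r_rl, r_baseline)
  expect_lt(abs(r_wiener - r_rl), 0.1 * r_baseline)
})

test_that("cube deconvolution with delta PSFs is the identity and is deterministic", {
  set.seed(8)
  arr <- array(runif(40 * 40 * 3, 0.1, 0.9), c(40, 40, 3))
  cube <- hyper_cube(arr, c(600, 650, 700))
  g <- patch_grid(40, 40, 20, 5)
  delta <- fixture_delta(9)
  psfs <- replicate(3, replicate(4, delta, simplify = FALSE), simplify = FALSE)
  out <- deconvolve_cube(cube, psfs, g, deconv_config(iterations = 16))
  expect_equal(out$data, cube$data, tolerance = 1e-10)
  out2 <- deconvolve_cube(cube, psfs, g, deconv_config(iterations = 16))
  expect_identical(out$data, out2$data)
  # missing PSF triggers an indexed error
  bad <- psfs; bad[[2]] <- bad[[2]][1:3]
  expect_error(deconvolve_cube(cube, bad, g, deconv_config(iterations = 2)),
               "frame 1, patch 3")
})

test_that("patchwise deconvolution leaves no seams on a smooth scene", {
  xg <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  yg <- matrix(seq_len(80), 80, 80)
  smooth <- 0.4 + 0.2 * sin(xg / 17) + 0.2 * cos(yg / 13)
  g <- patch_grid(80, 80, 40, 10)
  kern <- psf_from_spec(wavefront_spec(c(0, 0, -1, 0.3, 0.2, 0, 0)), 64, 0.5, 21)
  blurred <- pmax(wavepsf:::conv2_reflect_cpp(smooth, unclass(kern)), 0)
  dec <- deconvolve_frame(blurred, replicate(4, kern, simplify = FALSE), g,
                          deconv_config(iterations = 32))
  # discontinuity across the internal patch boundary vs typical gradient
  seam_r <- max(abs(dec[40, ] - dec[41, ]))
  seam_c <- max(abs(dec[, 40] - dec[, 41]))
  typical <- max(abs(diff(smooth[, 41])), abs(diff(smooth[41, ])))
  expect_lt(seam_r, 5 * typical)
  expect_lt(seam_c, 5 * typical)
})
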