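test_that("the template is reproducible, high-contrast, with edges in all octants", {
  spec <- scene_spec("small", seed = 5)
  t1 <- make_template(spec)
  t2 <- make_template(scene_spec("small", seed = 5))
  expect_identical(t1, t2)
  expect_false(identical(t1, make_template(scene_spec("small", seed = 6))))
  # contrast spans >= 80 % of the [0, 1] dynamic range
  expect_gte(diff(range(t1)), 0.8)
  # gradient-orientation histogram (central differences): every
  # 45-degree octant populated by strong edges
  n <- nrow(t1); m <- ncol(t1)
  gx <- (t1[2:(n - 1), 3:m] - t1[2:(n - 1), 1:(m - 2)]) / 2
  gy <- (t1[3:n, 2:(m - 1)] - t1[1:(n - 2), 2:(m - 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  strong <- mag > 0.25 * max(mag)
  ang <- atan2(gy[strong], gx[strong]) %% (2 * pi)
  octant <- floor(((ang + pi / 8) %% (2 * pi)) / (pi / 4))
  bins <- table(factor(octant, levels = 0:7))
  expect_true(all(bins > 50))
})

test_that("zero aberration and zero noise reduce the forward model to diffraction", {
  spec <- scene_spec("small", seed = 5,
                     wavelengths = seq(550, 950, 200),
                     field_fun = function(noll, x, y, l) 0)
  sim <- forward_blur_cube(spec, noise = FALSE)
  # all bands identical (no spectral variation left) and close to the
  # template up to the diffraction-limited kernel
  expect_identical(sim$cube$data[, , 1], sim$cube$data[, , 3])
  expect_gte(ncc(sim$cube$data[, , 1], sim$template), 0.9)
  # the returned kernels are exactly those applied: re-blurring the
  # template patchwise reproduces the cube bit-for-bit
  tp <- tile_frame(sim$template, spec$grid)
  reblur <- assemble_frame(lapply(seq_along(tp), function(p)
    wavepsf:::conv2_reflect_cpp(tp[[p]], unclass(sim$psfs[[2]][[p]]))),
    spec$grid)
  expect_equal(sim$cube$data[, , 2], pmax(reblur, 0), tolerance = 1e-12)
  # the diffraction kernel is a centered Airy spot
  k <- unclass(sim$psfs[[1]][[1]])
  expect_equal(which(k == max(k)), 10 * 21 + 11)   # center pixel (11, 11)
  expect_gt(sum(k[10:12, 10:12]), 0.5)
})

test_that("a pure tip ramp moves a point source linearly with wavelength", {
  # shift-theorem oracle: tip c2 shifts the PSF centroid by
  # -2 c2 / (pi * frac) pixels along x; a linear-in-lambda c2 gives a
  # linear-in-lambda centroid track
  spec <- scene_spec("small", seed = 5, wavelengths = seq(550, 950, 100),
                     sigma_mid = 0, sigma_edge = 0,
                     field_fun = function(noll, x, y, l)
                       if (noll == 2) 1.2 * l else 0)
  ps <- point_source_cube(spec)
  ctr <- ps$centers[5, ]   # an interior source
  sl <- wavepsf:::standardize(range(spec$wavelengths))
  xs <- vapply(seq_along(spec$wavelengths), function(b)
    centroid(ps$cube$data[, , b], ctr$row, ctr$col, 15)[2], numeric(1))
  l <- (spec$wavelengths - sl$center) / sl$scale
  expected <- ctr$col - 2 * (1.2 * l) / (pi * 0.5)
  expect_equal(xs, expected, tolerance = 0.08)
  # linearity: residual from a straight-line fit is tiny
  fit <- lm.fit(cbind(1, l), xs)
  expect_lt(max(abs(fit$residuals)), 0.05)
})

test_that("noise grows toward the spectral-range edges, minimizing edge SNR", {
  spec <- scene_spec("small", seed = 5, wavelengths = seq(550, 950, 50))
  sig <- wavepsf:::noise_sigma(spec)
  expect_equal(max(sig), spec$sigma_edge, tolerance = 1e-12)
  expect_equal(sig[which.min(abs(spec$wavelengths - 750))], spec$sigma_mid,
               tolerance = 1e-12)
  expect_true(all(diff(sig[spec$wavelengths <= 750]) <= 0))
  expect_true(all(diff(sig[spec$wavelengths >= 750]) >= 0))
  # realized per-band SNR is worst at the first/last frames
  sim <- forward_blur_cube(spec)
  clean <- forward_blur_cube(spec, noise = FALSE)
  snr <- vapply(seq_along(spec$wavelengths), function(b) {
    s <- clean$cube$data[, , b]
    n <- sim$cube$data[, , b] - s
    sd(s) / sd(n)
  }, numeric(1))
  expect_lt(snr[1], min(snr[4:6]))
  expect_lt(snr[length(snr)], min(snr[4:6]))
})

test_that("the point-source array has one source per patch and recovers the true PSFs", {
  spec <- scene_spec("small", seed = 5, wavelengths = c(650, 750, 850))
  ps <- point_source_cube(spec)
  expect_equal(nrow(ps$centers), spec$grid$n_patches)
  # instrument-geometry layout: 6 x 8 = 48 sources
  g <- patch_grid(640, 480, 80)
  expect_equal(g$n_patches, 48)
  # extracted kernels match the true PSFs at zero noise
  for (b in c(1, 3)) {
    for (p in c(1, 6, 12)) {
      ext <- extract_kernel(ps$cube$data[, , b], ps$centers$row[p],
                            ps$centers$col[p], 21)
      expect_gte(ncc(ext, unclass(ps$psfs[[b]][[p]])), 0.99)
    }
  }
})

test_that("point-source extraction degrades monotonically with noise", {
  nccs <- vapply(c(0, 0.01, 0.05), function(sg) {
    spec <- scene_spec("small", seed = 9, wavelengths = c(700, 750, 800),
                       sigma_mid = sg, sigma_edge = sg)
    ps <- point_source_cube(spec, noise = TRUE)
    mean(vapply(seq_len(spec$grid$n_patches), function(p)
      ncc(extract_kernel(ps$cube$data[, , 2], ps$centers$row[p],
                         ps$centers$col[p], 21),
          unclass(ps$psfs[[2]][[p]])), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(nccs) < 0))
})

test_that("the small-preset geometry and defaults define the study conditions", {
  spec <- scene_spec("small")
  expect_equal(c(spec$width, spec$height, spec$patch), c(160, 120, 40))
  expect_equal(length(spec$wavelengths), 41)
  expect_equal(spec$grid$n_patches, 12)
  inst <- scene_spec("instrument")
  expect_equal(c(inst$width, inst$height, inst$patch), c(640, 480, 80))
  expect_equal(length(inst$wavelengths), 501)
  expect_equal(inst$grid$n_patches, 48)
  # total patch count of a full acquisition
  expect_equal(length(inst$wavelengths) * inst$grid$n_patches, 24048)
  # true defocus is non-positive everywhere
  cf <- wavepsf:::true_coefficients(spec, 1)
  expect_true(all(cf[, "z4"] < 0))
})
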