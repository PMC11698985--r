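test_that("perturbation draws stay inside the epsilon box and are unbiased", {
  set.seed(31)
  c0 <- c(0.5, -0.2, -1.0, 0.3, 0.1, 0, 0.2)
  expect_identical(perturb(c0, 0), c0)   # degenerate interval
  draws <- t(replicate(2000, perturb(c0, 0.2, defocus_constrained = FALSE)))
  expect_true(all(abs(sweep(draws, 2, c0)) <= 0.2 + 1e-12))
  # uniform moments oracle: mean deviation ~ N(0, eps/sqrt(3 n))
  devs <- colMeans(sweep(draws, 2, c0))
  expect_true(all(abs(devs) < 3 * 0.2 / sqrt(3 * 2000)))
})

test_that("the defocus constraint clamps perturbations at zero", {
  set.seed(32)
  c0 <- c(0, 0, -0.01, 0, 0, 0, 0)
  draws <- t(replicate(500, perturb(c0, 0.3, noll_indices = 2:8,
                                    defocus_constrained = TRUE)))
  expect_true(all(draws[, 3] <= 0))
  expect_true(any(draws[, 3] > -0.01))   # clamp active, not just rare
  # explicit bounds are honored too
  draws2 <- t(replicate(200, perturb(c0, 0.5, lower = -0.2, upper = 0.2)))
  expect_true(all(draws2 >= -0.2 & draws2 <= 0.2))
})

test_that("acceptance probability follows the annealing rule", {
  expect_equal(accept_probability(-90, -95, 5), 1)       # better: always
  expect_equal(accept_probability(-90, -90, 5), 1)       # equal: exp(0)
  # direct evaluation of the exponential
  expect_equal(accept_probability(-90, -80, 10), exp(-1), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    q <- runif(1, -100, 100); dq <- runif(1, 0, 50); temp <- runif(1, 0.1, 20)
    expect_equal(accept_probability(q, q + dq, temp), exp(-dq / temp),
                 tolerance = 1e-12)
  }
  expect_error(accept_probability(-90, -80, 0), "temperature")
})

test_that("empirical acceptance of worse moves matches exp(dQ/T)", {
  set.seed(34)
  temp <- 2; dq <- 1.5
  n <- 4000
  acc <- mean(runif(n) <= accept_probability(-50, -50 + dq, temp))
  p <- exp(-dq / temp)
  expect_lt(abs(acc - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("the cooling schedule length follows the closed form", {
  cfg <- anneal_config(t0 = 10, alpha = 0.995, t_end = 0.1)
  expect_equal(wavepsf:::anneal_iterations(cfg),
               ceiling(log(0.1 / 10) / log(0.995)))
  cfg2 <- anneal_config(t0 = 1, alpha = 0.9, t_end = 0.5)
  expect_equal(wavepsf:::anneal_iterations(cfg2), ceiling(log(0.5) / log(0.9)))
  expect_error(anneal_config(alpha = 1.2), "alpha")
  expect_error(anneal_config(t0 = 1, t_end = 2), "t_end")
})

test_that("annealing is deterministic given a seed and best cost is monotone", {
  img <- fixture_image(44, 44)
  kern <- psf_from_spec(wavefront_spec(c(0, 0, -1.2, 0.4, 0, 0, 0)), 64, 0.5, 13)
  blur <- pmax(wavepsf:::conv2_reflect_cpp(img, unclass(kern)), 0)
  cfg <- anneal_config(t0 = 1, alpha = 0.9, t_end = 0.1, epsilon = 0.1)
  run <- function() anneal(blur, img, wavefront_spec(numeric(7)),
                           config = cfg,
                           deconv = deconv_config(iterations = 8),
                           psf = psf_options(grid_size = 32, out_size = 13),
                           border = 2, seed = 77)
  a <- run(); b <- run()
  expect_identical(a$state$trace, b$state$trace)
  expect_identical(a$spec$coefficients, b$spec$coefficients)
  expect_true(all(diff(a$state$trace$best_cost) <= 0))
  expect_equal(a$state$iterations, wavepsf:::anneal_iterations(cfg))
  expect_lte(a$state$best_cost, a$state$trace$cost[1])
})

test_that("an unblurred patch anneals to the zero-aberration optimum", {
  img <- fixture_image(44, 44)
  fit <- anneal(img, img, wavefront_spec(numeric(7)),
                config = anneal_config(t0 = 0.5, alpha = 0.95, t_end = 0.05,
                                       epsilon = 0.03),
                deconv = deconv_config(iterations = 8),
                psf = psf_options(grid_size = 64, out_size = 13),
                border = 2, seed = 5)
  # with no blur the optimum is the diffraction-limited (zero-aberration)
  # kernel; the annealer must stay in that basin
  k0 <- psf_from_spec(wavefront_spec(numeric(7)), 64, 0.5, 13)
  expect_gte(ncc(unclass(fit$psf), unclass(k0)), 0.99)
  expect_error(anneal(img, matrix(1, 44, 44), wavefront_spec(numeric(7)),
                      border = 2), "constant")
})

test_that("the nine-point key scheme enumerates corners, edge centers and center", {
  g <- patch_grid(640, 480, 80)   # 6 x 8 patches
  keys <- key_patch_indices(g)
  got <- paste(keys$row, keys$col)
  want <- c("0 0", "0 3", "0 7", "2 0", "2 3", "2 7", "5 0", "5 3", "5 7")
  expect_setequal(got, want)
  g2 <- patch_grid(160, 120, 40)  # 3 x 4 patches
  keys2 <- key_patch_indices(g2)
  expect_equal(nrow(keys2), 9)
  expect_setequal(unique(keys2$row), c(0, 1, 2))
  expect_setequal(unique(keys2$col), c(0, 1, 3))
})

test_that("key-frame selection takes every 50th frame within 550-950 nm", {
  wl <- seq(500, 1000, 1)
  kf <- key_frame_indices(wl)
  expect_length(kf, 9)
  expect_equal(wl[kf], seq(550, 950, 50))
  # scaled axis
  wl2 <- seq(550, 950, 10)
  expect_equal(wl2[key_frame_indices(wl2, 550, 950, 100)],
               seq(550, 950, 100))
})

test_that("coarse defocus scan lands in the right basin", {
  img <- fixture_image(60, 60)
  kern <- psf_from_spec(wavefront_spec(c(0, 0, -1.6, 0, 0, 0, 0)), 64, 0.5, 21)
  blur <- pmax(wavepsf:::conv2_reflect_cpp(img, unclass(kern)), 0)
  init <- coarse_initial(blur, img, defocus_grid = seq(-3, 0, 0.2),
                         deconv = deconv_config(iterations = 16),
                         border = 10)
  expect_lt(abs(init$coefficients[3] - (-1.6)), 0.41)
  expect_true(all(init$coefficients[-3] == 0))
})
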