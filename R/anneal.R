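#' Simulated-annealing configuration
#'
#' Geometric cooling: the temperature starts at `t0`, is multiplied by
#' `alpha` after every iteration, and the run stops once it falls to
#' `t_end`, giving `ceiling(log(t_end / t0) / log(alpha))` iterations.
#' The defaults (t0 = 10, alpha = 0.995, t_end = 0.1, epsilon = 0.05
#' rad) give 919 iterations, the same order as a typical single-patch
#' optimization of a few hundred steps; all values are tunable.
#'
#' @param t0 initial temperature (same scale as the cost, i.e. -100 x
#'   NCC units).
#' @param alpha cooling factor in (0, 1).
#' @param t_end end temperature, `< t0`.
#' @param epsilon half-width of the uniform coefficient perturbation
#'   (radians).
#' @param defocus_constrained clamp the defocus (Noll 4) coefficient to
#'   non-positive values during perturbation, removing the +/- defocus
#'   wavefront ambiguity.
#' @param lower,upper optional coefficient bounds (scalar or vector).
#' @export
anneal_config <- function(t0 = 10, alpha = 0.995, t_end = 0.1,
                          epsilon = 0.05, defocus_constrained = TRUE,
                          lower = NULL, upper = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (t_end >= t0 || t_end <= 0) stop("need 0 < t_end < t0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(t0 = t0, alpha = alpha, t_end = t_end, epsilon = epsilon,
                 defocus_constrained = isTRUE(defocus_constrained),
                 lower = lower, upper = upper),
            class = "anneal_config")
}

# Number of cooling steps until t0 * alpha^k <= t_end.
anneal_iterations <- function(config) {
  as.integer(ceiling(log(config$t_end / config$t0) / log(config$alpha)))
}

#' Perturb a coefficient vector
#'
#' Every component is redrawn uniformly from
#' `[c_i - epsilon, c_i + epsilon]`, then clamped to the configured
#' bounds (including defocus `<= 0` when constrained).
#'
#' @param coefficients numeric vector.
#' @param epsilon perturbation half-width (`>= 0`).
#' @param noll_indices Noll indices matching the coefficients (used to
#'   locate defocus).
#' @param defocus_constrained clamp Noll-4 to non-positive values.
#' @param lower,upper optional bounds, recycled over components.
#' @return Perturbed numeric vector; uses R's RNG stream.
#' @export
perturb <- function(coefficients, epsilon, noll_indices = 2:8,
                    defocus_constrained = TRUE, lower = NULL, upper = NULL) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  out <- coefficients + runif(length(coefficients), -epsilon, epsilon)
  if (!is.null(lower)) out <- pmax(out, lower)
  if (!is.null(upper)) out <- pmin(out, upper)
  if (defocus_constrained) {
    i4 <- match(4L, noll_indices)
    if (!is.na(i4)) out[i4] <- min(out[i4], 0)
  }
  out
}

#' Acceptance probability for a candidate solution
#'
#' A better (lower-cost) candidate is always accepted; a worse one with
#' probability \eqn{\exp((Q - Q')/T)} where `Q` and `Q'` are the current
#' and candidate costs (minimization-oriented, -100 x NCC).
#'
#' @param q_current,q_new costs of the current and candidate solutions.
#' @param temperature positive temperature.
#' @return Probability in (0, 1].
#' @export
accept_probability <- function(q_current, q_new, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (q_new < q_current) return(1)
  exp((q_current - q_new) / temperature)
}

#' PSF computation options shared by the annealer and field evaluation
#'
#' @param grid_size pupil grid side (even; default 64 — enough angular
#'   resolution for a 21-px kernel while keeping the per-iteration FFT
#'   cheap).
#' @param aperture_radius_fraction aperture radius as fraction of the
#'   grid half-width (default 0.5, Nyquist-sampled PSF).
#' @param out_size odd PSF kernel side (default 21, comparable to the
#'   10-px deconvolution border).
#' @export
psf_options <- function(grid_size = 64, aperture_radius_fraction = 0.5,
                        out_size = 21) {
  if (out_size %% 2 != 1) stop("out_size must be odd")
  if (grid_size %% 2 != 0 || grid_size < out_size)
    stop("grid_size must be even and >= out_size")
  structure(list(grid_size = grid_size,
                 aperture_radius_fraction = aperture_radius_fraction,
                 out_size = out_size),
            class = "psf_options")
}

#' Estimate Zernike coefficients for one patch by simulated annealing
#'
#' Each iteration composes a wavefront from the candidate coefficients,
#' converts it to a PSF, Richardson-Lucy-deconvolves the observed
#' (border-extended) patch, crops the border, and scores the result
#' against the template patch with `-100 x` NCC.  Candidates are
#' accepted by the annealing rule and the temperature cools
#' geometrically until `t_end`.  The best solution ever visited is
#' returned, so the best NCC trace is monotone non-decreasing.
#'
#' @param patch observed border-extended patch (non-negative matrix).
#' @param template matching ground-truth patch: either the same
#'   extended size (the border is cropped before scoring) or already
#'   the interior size.
#' @param initial a [wavefront_spec()] starting solution.
#' @param config an [anneal_config()].
#' @param deconv a [deconv_config()] used inside the loop.
#' @param psf a [psf_options()].
#' @param border border thickness cropped before scoring.
#' @param seed optional integer seed for a reproducible run.
#' @return List with `spec` (best [wavefront_spec()]), `psf` (its
#'   kernel) and `state` (an `anneal_state`: best/current cost, the
#'   per-iteration trace, iteration count).
#' @export
anneal <- function(patch, template, initial, config = anneal_config(),
                   deconv = deconv_config(), psf = psf_options(),
                   border = 10, seed = NULL) {
  stopifnot(inherits(initial, "wavefront_spec"))
  if (!is.null(seed)) set.seed(seed)
  patch <- as.matrix(patch)
  template <- as.matrix(template)
  interior <- function(m) {
    if (border > 0 && all(dim(m) == dim(patch)))
      m[(border + 1):(nrow(m) - border), (border + 1):(ncol(m) - border)]
    else m
  }
  tmpl_int <- interior(template)
  if (sd(tmpl_int) == 0) stop("degenerate template: constant image")
  basis <- zernike_basis(initial$noll_indices, psf$grid_size,
                         psf$aperture_radius_fraction)
  score <- function(coeffs) {
    kern <- psf_from_coefficients(basis, coeffs, psf$out_size)
    dec <- rl_deconv_cpp(patch, kern, deconv$iterations)
    dint <- if (border > 0)
      dec[(border + 1):(nrow(dec) - border), (border + 1):(ncol(dec) - border)]
    else dec
    if (sd(dint) == 0) return(100)  # constant output = failed deconvolution: worst cost
    -100 * ncc(dint, tmpl_int)
  }

  cur <- initial$coefficients
  q_cur <- score(cur)
  best <- cur; q_best <- q_cur
  n_iter <- anneal_iterations(config)
  temp <- config$t0
  trace <- matrix(NA_real_, n_iter, 4,
                  dimnames = list(NULL, c("iteration", "temperature",
                                          "cost", "best_cost")))
  for (it in seq_len(n_iter)) {
    cand <- perturb(cur, config$epsilon, initial$noll_indices,
                    config$defocus_constrained, config$lower, config$upper)
    q_cand <- score(cand)
    if (runif(1) <= accept_probability(q_cur, q_cand, temp)) {
      cur <- cand; q_cur <- q_cand
    }
    if (q_cand < q_best) { best <- cand; q_best <- q_cand }
    trace[it, ] <- c(it, temp, q_cur, q_best)
    temp <- temp * config$alpha
  }
  spec <- wavefront_spec(best, initial$noll_indices,
                         defocus_constrained = config$defocus_constrained)
  state <- structure(list(coefficients = cur, cost = q_cur,
                          best_coefficients = best, best_cost = q_best,
                          temperature = temp, iterations = n_iter,
                          trace = as.data.frame(trace)),
                     class = "anneal_state")
  list(spec = spec,
       psf = psf_from_spec(spec, psf$grid_size,
                           psf$aperture_radius_fraction, psf$out_size),
       state = state)
}

#' @export
print.anneal_state <- function(x, ...) {
  cat(sprintf("Annealing: %d iterations, best cost %.3f (NCC %.4f)\n",
              x$iterations, x$best_cost, -x$best_cost / 100))
  invisible(x)
}

#' Key-patch indices of the nine-point scheme
#'
#' Four corner patches, four central edge patches and one central patch.
#' On grids with an even row or column count the "central" index is the
#' lower of the two middle indices (`floor((n - 1) / 2)`, 0-based) — the
#' documented convention of this package.
#'
#' @param grid a [patch_grid()].
#' @return Data frame with 0-based `row` and `col` of the nine key
#'   patches (three distinct positions per axis).
#' @export
key_patch_indices <- function(grid) {
  rr <- c(0L, as.integer((grid$rows - 1) %/% 2), grid$rows - 1L)
  cc <- c(0L, as.integer((grid$cols - 1) %/% 2), grid$cols - 1L)
  out <- expand.grid(row = rr, col = cc)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Key-frame (band) selection for spectral sampling
#'
#' Picks the bands nearest to `seq(from, to, by)`; the defaults take
#' every 50 nm within 550-950 nm, i.e. 9 key frames on a 500-1000 nm,
#' 1 nm-sampled axis.  The band-edge regions are excluded from
#' estimation because their noise level makes patch optimization
#' meaningless; their PSFs come from spectral extrapolation of the
#' fitted field.
#'
#' @param wavelengths cube wavelength axis (nm).
#' @param from,to,by key-wavelength sequence (nm).
#' @return Integer vector of 1-based band indices (unique, increasing).
#' @export
key_frame_indices <- function(wavelengths, from = 550, to = 950, by = 50) {
  targets <- seq(from, to, by)
  idx <- vapply(targets, function(t) which.min(abs(wavelengths - t)),
                integer(1))
  sort(unique(idx))
}

#' Annealing at all key patches of all key frames, with warm starts
#'
#' The central patch of the first key frame starts from `initial`;
#' the remaining patches of that frame start from its solution; every
#' patch of a subsequent key frame starts from the solution of the same
#' patch in the previous (adjacent) key frame.  Warm starts keep
#' neighboring wavefronts in the same basin, which matters because
#' different wavefronts can produce identical PSFs.
#'
#' Annealing may run in stages: passing lists of [anneal_config()] /
#' [deconv_config()] objects (equal length) runs them in sequence per
#' patch, each stage starting from the previous stage's best solution.
#' A cheap broad stage (few deconvolution iterations) followed by a
#' short refinement stage at the full iteration count converges to the
#' deep optimum at a fraction of the cost of a single full-cost chain:
#' with few RL iterations the objective slightly favors
#' under-deconvolving kernels, a bias that vanishes as the scoring
#' deconvolution converges.
#'
#' @param cube a [hyper_cube()], spatially aligned with the template.
#' @param template ground-truth image, frame-sized matrix.
#' @param grid a [patch_grid()].
#' @param key_frames 1-based band indices (see [key_frame_indices()]).
#' @param initial starting [wavefront_spec()].
#' @inheritParams anneal
#' @param warm_config,warm_deconv optional configuration (single objects
#'   or stage lists) for patches that inherit a warm start from the
#'   adjacent key frame — every patch after the first key frame.  Warm
#'   starts land inside the right basin, so these runs only need a
#'   short refinement chain at a converged scoring deconvolution;
#'   `NULL` (default) reuses `config`/`deconv`.
#' @param seed integer seed; each (frame, patch, stage) run derives its
#'   own substream deterministically.
#' @param verbose print one line per optimized patch.
#' @return List with `knots` (coefficient table as in
#'   [write_coef_table()]), `traces`, and the configurations used.
#' @export
estimate_key_patches <- function(cube, template, grid, key_frames,
                                 initial = wavefront_spec(numeric(7)),
                                 config = anneal_config(),
                                 deconv = deconv_config(),
                                 warm_config = NULL, warm_deconv = NULL,
                                 psf = psf_options(), seed = 1,
                                 verbose = FALSE) {
  stopifnot(inherits(cube, "hyper_cube"))
  as_stages <- function(x, cls) if (inherits(x, cls)) list(x) else x
  configs <- as_stages(config, "anneal_config")
  deconvs <- as_stages(deconv, "deconv_config")
  if (length(configs) != length(deconvs))
    stop("config and deconv stage lists must have equal length")
  wconfigs <- if (is.null(warm_config)) configs
              else as_stages(warm_config, "anneal_config")
  wdeconvs <- if (is.null(warm_deconv)) deconvs
              else as_stages(warm_deconv, "deconv_config")
  if (length(wconfigs) != length(wdeconvs))
    stop("warm_config and warm_deconv stage lists must have equal length")
  template <- as.matrix(template)
  keys <- key_patch_indices(grid)
  # Key-patch windows are shifted inward at frame edges so they contain
  # only measured pixels: a window filled with reflected frame content
  # is inconsistent with a laterally shifting (tip/tilt) kernel and
  # poisons the estimate.  The knot is recorded at the window center.
  ext <- grid$patch + 2L * grid$border
  win <- lapply(seq_len(nrow(keys)), function(i) {
    r0 <- min(max(keys$row[i] * grid$patch - grid$border, 0),
              grid$height - ext)
    c0 <- min(max(keys$col[i] * grid$patch - grid$border, 0),
              grid$width - ext)
    list(rows = (r0 + 1):(r0 + ext), cols = (c0 + 1):(c0 + ext),
         y_px = r0 + (ext - 1) / 2, x_px = c0 + (ext - 1) / 2)
  })
  center_key <- which(keys$row == as.integer((grid$rows - 1) %/% 2) &
                      keys$col == as.integer((grid$cols - 1) %/% 2))
  # central patch first, then the rest of each frame
  order_keys <- c(center_key, setdiff(seq_len(nrow(keys)), center_key))

  knots <- NULL
  traces <- list()
  prev_frame <- NULL   # named list patch-id -> spec of previous key frame
  for (fi in seq_along(key_frames)) {
    f <- key_frames[fi]
    frame <- cube$data[, , f]
    this_frame <- list()
    center_spec <- NULL
    for (ki in order_keys) {
      pr <- keys$row[ki]; pc <- keys$col[ki]
      p_idx <- pr * grid$cols + pc + 1L
      w <- win[[ki]]
      warm <- !is.null(prev_frame) &&
        !is.null(prev_frame[[as.character(p_idx)]])
      init_k <- if (warm) prev_frame[[as.character(p_idx)]]
      else if (!is.null(center_spec)) center_spec
      else initial
      cfgs <- if (warm) wconfigs else configs
      dcvs <- if (warm) wdeconvs else deconvs
      fit <- NULL
      stage_traces <- list()
      for (sg in seq_along(cfgs)) {
        run_seed <- (seed * 10007L + f * 101L + p_idx * 7L + sg) %%
          .Machine$integer.max
        fit <- anneal(frame[w$rows, w$cols], template[w$rows, w$cols],
                      init_k, config = cfgs[[sg]], deconv = dcvs[[sg]],
                      psf = psf, border = grid$border, seed = run_seed)
        init_k <- fit$spec
        stage_traces[[sg]] <- cbind(stage = sg, fit$state$trace)
      }
      if (ki == center_key && is.null(center_spec)) center_spec <- fit$spec
      this_frame[[as.character(p_idx)]] <- fit$spec
      row <- data.frame(frame = f - 1L, wavelength_nm = cube$wavelengths[f],
                        patch_row = pr, patch_col = pc,
                        x_px = w$x_px, y_px = w$y_px)
      cf <- as.list(setNames(fit$spec$coefficients,
                             paste0("z", fit$spec$noll_indices)))
      knots <- rbind(knots, cbind(row, as.data.frame(cf)))
      traces[[sprintf("f%d_p%d", f - 1L, p_idx - 1L)]] <-
        do.call(rbind, stage_traces)
      if (verbose)
        message(sprintf("frame %d (%.0f nm) patch (%d,%d): NCC %.4f",
                        f - 1L, cube$wavelengths[f], pr, pc,
                        -fit$state$best_cost / 100))
    }
    prev_frame <- this_frame
  }
  list(knots = knots, traces = traces, config = config, deconv = deconv,
       psf = psf, noll_indices = initial$noll_indices)
}
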