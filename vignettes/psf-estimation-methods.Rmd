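---
title: "PSF estimation from computed wavefronts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSF estimation from computed wavefronts: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hyperspectral imaging (HSI) systems acquire hundreds of narrow spectral
bands over a wide wavelength range, and their optics cannot be corrected
equally well at every wavelength and field position.  The result is a
blur — a point spread function (PSF) — that varies both across the field
of view and along the spectral axis, typically accompanied by a
wavelength-dependent lateral shift of the image.  Deconvolution can
reverse much of this degradation, but it needs the PSF, and measuring
PSFs directly (by imaging sub-resolution point sources) fails exactly
where it is needed most: in bands where the sensor is noisy.

`wavepsf` estimates the PSF *computationally*.  It exploits the fact
that the blur of a conventional camera-type optic is well described by a
small number of low-order optical aberrations, so the search space of
plausible PSFs is tiny compared with a free-form kernel.  The estimate
is semi-blind: a spatially aligned, high-contrast ground-truth template
of the imaged target (classically a printed text page, which has edges
in every orientation) anchors the optimization.

## Model

### Wavefront, pupil, PSF

A wavefront error is expanded in Noll-indexed Zernike polynomials on the
unit disk,

$$W(\rho, \theta) = \sum_{n} c_n Z_n(\rho, \theta),$$

with the default mode set Noll 2–8: tip, tilt, defocus, oblique and
vertical primary astigmatism, and vertical and horizontal coma.  These
seven modes dominate camera optics; higher orders add little for this
class of system.  The polynomials are Noll-normalized (unit variance
over the disk), and coefficients are *radians of optical phase at the
pupil*.  The convention matters: the pupil function

$$P = A\,e^{-iW}$$

then needs no extra scale factor ($A$ is a binary circular aperture
mask).  Nothing in the chain pins the physical unit — only the phase
$W$ enters — so a configuration switch (`unit = "waves"` in
`wavefront_spec()`) reinterprets inputs in waves by multiplying by
$2\pi$.

The incoherent PSF is the squared modulus of the Fourier transform of
the pupil:

$$\mathrm{PSF}(u, v) = \left|\mathcal{F}\{P\}\right|^2 .$$

Numerically, the aperture is embedded in a grid twice its diameter
(`aperture_radius_fraction = 0.5`), which yields a Nyquist-sampled PSF;
the intensity is centered, cropped to a small odd-sized kernel
(default 21 px, comparable to the 10-px deconvolution border) and
normalized to unit sum.  Tip and tilt deliberately shift the kernel's
centroid off-center: that is how the model absorbs the instrument's
wavelength-dependent lateral shift, so the deconvolution also
co-registers the bands.

### The objective

A candidate PSF is scored by deconvolving the observed patch with it
(Richardson–Lucy) and correlating the result with the template patch
using the normalized cross-correlation (NCC).  Internally the optimizer
minimizes $-100 \times \mathrm{NCC}$, a cost-like scale on which the
annealing acceptance rule $\exp((Q - Q')/T)$ reads naturally.

### Simulated annealing

Coefficients are perturbed jointly, each drawn uniformly from
$[c_i - \varepsilon,\ c_i + \varepsilon]$ with a constant perturbation
factor $\varepsilon$.  A better candidate is always accepted; a worse
one with probability $\exp((Q - Q')/T)$.  The temperature cools
geometrically ($T \leftarrow \alpha T$) each iteration until it reaches
`t_end`, so the run length is
$\lceil \ln(T_\mathrm{end}/T_0)/\ln\alpha \rceil$ — 919 iterations at
the defaults ($T_0 = 10$, $\alpha = 0.995$, $T_\mathrm{end} = 0.1$,
$\varepsilon = 0.05$ rad).  All four knobs are exposed; in practice we
found schedules starting near $T_0 \approx 1$ spend less of the budget
in undirected random walk (typical cost differences between neighboring
candidates are of order 1 on the $-100\times$NCC scale) and converge
tighter in the same wall time.

Two safeguards address the wavefront–PSF ambiguity (different
wavefronts can produce identical PSFs, e.g. sign-flipped defocus with
sign-flipped even companions):

* **Defocus sign constraint.**  The defocus coefficient is clamped to
  non-positive values at the perturbation step (on by default).
  Without it, neighboring patches can converge to opposite-sign
  wavefronts whose *interpolation* is meaningless even though each
  endpoint PSF is fine.
* **Warm starts.**  The central patch of the first key frame starts
  from a user-supplied or automatically derived initial; the remaining
  patches of that frame start from its solution; patches of each
  subsequent key frame start from the same patch of the adjacent,
  already-solved frame.  This keeps neighboring solutions in the same
  basin.

`coarse_initial()` automates what an operator would otherwise do by
eye before optimization: it scans a one-dimensional grid of pure
defocus values (default $0$ to $-3$ rad in steps of $0.25$), scores
each by deconvolution NCC, and returns the winner as the starting
solution.  Defocus dominates the blur budget, and starting in the right
defocus basin removes the main multi-modality we observed: without the
scan, roughly one run in four converged to a visibly shallower defocus
with a PSF correlation several points lower.

Two further properties of the objective shaped the pipeline defaults:

* **Under-deconvolution bias at few scoring iterations.**  When the
  Richardson–Lucy deconvolution inside the scoring loop is truncated
  early (a few dozen iterations), kernels slightly weaker than the
  truth can out-score it — the truncated restoration of the true
  kernel still looks blurred, while a weak kernel's restoration
  plateaus quickly.  The bias vanishes as the scoring deconvolution
  converges.  `estimate_key_patches()` therefore supports *staged*
  annealing: a cheap broad chain at 24 scoring iterations to find the
  basin, then a short refinement chain scored at 96+ iterations.
  Patches that inherit a warm start from an adjacent key frame skip
  the broad stage entirely.
* **Frame-edge windows.**  Key-patch windows at the frame boundary are
  shifted inward so they contain only measured pixels, and the knot is
  recorded at the window center.  Extending them with reflected frame
  content — as the deconvolution tiling legitimately does — poisons
  estimation, because reflection mirrors the lateral shift direction:
  reflect(blur(x)) and blur(reflect(x)) disagree under a tip/tilt
  kernel, and the optimizer resolves the contradiction by discarding
  the shift.  On the worst synthetic corner patch this single change
  moved the recovered-PSF correlation from 0.65 to 0.97.

### Key patches and interpolation

PSF estimation runs only at *key* locations: nine key patches per key
frame (four corners, four central edge patches, one central patch; on
grids with an even number of rows or columns the "central" index is
`floor((n-1)/2)`, 0-based) and one key frame every 50 nm within
550–950 nm by default (9 key frames on a 500–1000 nm axis).  On the
full instrument geometry that is 81 optimizations out of 24,048
patches; every other PSF comes from interpolation.

Each Zernike coefficient is then fitted with a polynomial in
(window-center $x$, window-center $y$, wavelength): per-axis orders of
`min(3, distinct positions - 1)` — with the nine-point scheme there are
only three distinct positions per spatial axis, so the spatial order is
honestly 2 — combined with a cap on the *total* degree at 3, i.e. a
joint third-order polynomial rather than a full tensor product.  The
cap matters statistically: the tensor basis has 36 terms, which against
45–81 knots is nearly interpolatory, so every knot error transfers to
the field and is amplified between knots; the 18-term joint cubic
leaves real residual degrees of freedom.  For the same reason the fit
is robust by default (Huber IRLS): an individual annealed knot can fail
outright — typically at noisy band edges — and a plain least-squares
fit lets one such knot bend the entire surface.  Coordinates are
centered and scaled to $[-1, 1]$ before fitting for conditioning; a
rank-deficient system triggers an automatic order reduction with a
warning.  At evaluation time spatial coordinates are clamped to the
knot hull (frame-edge key windows sit at most half a patch inside the
outer patch centers; the coefficient gradient over those few pixels is
negligible, while polynomial extrapolation error is not).  Because the
wavefront is linear in its coefficients, interpolating coefficients is
*exactly* equivalent to interpolating wavefronts.  Interpolated defocus
is clamped at zero so the sign convention survives round-off at the
constraint boundary.

Frames outside the key-frame range (the noisy band edges, e.g.
500–549 nm) receive spectrally extrapolated coefficients by default;
clamping to the nearest key wavelength is available
(`extrapolate = "clamp"`), and every evaluation outside the fitted
range can be silenced, warned about, or made an error.

### Deconvolution

Each frame is tiled into square patches (80 px on the instrument
geometry; frame dimensions must divide evenly — anything else is
rejected rather than silently truncated), every patch is extended by a
10-px border, deconvolved with its own PSF, cropped back, and the crops
reassembled.  The crops partition the frame exactly, so the only
blending mechanism is the border overlap — which is also what absorbs
tip/tilt-induced shifts at patch edges.

Richardson–Lucy is the default algorithm (128 iterations by default; the
iteration count is the resolution-vs-noise knob).  The update runs in
the frequency domain on a reflect-padded support, which makes the
circular convolutions behave as linear convolutions over the patch;
reflection was chosen over zero-padding because it minimizes ringing on
text-like content.  The iterate starts from the observed patch rather
than a flat image — convergence is faster and, at 128 iterations, the
result was indistinguishable on every scene we tested.  A Wiener filter
(`wiener()`) is provided for parity; it produced equivalent PSF
estimates and is not the default.

## The synthetic validation instrument

Real validation data (a push-broom HSI acquisition plus a fiber-array
PSF measurement) cannot ship with a package, so `wavepsf` includes a
forward model that emulates one:

* **Template:** procedural glyph-like strokes — oriented bars every
  22.5°, rings, seeded random rectangles — dark on light, contrast
  spanning ≥ 80 % of the dynamic range, strong edges in all eight
  orientation octants.  (Rendered text would add nothing: only the
  edge-orientation property matters.)
* **True coefficient field:** smooth low-order polynomial surfaces per
  Zernike mode; defocus everywhere negative, growing toward band edges
  and field corners; a wavelength-linear tip/tilt ramp reproducing the
  push-broom lateral shift (≈ ±1.3 px over the range at the default
  `tip_ramp = 1` rad).
* **Noise:** additive Gaussian on reflectance, $\sigma$ rising
  quadratically from 0.002 mid-band to 0.05 at the spectral-range
  edges — the regime in which real edge bands are too noisy to use.
* **Geometry:** the default `"small"` preset is a scaled-down
  instrument — 160 × 120 frames, 40-px patches (4 × 3 grid), 41 bands
  over 550–950 nm at 10 nm — chosen so the full
  estimate → interpolate → deconvolve loop runs in minutes on one CPU;
  the `"instrument"` preset reproduces the full 640 × 480 × 501
  geometry.
* **Point sources:** `point_source_cube()` places one sub-pixel source
  at each patch center (48 sources in 6 × 8 instrument geometry),
  blurred by the same true field — the simulated analogue of a
  fiber-based PSF measurement array, used to verify that deconvolution
  shrinks the wavelength-dependent centroid drift.

What the generator does *not* emulate: spectral smile/keystone,
radiometric calibration error, push-broom temporal artifacts,
spatially correlated noise, and any blur not expressible by Noll 2–8.
Passing the package's tests therefore demonstrates that the estimation
machinery recovers what its own model class can represent under
realistic noise — not that seven Zernike modes suffice for any
particular real instrument.

## Numerical choices

* Pupil grid 256 for presentation-quality kernels; 64 inside the
  annealer (enough angular resolution for a 21-px kernel at a fraction
  of the FFT cost).  Both configurable via `psf_options()`.
* `rho = 0` evaluates radial polynomials by their (finite) limit.
* PSF kernels must be odd-sized so a center pixel exists; even
  requests are errors, not silent crops.
* A constant (zero-variance) image makes the NCC undefined; `ncc()`
  raises an error rather than returning 0, because a constant
  deconvolved patch signals a failed deconvolution, not a neutral
  score.  Inside the annealer a constant candidate output is scored as
  the worst possible cost (+100) instead of aborting the run.
* RL divisions are guarded at $10^{-12}$; updates clamp at zero.
* Coefficient fields serialize with C99 hex doubles so a round trip
  through JSON restores evaluation bit-exactly.
* Determinism: every stochastic stage consumes R's RNG; `anneal()`
  takes an explicit seed, and `estimate_key_patches()` derives one
  seed per (frame, patch) from the top-level seed, so runs are exactly
  reproducible and independent of patch execution order.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full pipeline on the
`"small"` preset: 9 key frames (every 50 nm in 550–950 nm) × 9 key
patches = 81 annealed knots.  First-key-frame patches run two stages
(broad: $T_0 = 1$, $\alpha = 0.985$, $\varepsilon = 0.08$ rad at 24
scoring iterations; refine: $T_0 = 0.3$, $\alpha = 0.96$,
$\varepsilon = 0.05$ at the converged scoring count), warm-started
patches run the refinement stage only; whole-cube deconvolution uses
64 RL iterations.  The single-patch recovery experiment uses a single
dense chain ($\alpha = 0.996$, 48-iteration scoring) after the defocus
scan.  These sizes were chosen as the smallest at which the scientific
claims are meaningfully exercised — key-patch recovery, smooth
interpolation, resolution gain, shift correction — while keeping a
complete run in the minutes range on one core.

## Known limitations

* The recovered wavefront is *a* wavefront producing the right PSF,
  not necessarily the instrument's true aberration map; only the PSF
  (and quantities derived from it) should be interpreted.
* Two-dimensional PSFs correct spatial blur only; aberrations along
  the spectral direction are out of scope.
* The template must be pre-aligned with the acquisition; registration
  is not part of this package.
* Deconvolution trades noise amplification for resolution; the RL
  iteration count must be tuned per application.
* Non-circular pupils and deformable-mirror parameterizations are not
  supported.
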