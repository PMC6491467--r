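---
title: "Decoding color and depth from unmodified single-molecule PSFs"
author: "smlmpsf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding color and depth from unmodified single-molecule PSFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In single-molecule localization microscopy (SMLM) each camera frame holds a
sparse set of diffraction-limited spots, one per photoswitched fluorophore.
The classical output is the lateral (x, y) position of each spot, but the
spot image — the point spread function (PSF) — carries more: its overall
scale grows with the emission wavelength, and its detailed ring structure
and asymmetry encode the axial (z) position of the emitter through defocus
and index-mismatch aberration. `smlmpsf` implements an end-to-end framework
that extracts both quantities from *unmodified* PSFs — no astigmatic lens,
no phase mask, no channel splitting:

1. a physical PSF simulator (stratified-medium scalar diffraction with
   Poisson shot noise) that provides labeled training and benchmark data;
2. a tricubic-spline PSF model with Poisson maximum-likelihood fitting
   (MLE) and Cramér–Rao lower bounds (CRLB), the parametric baseline;
3. small fully-connected neural networks: a Softmax color classifier with
   confidence-based rejection, and per-dye scalar regressors for z (and
   optionally for sub-pixel x/y);
4. the shared preprocessing path (detection, 2D Gaussian refinement,
   quality filters, 13×13 crops, zero-mean/unit-norm normalization) and a
   pipeline that merges color and z calls into one localization table.

## The optical model

The simulator evaluates the scalar Gibson–Lanni diffraction integral over
the normalized pupil radius $\rho$:

$$U(r,z) = \int_0^{\rho_{\max}} J_0(k\, r\, \mathrm{NA}\, \rho)\,
          e^{i k\, \mathrm{OPD}(\rho, z)}\, \rho \, d\rho,
\qquad I = |U|^2,$$

with $k = 2\pi/\lambda$ and an optical path difference for an emitter at
depth $d_0 + z$ in a medium of index $n_s$ behind immersion of index
$n_i$:

$$\mathrm{OPD}(\rho, z) = (d_0 + z)\sqrt{n_s^2 - \mathrm{NA}^2\rho^2}
  \;-\; d_0\,\frac{n_i}{n_s}\sqrt{n_i^2 - \mathrm{NA}^2\rho^2}.$$

Three geometry choices deserve explanation because the design space was
genuinely open:

* **Particle-scan geometry.** The axial coordinate moves the *emitter*
  while the focal plane stays fixed, which is the situation in SMLM of
  cells: molecules sit at different heights, the objective does not move.
  The defocus term therefore uses the sample-medium root
  $\sqrt{n_s^2-\mathrm{NA}^2\rho^2}$, and axial position and aberration are
  physically coupled. This coupling is precisely the source of the
  z-asymmetry and the color-vs-defocus disentangling that the decoders
  exploit; a fixed-depth focal-scan geometry makes the two emission colors
  nearly interconvertible at moderate defocus and would misrepresent the
  measurement.
* **z = 0 is best focus.** With index mismatch the plane of maximal
  on-axis intensity sits a couple of hundred nanometres from the paraxial
  focus. An experimenter focuses by maximizing sharpness, so the stack
  generator locates the best-focus plane numerically
  (`find_best_focus()`) and labels its axial axis relative to it. z > 0
  means the emitter is farther from the coverslip than the focal plane,
  consistently in simulation, training labels and inference output.
* **Pupil truncation.** For NA $> n_s$ the sample-medium root is imaginary
  beyond the critical angle $\rho = n_s/\mathrm{NA}$; those supercritical
  (evanescent) components are excluded, matching the stated non-goal of
  supercritical-angle fluorescence modeling. With matched indices the
  model reduces exactly to the Airy integral, which anchors the
  simulator-physics tests.

The pupil integral is evaluated by Gauss–Legendre quadrature whose node
count doubles until two successive evaluations agree to $10^{-6}$
(relative to the profile maximum), with a hard failure — not a silent
degradation — if the cap is reached.

### Simulation conditions

Defaults mirror the reference operating conditions throughout: NA 1.45,
immersion index 1.51, sample index 1.33, working distance 130 µm, nominal
particle depth 1 µm; two emission wavelengths 600 nm ("yellow") and 700 nm
("red"); stacks over ±600 nm in 20 nm steps at 5 nm lateral resolution,
area-binned onto a 100 nm detector grid; photon counts normalized so the
24×24-pixel region-of-interest sum equals the requested signal, plus a
uniform background of 10 photons/pixel; per-pixel Poisson shot noise. The
operating points 2000/5000/10000/15000 photons span the benchmark
regimes. Sub-pixel lateral offsets are applied by shifting the
5-nm-resolution field before binning, so pixelation jitter is genuine
rather than interpolated; offsets default to uniform within ±half a pixel
for training sets (a flag disables them).

What the simulator does **not** emulate: EM-CCD excess noise and camera
gain/offset, sCMOS pixel-dependent noise, supercritical-angle
fluorescence, vectorial/polarization effects, field-dependent PSFs, and
sample drift. Passing benchmarks on simulated data therefore demonstrate
the correctness of the estimators and the information content of the
scalar model, not performance on any particular camera.

## The spline model, MLE and CRLB

The reference stack (per-slice normalized to unit sum, so the photon
parameter means "photons inside the stack window" at every z) is converted
to per-cell tricubic polynomials by three separable natural-cubic-spline
passes. This representation interpolates the stack exactly at the knots,
is C² across cells, and exposes analytic derivatives — the ingredients the
Poisson machinery needs:

* expected image $\mu_k(\theta) = N\,S_k(x,y,z) + b$ for
  $\theta = (x, y, z, N, b)$;
* likelihood error $L(\theta) = \sum_k \mu_k - n_k \log \mu_k$ (the
  negative Poisson log-likelihood with the $\log n_k!$ term dropped; the
  dropped term is constant in $\theta$ and cancels in every comparison
  made);
* Fisher information
  $I_{ij} = \sum_k \partial_i\mu_k\, \partial_j\mu_k / \mu_k$ and CRLB
  $\sqrt{(I^{-1})_{ii}}$.

Numerical choices: natural boundary conditions with the outermost knot
shell excluded from the fit domain (no extrapolation); spline values below
$10^{-6}$ are clamped, with zero spatial gradient, before entering the
likelihood so that $\log\mu$ stays finite in empty corners; parameters are
clamped to the model domain every iteration.

The optimizer is a damped (Levenberg-style) Newton iteration on the
Fisher-scoring Hessian with analytic gradients; steps are accepted only if
they do not increase $L$. Unmodified PSFs have a rugged likelihood in z —
shallow "shoulder" minima flank the global basin — so after Newton
convergence the fitter profiles $L$ over a coarse 40 nm z grid at the
current estimate and restarts Newton from any strictly lower basin (at
most three rounds). Monotone descent is preserved. The two-round dual-initialization scheme sits on top of this: `fit_z_dual_init()` runs the fit from
z = +300 nm and −300 nm (x, y from the intensity-weighted centroid,
background from the 20th-percentile pixel, photons from the
background-subtracted sum) and returns the branch with the lower
likelihood error; ties prefer the +z branch. Color classification by MLE
fits each candidate dye's spline model with the dual-z scheme — four MLE
rounds for two colors — and picks the color minimizing the likelihood
error, lower index on ties.

For efficiency measurements the Poisson replicates are drawn from the
spline model's own expected image, the design for which the CRLB is the
exact benchmark; simulator-rendered images (5 nm lateral quantization,
linear z interpolation between slices) are used for the calibration-slope
and classification benchmarks, where the small model mismatch is part of
what is being measured. The suite checks the empirical standard deviation
against the CRLB with an explicit Monte-Carlo allowance of three standard
errors of the sd estimate on the lower side ($\approx 1 - 3/\sqrt{2(n-1)}$
for n replicates), and against twice the CRLB on the upper side.

## The networks

Both decoders share one architecture: the flattened, zero-mean,
unit-Euclidean-norm 13×13 patch feeds four fully-connected
rectified-linear hidden layers. The reference architecture is
4096-4096-2048-1024 neurons (the `network_spec()` default); the package's
benchmark configuration scales this down to 1024-1024-512-256 for the
color classifier — the narrower 256-256-128-64 net converges about two
accuracy points short of the likelihood ceiling on this task, with
noticeable seed-to-seed wobble, while the 1024-wide net closes most of
that gap and still trains in minutes on one CPU — and to 256-256-128-64
for the axial regressors, where the narrow net already reaches
within ~1.3× of the CRLB and wider ones gave no measurable gain.

* **Color classifier.** Softmax head over the dye classes, cross-entropy
  loss, dropout 0.5 before the final layer, no weight penalty; Adam at
  initial rate 10⁻⁴, batch 64. Training sets are balanced by stratified
  subsampling. The Softmax output is the class posterior; the decision is
  maximum-a-posteriori, and the confidence is
  $\Delta = P(\text{dye 1}) - P(\text{dye 2})$ in the binary case (top
  minus runner-up for more classes, which reduces to the same thing at
  M = 2). Molecules with $|\Delta|$ below a user threshold $\delta$ are
  rejected rather than assigned; $\delta \in \{0, 0.4, 0.8\}$ are the
  standard operating points.
* **Axial (and lateral) regressors.** One network per dye, scalar head.
  The batch loss is the L2 *norm* of the residual vector, and the L2 norms
  of the per-layer weight matrices enter the loss with factor 0.01 —
  implemented literally in that form. This reading matters: with the
  conventional mean-square/squared-penalty interpretation the same factor
  suppresses the network far below the information limit, while the
  literal norms yield precision close to the CRLB, which is the documented
  behaviour of the method. Adam at initial rate 10⁻³, batch 32. Labels are
  standardized internally and predictions returned in nm.

Shared training mechanics: Xavier-uniform initialization, seed-exact
reproducibility (one seed governs shuffling, dropout masks and
initialization), learning-rate decay by a factor 0.2 (a "roughly 5×" step-down fixed to one exact value) every 1000 iterations, at
most 10 epochs with early stop after 3 epochs without validation
improvement, best-epoch weights restored. Training photon counts default
to the 4500–5500 band so the noise level is consistent across classes and
z — the condition the training procedure requires — and inference is deterministic
(dropout disabled).

Study sizes for the benchmarks, chosen once: 10000 molecules per color for
the classifier with 1000/class
validation; 6000 for each axial regressor over ±580 nm labels; classification evaluated over z uniform on ±400 nm at
5000 and 2000 photons, 400 molecules per color per level.

## Pipeline and evaluation

`run_inference_pipeline()` applies a photon threshold (exposed, not fixed:
3000 is the cell-analysis value, 4000 the bead-analysis one), calls color
at threshold $\delta$, routes accepted molecules to the axial network of
their called color, and merges everything into one localization table
(frame, x, y, z, color, photons, confidence, method). Every input molecule
ends in exactly one place — the table or the reject log with a reason code
— and the suite asserts this conservation plus routing consistency.
`evaluate_classification()` reports accuracy among accepted molecules and
rejection rate per threshold, stratified by photon and true-z bins (empty
strata are NA, not zero); `evaluate_axial()` reports per-z bias and spread
with an optional CRLB overlay. `run_full_benchmark()` chains the whole
study from one seed and emits a JSON report; two runs with the same seed
are byte-identical.

## Known limitations

* The simulator's realism bounds what the benchmarks can claim; see the
  exclusion list above. In particular real EM-CCD excess noise roughly
  halves the effective photon count, so real-data accuracy at a nominal
  photon level will sit below the simulated curve at the same level.
* The spline model and the renderer differ slightly by construction
  (cubic vs linear z interpolation, 5 nm offset quantization); this is a
  deliberate model-mismatch of realistic size, visible as a few-percent
  excess of empirical spread over the CRLB in the simulator-rendered
  benchmarks.
* The 2D detector is a declared stand-in validated on simulation; real
  SMLM stacks bring detection challenges (overlap, drift, hot pixels)
  that are out of scope here.
* Axial training data in practice comes from coverslip-attached emitters
  whose PSFs differ from molecules inside cells (depth-dependent
  aberration); the package supports retraining on user stacks but ships
  no real data.
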