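---
title: "Deep-learning adaptive optics for SMLM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning adaptive optics for SMLM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-molecule localization microscopy (SMLM) reconstructs
super-resolved images by localizing stochastically blinking fluorophores.
Imaging deep into tissue, refractive-index inhomogeneities distort the
wavefront collected by the objective; the distorted point spread function
(PSF) degrades both the localization precision and the fidelity of the
reconstruction. Classical sensorless adaptive optics (AO) corrects such
distortions by trial-and-evaluate sweeps of deformable-mirror modes
against an image-quality metric, which is slow and unstable on volumetric
blinking data. The alternative implemented here infers the shared
wavefront distortion *directly* from the sparse single-molecule emission
patterns themselves: a convolutional network regresses mirror-mode
amplitudes from each detected subregion, a Kalman filter fuses the
per-cycle estimates, and the negated posterior drives the mirror. This
package is a fully simulated, closed-loop testbed for that feedback
architecture, including its two baselines (Gerchberg–Saxton phase
retrieval from bead z-stacks, metric-based AO) and its evaluation
machinery (W~rms~, 3D normalized cross-correlation, Poisson Fisher
information / Cramér–Rao bounds).

Everything is desk-scale: the defaults are chosen so that the entire
study — training three networks and running 165 closed loops — fits in
tens of minutes on one CPU core, while keeping the acquisition statistics
of the simulated characterization protocol intact.

## Optical forward model

The PSF model is scalar diffraction through the pupil: the camera image
of an emitter is `|FT{A(k) exp(i phi(k))}|^2`, with the pupil magnitude
`A` a flat disk of radius `NA/lambda` and the phase `phi` the sum of

* the instrument pupil phase (flat by default),
* the shared aberration (a linear combination of basis modes),
* an angular-spectrum defocus term
  `2*pi*z*sqrt((n_imm/lambda)^2 - |k|^2)` for the emitter's axial
  position plus the detection-plane offset, and
* a linear tilt encoding the lateral position.

Defaults: wavelength 690 nm (far-red emission inside a 731/137 band-pass),
NA 1.35 silicone-oil objective with `n_imm = 1.406`, water-based sample
medium `n_sample = 1.35`, camera pixel 119 nm. Images are rendered on a
64-pixel pupil/Fourier grid and cropped to 32 pixels; the grid spacing
ties the Fourier sampling to the camera pixel, so a plain FFT yields the
camera-plane PSF. Photons split 50/50 between two detection planes offset
by ±300 nm (biplane detection; the offset is a configurable surrogate, as
is the wavelength — neither is dictated by the simulated protocol).
Energy accounting is exact on the full Fourier grid before cropping.
Piston is invisible by construction; the scalar model ignores
polarization and dipole-orientation effects, which matter quantitatively
at NA 1.35 but not for the closed-loop questions studied here.

Depth-induced index-mismatch aberration is available in closed form,
`2*pi*depth*(kz_sample - kz_immersion)` with the evanescent region
clamped to zero. At NA equal to `n_sample` this phase has an unbounded
radial slope at the very pupil edge; analyses that render it (the Fisher
comparison) first remove piston and the best-fit defocus — re-focusing,
as the stage does in practice — and use a 128-pixel pupil grid so that
the remaining phase is sampled adequately except in a sub-pixel annulus
at the edge.

## Wavefront bases

Zernike circle polynomials in Wyant (fringe) order are sampled on the
discrete pupil support, orthonormalized by modified Gram–Schmidt under
the support-mean inner product, and scaled to unit W~rms~ — so one
coefficient unit is exactly one radian of RMS wavefront error, and the
Euclidean norm of a coefficient vector equals the W~rms~ of the composed
wavefront on an orthonormal basis. W~rms~ itself is the plain RMS of the
pupil phase over the support; no piston or tilt removal is applied to a
phase handed to `wrms()`.

Physical mirror deformation modes are instrument-specific and not
publicly available, so `build_mirror_basis()` constructs a documented
synthetic surrogate: Zernike modes mixed by a seeded near-identity
matrix (off-diagonal entries uniform, scaled by
`coupling_strength/sqrt(n_modes - 1)`), renormalized to unit W~rms~.
With the default `coupling_strength = 0.1` each synthetic mirror mode
keeps at least 90% of its norm on its parent Zernike, mimicking the
experimentally observed cross-coupling of mirror modes without
reproducing any particular mirror.

The desk-scale basis uses six modes — both astigmatisms, both comas,
primary spherical and one trefoil (Wyant indices 4–9). Tip, tilt and
defocus are excluded deliberately: they are degenerate with the unknown
lateral and axial position of each emitter, so a single-molecule
estimator cannot (and need not) sense them. The full 28-mode basis used
by the physical system is available through the same constructors and
the network width is configurable to 28 outputs, but the tested,
documented configuration is the 6-mode one.

## Synthetic blinking acquisition

`simulate_frames()` reproduces the simulated characterization protocol:
128 × 128-pixel biplane frames, emitter count per frame Poisson with mean
13, lateral positions uniform over the field, axial positions uniform in
±1 µm, photon counts exponential with mean 2,500, and 10 background
photons per pixel, all behind Poisson shot noise. What the generator
deliberately does *not* model: fluorophore photophysics (on/off kinetics,
bleaching), sCMOS read-noise maps, drift, structured background, and
channel-registration error between the two planes. Tests passing on this
generator therefore demonstrate the control architecture under ideal
camera statistics, not robustness to those real-data effects.

Acquisition-side processing mirrors the real pipeline: a temporal median
over the cycle's frames estimates the per-pixel background; detection
runs on the background-subtracted sum of both planes after Gaussian
smoothing (sigma 2 px — wide enough that a 2,500-photon emitter at
|z| = 1 µm still stands ~7 sigma above the smoothed shot noise, chosen
to meet a ≥90% recall / ≤0.01 false-positives-per-frame budget);
candidates closer than 16 px to another detection are discarded, as are
border-clipped crops and subregions whose summed background-subtracted
photons fall below the 1,500-photon intensity threshold. The exact
segmentation recipe of the physical system is not public; this
smoothed-local-maximum detector is a standard surrogate and all its
parameters live in `acquisition_config()`.

## The estimator

Training pairs are generated by the forward model itself: a coefficient
direction uniform on the mode sphere, a total W~rms~ uniform in the
network's amplitude range, an emitter with uniform z (±1 µm), uniform
photons (1,500–8,000 — the segmentation-surviving range), uniform
background (5–20/px) and a sub-pixel lateral offset, rendered, Poisson
noised and background-subtracted. Each noisy crop is then *recentered on
the smoothed peak of the summed planes*, exactly as the subregion
segmentation centers its crops: a heavily aberrated emission pattern
peaks several pixels away from its emitter, and training on
emitter-centered crops while inferring on peak-centered ones costs a
large shrinkage bias at high amplitudes (measured during development:
segmentation centers sit a median of ~4 px from the emitter at 2.5 rad,
versus ~1.5 px when nearly unaberrated). For the same reason each
training window also receives a Poisson number (mean 3.2) of
*contaminant emitters*: at the default acquisition density a real
subregion's 64-px neighbourhood contains about three other emitters, and
their light is a large fraction of many accepted crops (median ~10% of
the crop photons, with a heavy tail). Bright contaminants are kept
outside the isolation radius — a detected close pair would have been
discarded — while dim ones may fall anywhere. Training on pristine
single-emitter crops while inferring on contaminated ones was the
dominant term in the estimator's error floor. Each crop is normalized by
its
total photon count, and that normalization is applied identically at
inference — the one invariant that must match bit-wise between training
and use.

The network is a compact residual CNN: stride-2 convolutions
(2→8→16→32→48 channels) with batch normalization and PReLU activations,
residual blocks at the 8×8 and 4×4 resolutions, a valid convolution
"fully connecting" to 1×1 spatial size and a 1×1 convolution emitting
the coefficient vector (~63k parameters for 6 modes). It is trained with
Adam on per-mode mean-squared error, equal weights; both the weight
initialization and the batch shuffling are seeded, and the whole
forward/backward engine is single-threaded compiled code, so training is
bit-reproducible. An inference call averages the per-subregion outputs
and reports the across-subregion standard error as the measurement
uncertainty — the definition of "inference uncertainty" chosen here,
since model ensembles or dedicated uncertainty heads would multiply the
training budget.

Three networks are trained on nested amplitude ranges (0–0.8, 0–1.8 and
0–3.4 rad total W~rms~; the largest range extends past the highest
studied level, 2.75 rad, so that the top levels do not sit on the
training boundary where mean-squared-error regression shrinks hardest).
Training is a curriculum: the largest-range member trains from scratch
on 24k samples, and each smaller member is fine-tuned from the
next-larger one on 12k range-restricted samples — cheaper and more
accurate than training each from scratch. The loop starts on the largest
range; within every cycle, after the first inference it re-selects the
smallest-range member whose range contains the estimate magnitude plus
twice its uncertainty (boundary ties go to the smaller range) and
re-infers the same subregions with it, so even the very first mirror
update of a mildly distorted system benefits from a precise small-range
network. It moves back up when the current range is exceeded.

## The controller

Per mirror mode, an independent scalar Kalman filter tracks the residual
distortion: predict (mean shifted by the commanded mirror delta,
variance inflated by a process noise of (0.05 rad)² absorbing mirror
nonlinearity), then update with the measurement variance `stderr²`
(floored at (0.02 rad)²). The applied correction is the negated
posterior times a gain of 1.0; the loop stops after 20 updates or once
the measured residual magnitude stays below 0.1 rad for two consecutive
cycles. After an early stop the mirror is frozen, so the residual "after
19 updates" equals the residual at the stop — convergence summaries
carry the last value forward.

The simulated mirror applies a per-mode saturating stroke nonlinearity,
`realized = stroke * tanh(commanded/stroke)` with stroke 4 rad — a
surrogate for the nonlinear deformation response that motivates the
multi-update behaviour — plus an optional commanded-to-realized coupling
matrix and seeded actuation noise.

Changing the amplitude of the spherical mode shifts the apparent focal
plane. The slope was measured in this model by locating the through-focus
peak of bead stacks rendered at ±1 and ±0.5 rad of the spherical mode:
+0.106 µm per unit amplitude. The stage compensation therefore uses
−0.106 µm per unit spherical delta in the desk preset (the physical
system quotes −0.3 and −0.2 µm for its two spherical-like mirror modes;
the sign convention is "stage offset that recenters the emitters").

## Baselines

*Phase retrieval.* Gerchberg–Saxton alternation over a 31-slice bead
stack (−1.5 to 1.5 µm, 100 nm steps), rendered on the full 64-px Fourier
window — at 1.5 µm defocus the PSF wings extend far beyond a 32-px crop,
and truncating them corrupts the image-space constraint: image-space
magnitudes are replaced
by the measured square-root intensities per z, the pupil-space constraint
resets the magnitude to the flat disk (known apodization) and keeps only
the phase, with the mean phase (piston) zeroed each iteration. 100
iterations by default; the per-iteration intensity residual is logged and
the best iterate is returned with a warning if convergence is
non-monotone. Mirror modes are "measured" as in the physical protocol:
phase retrieval at ±1 commanded unit, half the difference — cancelling
static baseline aberrations by construction.

*Metric-based AO.* For each mode, 11 amplitudes spanning ±1 rad around
the current correction are applied; each image's sub-pixel symmetry
center is found by the radial-symmetry method, a Gaussian mask (sigma
6 px by default) is placed there, and the masked sum is the metric; a
least-squares parabola through the 11 samples gives the optimum (clamped
to the sweep, falling back to the sampled argmax with a warning when the
fit has no maximum). Optima are applied immediately within a pass and the
full sweep repeats 5 times: 28 × 11 × 5 = 1,540 evaluations for the full
basis. The sweep span and mask width are not specified by the original
protocol. The mask width matters more than it looks: with a tight (2 px)
mask the metric is so sharply peaked over a ±1 rad sweep that the
full-sweep parabola puts its vertex far beyond the true optimum; at
sigma 6 the metric-versus-amplitude curve is approximately quadratic
over the sweep and a single pass lands within 0.1 rad of a 0.8-rad
single-mode optimum. The mask is re-centered on every image.

## Evaluation

3D NCC is the Pearson correlation over all stack voxels. Fisher
information uses the Poisson model `I = sum (dmu/dtheta_i)(dmu/dtheta_j)
/ mu` with central differences (5 nm lateral, 10 nm axial), pixels with
expected counts below 1e-6 excluded, summed over both detection planes;
CRLB precision is `sqrt(diag(I^-1))`. The convergence experiment runs
11 induced levels (0.25–2.75 rad, the grid implied by N = 165 / 15
repeats) × 15 repeats, each loop seeded independently from a master
seed; `convergence_statistics()` is a pure function of the traces.

The acceptance script (`scripts/acceptance.R`) reruns the pipeline end to
end at 3 repeats per level (33 loops) to stay within a small compute
budget; the test suite runs the full 15-repeat experiment.

## Numerical choices and degenerate inputs

* FFTs use a centered convention (zero frequency at `n/2 + 1`); the
  rendered PSF of a centered emitter peaks at crop pixel
  `(s/2 + 1, s/2 + 1)`.
* Gram–Schmidt rejects numerically degenerate modes; `decompose`
  uses plain inner products on orthonormal bases and QR least squares on
  coupled mirror bases.
* Zero-stderr measurements (identical subregions) are floored at the
  Kalman level, not in the estimator.
* Cycles with fewer than two usable subregions skip the mirror update
  and are flagged in the trace; an all-dark acquisition therefore leaves
  the mirror untouched.
* `quadratic_optimum` clamps the vertex into the sampled interval so a
  noisy sweep cannot command an extrapolated amplitude.
* Seed derivation for nested experiment streams uses exact Lehmer
  arithmetic below 2^53 so repeats receive genuinely distinct seeds on
  every platform.

## Known limitations

* Scalar, non-vectorial PSF; no apodization, polarization or dipole
  effects.
* The synthetic mirror basis and its coupling are surrogates; absolute
  convergence numbers transfer to a physical mirror only qualitatively.
* The 28-mode and astigmatism-modality configurations are exposed as
  degrees of freedom but are not covered by the desk-scale tests.
* Uncertainty is the across-subregion standard error; it under-estimates
  the error when all subregions share a systematic bias (e.g. at
  training-range edges).
* Real blinking data violates the generator's independence assumptions
  (photophysics, structured background); results here characterize the
  controller, not field performance.
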