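# dlao — deep-learning adaptive optics for SMLM, in simulation

Single-molecule localization microscopy (SMLM) breaks the diffraction
limit by localizing stochastically blinking fluorophores, but imaging
through tens of micrometres of tissue distorts the collected wavefront
and destroys both localization precision and reconstruction fidelity.
Because SMLM has no guide star, classical sensorless adaptive optics
(AO) must sweep deformable-mirror modes against an image-quality metric
— slow, and unstable on volumetric blinking data.

`dlao` is a fully simulated closed-loop testbed for the alternative:
*inferring the shared wavefront distortion directly from the
single-molecule emission patterns*. It is aimed at microscopy-methods
researchers who want to study, modify or benchmark this control
architecture without a microscope.

The loop implemented here is

1. a scalar pupil-function forward model renders biplane emission
   patterns: `PSF(r) = |FT{A(k) e^{i phi(k)}}|^2`, with the pupil phase
   `phi = phi_aberration + phi_defocus(z) + phi_tilt(x, y)`;
2. wavefronts are expressed on an orthonormal mirror-mode basis
   (Zernike polynomials in Wyant order, optionally cross-coupled into
   synthetic mirror modes), normalized so a unit coefficient is 1 radian
   of RMS wavefront error (`W_rms`) and `||c||_2 = W_rms` of the
   composed wavefront;
3. a residual CNN (stride-2 convolutions, batch norm, PReLU, residual
   blocks, 1×1-convolution head; implemented from scratch in
   RcppArmadillo) maps each background-subtracted biplane subregion to
   the mode-coefficient vector; estimates are averaged over the cycle's
   subregions with an across-subregion standard error;
4. one scalar Kalman filter per mode fuses measurements across
   correction cycles (`x_k | y_1..y_k`, measurement variance =
   stderr², process noise absorbs mirror nonlinearity), and the negated
   posterior drives a simulated deformable mirror with tanh stroke
   saturation and optional mode coupling;
5. three networks trained on nested amplitude ranges (0–0.8, 0–1.8,
   0–3.4 rad, as a fine-tuning curriculum from the largest range down)
   are switched based on the inference uncertainty, re-inferring each
   cycle's subregions with the range-matched member.

Baselines and evaluation: Gerchberg–Saxton phase retrieval from
31-slice bead z-stacks (and differential mirror-mode measurement),
iterative metric-based AO (radial-symmetry centering, Gaussian-masked
peak signal, quadratic-fit optima, 28 modes × 11 amplitudes × 5
iterations), 3D normalized cross-correlation, and Poisson Fisher
information / Cramér–Rao bounds for 3D localization.

## Worked example

```r
library(dlao)

setup <- desk_setup()          # optics, 6-mode mirror basis, acquisition
ensemble <- train_desk_ensemble(setup, seed = 1)   # ~10 min, one core

# induce a 1.5-rad distortion and let the loop compensate it
truth <- scale_to_wrms(c(1, -0.5, 0.8, 0.3, -0.6, 0.2), 1.5, setup$basis)
trace <- run_closed_loop(
  truth, ensemble, mirror_model(setup$basis), setup$optics, setup$acq,
  loop_config(focal_shift_constants = setup$focal_shift_constants),
  seed = 7)
print(trace)
```

```
Closed-loop trace: induced 1.500 rad, 4 updates, final residual 0.074 rad
  update residual_wrms n_subregions network_id est_mag post_mag skipped injected stage_um
1      0        1.5000           NA         NA      NA       NA   FALSE    FALSE   0.0000
2      1        0.2389           41          2  1.2872   1.2872   FALSE    FALSE  -0.0476
3      2        0.1263           52          1  0.1448   0.1294   FALSE    FALSE  -0.0543
4      3        0.0958           52          1  0.0503   0.0442   FALSE    FALSE  -0.0571
5      4        0.0743           43          1  0.0531   0.0465   FALSE    FALSE  -0.0603
```

Reading the trace: the induced distortion (1.5 rad `W_rms`) drops to
0.24 rad after a single mirror update — estimated from 41
single-molecule subregions and fused by the Kalman filter — and settles
near the 0.1-rad stop threshold within 4 updates. `network_id` shows
the uncertainty-driven switch from the mid-range to the small-range
network as the residual shrinks; `stage_um` is the focal-shift stage
compensation applied for spherical-mode corrections.

The same machinery exposes the repeated characterization experiment:

```r
exp <- run_convergence_experiment(ensemble, setup$basis, setup$optics,
                                  setup$acq, levels = seq(0.25, 2.75, 0.25),
                                  repeats = 15, seed = 20)
print(exp$summary)
```

A command-line interface wraps the pipeline for shell use:

```sh
Rscript inst/cli/dlao.R simulate --config run.yaml --out out/ --frames 20
Rscript inst/cli/dlao.R run-loop --config run.yaml --levels 0.5,1.5 --repeats 3
```

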