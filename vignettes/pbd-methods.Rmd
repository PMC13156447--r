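---
title: "Phase-based diffusion and T2 mapping: model, reconstruction and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based diffusion and T2 mapping: model, reconstruction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdmap)
```

## The measurement principle

An RF-spoiled gradient-echo sequence run with a *small* quadratic transmit-phase
increment (phi(n) = phi(n-1) + n\*theta, theta of order 1-4 degrees) does not
destroy transverse coherence: the steady state is a sum of many echo pathways
created by successive excitations.  Pathways that have lived longer in the
transverse plane carry more accumulated RF phase, and both T2 decay and
diffusion through the unbalanced crusher gradient attenuate pathways
differentially.  The net complex signal therefore *rotates*: its phase carries
quantitative information about T2 and about the apparent diffusion coefficient
(ADC), with the diffusion sensitivity controlled by the crusher moment.

The protocol acquires four passes: low and high crusher moment, each with
+theta and -theta.  Within a moment, the +/-theta passes have equal magnitude
and background phase but opposite encoded phase, so

φ = arg(I+ · conj(I−)) / 2

cancels every background contribution (B0, susceptibility, eddy currents)
exactly and returns the encoded phase.  The pair (φL, φH) is then inverted
voxel-wise for (ADC, T2) using the closed-form signal model.

## The closed-form steady state

Transverse and longitudinal magnetization are expanded in configuration
orders l (integer multiples of the per-TR crusher dephasing).  One TR applies
(i) the RF rotation, which couples order l to the conjugate of order -l and
to the longitudinal order, and (ii) relaxation, diffusion and the crusher
shift l to l+1.  Relaxation and diffusion enter through

- X(l) = exp(-t/T2) · exp(-κ (l² + l + 1/3)),
- Y(l) = exp(-t/T1) · exp(-κ l²),   κ = D γ² G² t³,

the standard b-factors of a rectangular gradient of amplitude G and duration
t.  For the quadratic phase schedule the steady state is stationary after
demodulation, and eliminating the longitudinal orders turns the balance
equations into a 2x2 transfer-matrix recursion with matrices Ψ_l
(`psi_matrix()`).  Truncating at order L (configurations beyond L negligible)
closes the recursion: with Ω = Ψ_L···Ψ_1,

ε + iη = -Ω22/Ω21,

and the demodulated signal is

S = i · β · (η X(0) + i(η² − ε(X(0) − ε))),

with β the real coefficient assembled from X(0), Y(0), flip angle and M0
(`configuration_recursion()`, `steady_state_signal()`).  The leading factor i
fixes the receiver convention such that S(−θ) = conj(S(+θ)) exactly — the
property the four-pass cancellation rests on — and places the operating-range
phase in (0°, 90°).

**Validation.**  The transcription is locked in by three independent
simulators that share physics but no code with the closed form:

1. `epg_steady_state()` — extended-phase-graph time stepping with the same
   per-order diffusion attenuation, run TR by TR with the explicit quadratic
   phase schedule (no steady-state ansatz);
2. `isochromat_bloch()` — a plain Bloch isochromat sum for the D = 0 limit;
3. `random_walk_signal()` — a Bloch-Torrey Monte Carlo in which every spin
   carries a persistent Brownian displacement and the crusher converts the
   displacement history into phase.  No configuration orders appear anywhere
   in it, which makes it the strongest check of how diffusion enters.

`validate_model()` tabulates closed-form vs EPG agreement over the operating
grid; the test suite requires < 0.1 degree phase and < 0.5 % magnitude
agreement on a 5x5x3x2 (T2 x ADC x flip x moment) grid and three-way
agreement at D = 0.

### Truncation order

The truncation study (see `test-signal-model.R`) shows the closure converges
almost immediately wherever diffusion damps high orders, and slowest at
D = 0 with long T2: at T2 = 300 ms the relative error is ~5e-3 at L = 8 and
~3e-5 at L = 32.  `sequence_params()` defaults to L = 8, which is adequate
for signal-level work at moderate flip angles; every analysis that feeds a
fit or a derivative (lookup tables, CRLB, effective b-value) uses L = 32.
The 2x2 product is renormalized each step (the closure uses only a ratio of
entries), so large L at strong diffusion weighting cannot overflow.

### Verified signal behavior

With the phase convention above (phase positive, increasing with T2):

- the single-pass phase *decreases* with ADC at the high moment, with
  |dφ/dADC| concentrated almost entirely at the high moment;
- the low-minus-high phase difference (ang L − ang H) increases monotonically
  with both ADC and T2;
- the encoding is carried by one quadrature: in the encoding frame (receiver
  frame rotated −90°) the real component attenuates strongly with ADC and T2
  while the imaginary component is nearly constant;
- the phase is nearly T1-independent (T1 700→1300 ms moves it by under a
  quarter of its T2-induced range).

All of these are asserted against the oracle stack; the random-walk
simulator confirms the sign of the ADC trend, which is a point where
intuition ("both T2 and diffusion weight the long pathways") can mislead:
T2 penalizes pathway *duration* while diffusion penalizes order *excursion*,
and the two weightings rotate the coherent sum in opposite directions.

## Units and protocol conventions

Several acquisition constants are conventions of this package and are stated
once here:

- **Crusher moment in pi-units.**  Protocol moments are labelled by the
  dephasing they produce across a reference length, in multiples of π.  The
  reference length defaults to 1.125 mm, the in-plane voxel of the in vivo
  protocol (18 cm field of view / 160 samples).  This calibration is fixed
  by two independent constraints: it makes κ ≈ 0.01 dimensionless at
  D = 1000 μm²/s for the 14π high moment, and it reproduces the reported
  CRLB precision values at the experimental operating point.  Converters
  `moment_pi_to_amplitude()` / `amplitude_to_moment_pi()` expose the
  convention explicitly; printed ms·mT/m moment values in the protocol
  table are not consistent with the π-axis under any single length and can
  be entered directly via `grad_amplitude` instead.
- **Crusher duration.**  Never printed; default `TR − 2 ms`.  The sequence
  rewinds and crushes continuously, so the per-TR relaxation interval is
  taken equal to the crusher duration (the model's X/Y factors use one
  interval t), and the oracles use the same convention.
- **SNR.**  In the CRLB module, SNR is signal magnitude over the *complex*
  noise SD; the background-free pass-pair phase then has variance
  1/(4 SNR²) at the reference pass.  This convention is what reproduces the
  reported precision numbers.  The Monte Carlo noise benchmark instead
  defines its effective-SNR axis per channel (magnitude / per-channel SD of
  the reference method's first image), the usual convention for Rician
  simulations.

## Reconstruction

`fit_maps()` minimizes

J(x1, x2) = (fH − φH)² + (fL − φL)² + λ(TV(x1) + TV(x2)) + β(x1² + x2²)

over normalized maps x1 = ADC/1000 μm²/s, x2 = T2/100 ms (so a single step
size serves both parameters).  Design choices:

- **Forward interpolant.**  fL/fH and their gradients come from a
  tensor-product cubic B-spline fit of the closed form on a uniform
  (ADC, T2) grid (default 50 μm²/s × 5 ms steps over 0–3200 μm²/s ×
  15–520 ms, covering the fit bounds with margin).  Off-grid error is below
  1e-4 rad; out-of-range queries are clamped and counted.
- **Initialization.**  A per-voxel coarse grid search (25×25 nodes over the
  bounds) of the data term, then gradient refinement.  The data-fidelity
  surface has a long curved valley (φL is nearly a function of T2 alone);
  a constant starting map can ride that valley into a bound for short-T2
  voxels, while the grid start is reliable over the whole box and is
  deterministic.  Constant starts remain available via
  `recon_config(init = c(adc =, t2 =))`.
- **Optimization.**  Projected gradient descent with Barzilai–Borwein steps
  (global step for the coupled TV problem, per-voxel steps in
  `fit_voxel()`), step clipped to [1e-8, 1e2] in normalized units.  BB
  iterations are intentionally non-monotone; the safeguard tracks the best
  iterate, restarts from it with a small fixed step after five consecutive
  iterations more than twice above the best objective, and always returns
  the best iterate.  Convergence: the best objective improves by less than
  1e-8 (relative to its starting value) over a 20-iteration window, with a
  2000-iteration cap.
- **TV smoothing.**  Isotropic 3D TV with ε = 1e-6 smoothing to admit
  gradient descent; forward differences, Neumann boundaries.
- **Regularization weights.**  λ = β = 1e-6 by default — small enough not
  to confound quantification, present to stabilize low-SNR regions.
- **No phase unwrapping.**  Model phases stay within (0°, 90°) over the
  operating range (verified by a dense grid scan, maximum ≈ 59°), so the
  (−90°, 90°] principal value of the pass-pair phase never wraps in
  noiseless data; low-magnitude voxels are masked instead.
- With λ = β = 0 the problem is voxel-separable and a one-voxel volume
  reproduces `fit_voxel()` to machine precision (tested).

## Protocol analyses

**Effective b-value** (`effective_bvalue()`): the encoded signal component is
fit to S0·exp(−bD) over D ∈ [0, 2000] μm²/s at a representative T2 of 120
ms (Gauss–Newton on the nonlinear model, log-linear start).  The b-value of
this sequence is approximate by construction — pathways see different
diffusion times — and the resulting b̂ depends on the unprinted crusher
duration, so numerical b̂ values are documentation, not targets; the tested
claims are b̂ ≈ 0 without a crusher and strict growth with moment.

**B1+ bias** (`b1_bias_curves()`): phase pairs are generated at
actual flip = B1 × nominal and inverted assuming nominal flip.  ADC is
overestimated below B1 = 100 % and underestimated above; T2 is biased
downward at both ends of the B1 range.

**CRLB** (`crlb_point()`, `crlb_sweep()`): the Jacobian of (φL, φH) with
respect to (D, T2) by central differences (1 % steps, halving changes the
result by < 0.1 %), Fisher information J'Σ⁻¹J, and SD = sqrt(diag(F⁻¹)).
Two noise models share the SNR convention above: *equal variance*
(Var φL = Var φH = 1/(4 SNR²)) and *amplitude-weighted* (one complex noise
level fixed so the low-moment pass has the reference SNR; the high-moment
phase variance scales with the inverse squared magnitude).  The
amplification ratio r = SD_amp/SD_eq attributes precision limits: ADC is
amplitude-limited (r > 1) at high moments, T2 is conditioning-limited
(r ≈ 1) everywhere.  At the experimental point (20°, 14π) the predicted
ADC SD is ≈ 438 μm²/s, at the sweep optimum (17°, 15π) ≈ 405 μm²/s — within
a few percent of the reported reference values of 456/440.  The same computation yields T2 SDs
of ≈ 17.5 ms (experimental) and ≈ 15.7 ms (sweep minimum), about 18 % below
the published 21.4/18.9 ms; no self-consistent noise convention matches
both the ADC and T2 pairs simultaneously (a single noise scale moves all
four SDs together), so the T2 values are reported as computed.

## Time-normalized noise benchmark

`compare_methods()` compares PBD against single-shot EPI (log-ratio ADC, one
or three directions) and multi-echo spin-echo T2 fitting at a fixed total
scan time (10 min) and matched voxel size.  Baseline amplitudes come from
each method's physical model (spin-echo signal for EPI/SESE, |S| of the
closed form for PBD).  Noise variance scales as BW / (NSA · Ns), with NSA
the number of whole averages fitting the budget (600 s over per-average
times of 288/205/285 s → NSA ≈ 2.08/2.93/2.11) and Ns the number of slice
positions encoded per volume (22 EPI, 32 spin echo, 32 PBD) — i.e. equal
scan time per covered volume.  This Ns reading is fixed by two reported
behaviors simultaneously: the PBD/EPI ADC SD ratio in the 1.5–14 range and
PBD T2 variability comparable to the spin-echo reference.  Reading Ns as a
pure 3D-averaging benefit (2D methods = 1) would make PBD's ADC SD *smaller*
than EPI's and its T2 SD five times smaller than the spin echo's,
contradicting both.

The three-direction EPI estimator averages the three directional
acquisitions complex-valued before the magnitude (legitimate under isotropic
diffusion, where the three true signals are identical); this is the only
averaging scheme by which "noise reduction of averaging" can reduce the
Rician-floor bias of the mean, and it reproduces the reported behavior
(3-dir mean bias ≈ −8 % vs 1-dir ≈ −26 % at SNR 5).  Plain magnitude
averaging leaves the floor bias intact and was measured to make the 3-dir
mean *worse*.

Failure replicates (non-finite fits, diverged nonlinear least squares) are
excluded and tallied.  All simulations run on a deterministic seed ladder;
identical configurations give bit-identical tables.

At the default conditions PBD's median ADC stays within about ±2 % of truth
for reference SNR ≥ 10 at all three tissue settings, while the EPI median is
pulled down 15–65 % at SNR ≤ 5 by the Rician floor; PBD pays with a 1.6–8×
larger ADC SD.  At reference SNR 5–7 the PBD pass SNR is only ~1.6–2.4 under
this time normalization, and occasional ±90° wraps of the pass-pair phase
push the worst-case median bias to about −7 %.

## What the synthetic phantoms do and do not show

`make_phantom()` builds a 16-vial grid (4 ADC levels × 4 T2 levels, defaults
spanning 300–2100 μm²/s and 40–250 ms — synthetic choices covering the model
grid, not published reference values), a prostate-like geometry with an
air disc, or a uniform block.  `forward_acquire()` simulates the four passes
from the closed form, multiplies in smooth random second-order polynomial
background-phase fields (different per moment, amplitude up to ±π, stressing
the cancellation hard) and adds complex Gaussian noise.

Because the forward simulator and the reconstruction share the signal model,
phantom recovery is an *inverse-crime* consistency check: it validates the
pipeline (phase extraction, interpolant, optimizer, masking) to the
interpolation tolerance, and the noisy-case spread against the CRLB.  It
cannot probe model error against real tissue: no T2*, no magnetization
transfer, no flow, no motion or misregistration between passes, no
susceptibility or distortion physics, and Gaussian (single-compartment)
diffusion only.  Geometric-fidelity claims about real scans are
acquisition-physics effects outside an image-space simulator and are not
reproduced here.

## Problem sizes used by the validation suite

The shipped tests run the oracle grid at 150 points (EPG order 128 where the
slow corner demands it), the Monte Carlo benchmark at 10 000 replicates per
condition over SNR 3–50, and the end-to-end phantom at 64×64×8 voxels,
noiseless and at a complex noise SD of 0.002 (pass-pair SNR ≈ 20–45 across
vials).  These sizes keep the full suite within a few minutes on one CPU
while leaving every Monte Carlo margin far from its threshold.
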