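# pbdmap

Joint apparent-diffusion-coefficient (ADC) and T2 mapping from
RF-phase-modulated gradient-echo MRI — "phase-based diffusion" (PBD)
mapping.

## The problem

Clinical diffusion imaging relies on single-shot EPI, which distorts badly
near air–tissue interfaces (rectum, sinuses, metal) and limits resolution.
A spoiled gradient-echo sequence run with a *small* quadratic RF phase
increment θ keeps many echo pathways coherent; T2 decay and diffusion
through an unbalanced crusher gradient attenuate the long-lived pathways
differentially, so the *phase* of the steady-state signal encodes both T2
and ADC — distortion-free, 3D, at gradient-echo resolution.

The steady state has a closed form.  Expanding the magnetization in
configuration orders *l* with relaxation/diffusion factors

    X(l) = exp(-t/T2) exp(-κ(l² + l + 1/3)),  Y(l) = exp(-t/T1) exp(-κ l²),
    κ = D γ² G² t³,

the order amplitudes obey a 2×2 transfer-matrix recursion Ψ_l; with
Ω = Ψ_L···Ψ_1 and ε + iη = −Ω22/Ω21, the demodulated signal is

    S = i β (η X(0) + i(η² − ε(X(0) − ε))),
    β = (1−Y(0)) M0 sin α / ((X(0)−ε)(X(0)(cos α−Y(0)) + ε(1−Y(0) cos α)) − η²(1−Y(0) cos α)).

Acquiring four passes (low/high crusher moment × ±θ) and forming
φ = arg(I₊·conj(I₋))/2 per moment cancels all background phase exactly and
leaves two observables (φL, φH) that are inverted voxel-wise for (ADC, T2).

The package provides:

- the closed-form signal model (`steady_state_signal()` and friends), with
  extended-phase-graph, isochromat and random-walk Bloch–Torrey simulators
  as independent numerical oracles (`epg_steady_state()`,
  `isochromat_bloch()`, `random_walk_signal()`, `validate_model()`);
- four-pass phase extraction and TV/L2-regularized map reconstruction with
  Barzilai–Borwein steps and a cubic-spline forward interpolant
  (`extract_phase_pair()`, `build_phase_lookup()`, `fit_voxel()`,
  `fit_maps()`);
- protocol analyses: effective b-value (`effective_bvalue()`), transmit-field
  bias curves (`b1_bias_curves()`), Cramér–Rao lower bounds under two phase
  noise models (`crlb_point()`, `crlb_sweep()`);
- a time-normalized Monte Carlo noise benchmark against EPI ADC and
  spin-echo T2 estimators (`compare_methods()`);
- synthetic digital phantoms and complex-volume NIfTI I/O
  (`make_phantom()`, `forward_acquire()`, `read_complex_volume()`, …) and a
  thin command-line wrapper (`inst/cli/pbd.R`).

See the methods vignette (`vignettes/pbd-methods.Rmd`) for the model,
conventions (moment π-units, SNR definitions, time normalization) and
design choices.

## Worked example

Simulate the 16-vial digital phantom, acquire the four passes with random
background-phase fields and noise, and reconstruct:

```r
library(pbdmap)

seq_low  <- sequence_params(TR = 10.9, alpha = 20, theta = 2, moment_pi = 2)
seq_high <- sequence_params(TR = 10.9, alpha = 20, theta = 2, moment_pi = 14)
seq_high
#> PBD sequence: TR 10.90 ms, TE 0.00 ms, alpha 20 deg, theta +2 deg
#>   crusher: 16.420 mT/m x 8.90 ms (146.14 ms mT/m = 14.00 pi per 1.125 mm), L = 8

tissue <- tissue_params(T1 = 1000, T2 = 120, D = 1300)
S <- steady_state_signal(tissue, seq_high)
sprintf("|S| %.4f, phase %.2f deg", Mod(S), Arg(S) * 180 / pi)
#> "|S| 0.0776, phase 25.26 deg"

truth <- make_phantom(phantom_spec(dim = c(64, 64, 8), seed = 7))
acq   <- forward_acquire(truth, seq_low, seq_high, noise_sd = 0.002, seed = 11)
pair  <- extract_phase_pair(acq, mag_floor = 0.01)   # ~5x the noise SD
maps  <- fit_maps(pair, recon_config(), seq_low = seq_low, seq_high = seq_high)
maps
#> PBD parameter maps 64x64x8: 284 iterations, converged
#>   ADC median 1159 um2/s, T2 median 118.9 ms over 14336 masked voxels

head(roi_summary(maps, truth), 3)
#>   label adc_true t2_true adc_median t2_median n_voxels adc_err_pct t2_err_pct
#> 1     1     2100     250   2099.417 250.10503      896 -0.02778448  0.04201155
#> 2     2     2100     150   2093.015 149.97736      896 -0.33259958 -0.01509651
#> 3     3     2100      90   2093.852  89.69096      896 -0.29276396 -0.34338285
```

Per-vial median errors stay well under 1 % at this noise level (pass-pair
SNR ≈ 20–45 across vials).  The predicted precision at the experimental
operating point (flip 20°, moment 14π, reference SNR 10):

```r
unlist(crlb_point(crlb_config(), alpha = 20, moment_pi = 14))[
  c("sd_adc_amp", "sd_t2_amp", "r_adc", "r_t2")]
#> sd_adc_amp  sd_t2_amp      r_adc       r_t2
#> 438.167619  17.515758   1.202329   1.000837
```

i.e. an ADC standard deviation of ≈ 438 μm²/s, amplitude-limited
(r > 1), and a T2 standard deviation of ≈ 17.5 ms, conditioning-limited
(r ≈ 1).

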