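---
title: "Models and methods behind the samba toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the samba toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samba)
```

This vignette is the package's own account of its science: the signal
models and their assumptions, the numerical choices inside the spiral
reconstruction and the fitters, what the synthetic phantom does and does
not emulate, and the design decisions that were genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Quantitative T1/T2 mapping on low-field preclinical scanners is limited by
the scan time of gold-standard spin-echo protocols: one phase-encode line
per repetition time, times 13 inversion times (T1) or 7 preparation times
(T2), adds up to hours per slice. The toolkit implements and evaluates a
fast alternative that combines a multi-shot interleaved **spiral
acquisition** (minutes per map) with **dictionary matching** of the
resulting magnitude time-courses, and provides everything needed to
compare the four method permutations — spin-echo vs. spiral acquisition
crossed with least-squares fitting vs. matching — on synthetic multi-tube
relaxation phantoms.

## Signal models

All four models live in `R/signal_models.R` and are consumed unchanged by
the dictionary builder and the phantom simulator, so estimator and
simulator share one physics layer.

**Inversion-prepared Look-Locker train** (`ll_ir_signal`). One adiabatic
inversion followed by `n_readouts` small-flip excitations spaced
`readout_spacing` τ apart:

* inversion: Mz ← (1 − 2ε)·Mz. ε = 1 (ideal adiabatic inversion) by
  default; the paper-level efficiency of the pulse is modeled as this one
  scalar. The (1 − 2ε) convention makes ε = 0 a no-op and matches the
  familiar IR expression below.
* per readout: Mz ← M0 + (Mz − M0)·e^(−τ/T1); sᵢ = sin α · Mz;
  Mz ← cos α · Mz.

Assumptions: T2 decay over the 1.66 ms echo time is neglected (τ = 265 ms);
each shot starts from equilibrium (TR = 14 s leaves ~750 ms of recovery
after the 13.25 s train, so this is not exact — an `n_dummy_shots`
argument simulates the approach to the inter-shot steady state for anyone
who wants to quantify the difference); the first readout occurs one
`readout_spacing` after the inversion (`first_delay`, exposed as a
parameter because the sequence timing does not pin it down).

**T2 preparation** (`t2prep_signal`): s = M0·e^(−TP/T2), ideal preparation
with no relaxation during the prep block. **IR spin echo**
(`ir_se_signal`): s = M0(1 − 2ε·e^(−TI/T1) + e^(−TR/T1)), the finite-TR
recovery term included by default. **Spin-echo T2** shares the preparation
decay model.

## Dictionary matching

`build_dictionary()` simulates the protocol's signal for every candidate
relaxation value, takes magnitudes (measured images are magnitude images;
`signed = TRUE` keeps polarity for synthetic complex data) and stores
unit-L2 atoms together with their pre-normalization norms.
`match_signal()` maximizes the cosine similarity between the normalized
signal and the atoms — scale invariance makes the match independent of
M0, and M0 falls out of the un-normalized inner product for free.
Euclidean distance on normalized vectors would order candidates
identically; the inner product is kept because it directly yields both the
quality score in [0, 1] and the M0 estimate. Ties break toward the smaller
grid value for reproducibility.

Default grids: T1 50–5000 ms in 10 ms steps; T2 5–100 ms in 1 ms steps
then 2 ms steps to 500 ms. They bracket the spin-echo sampling ranges
(TI up to 9250 ms resolves T1 well past 3000 ms; TP up to 400 ms) with a
step below the noise-induced estimation error at the default noise level,
so grid quantization is never the dominant error source. The exact grid
used on any given scanner is not public; these are the package's own
defaults and are recorded in each dictionary's provenance fingerprint.

## Spiral acquisition and gridding

`design_spiral()` builds a constant-angular-density Archimedean spiral,
k(u) = k_max·u·e^(i(2π·n_turns·u + φ_m)), with k_max = N/(2·FOV) (Cartesian
Nyquist), n_turns = N/(2·n_interleaves) (azimuthal Nyquist at the k-space
edge) and interleaf phases φ_m = 2πm/n_il. Gradient and slew-rate limits
are not modeled — only the published interleaf and sample counts are
reproduced, and the simulator and reconstructor share the same nominal
trajectory, so the hardware trajectory-calibration problem does not arise
in silico (on a scanner the trajectory would be measured; that workflow is
out of scope here).

Two density-compensation estimators: the analytic annulus-area rule
(w ∝ ‖k‖·Δ‖k‖ with a nonzero floor at the center) and discretized Voronoi
cell areas (nearest-sample assignment of a fine grid over the Nyquist
disk; an approximation chosen over exact polygon clipping, accurate to the
grid resolution). Both normalize to the disk area πk_max².

The forward model s(k) = Σ_r x(r)·e^(−2πi k·r) has two implementations:
direct evaluation (the testing oracle, O(samples × pixels)) and
interpolation from a 2×-oversampled FFT grid through a width-4
Kaiser-Bessel kernel with β per the standard Beatty prescription.
Deapodization uses the kernel's exact continuous Fourier pair, so forward
interpolation and adjoint gridding are built from the same sparse
operator and satisfy ⟨Ax, y⟩ = ⟨x, A*y⟩ to machine precision — the adjoint
test in the suite fixes the FFT sign/shift conventions once and for all.
Reconstruction is adjoint gridding of density-weighted samples scaled by
the pixel area Δ²; the disk-vs-square spectral support difference makes
the round trip a mild low-pass, which is why the round-trip bound is
checked on a smooth phantom (NRMSE < 0.05) and ROI means of tube phantoms
are compared at the 2 % level, with ROIs eroded by 1.5 px to avoid edge
ringing and partial-volume voxels, as one would draw ROIs in practice.

## Least-squares fitting

**T2**: ordinary least squares of log s on TP (slope −1/T2). The weighted
variant (weights s²) compensates the noise distortion of the log
transform. Fits with T2 above 10 s are flagged not-converged — a
near-constant series carries no decay information.

**T1 from magnitude IR data** cannot be linearized without restoring
polarity, so "conventional" fitting here means: for each candidate flip
index k, negate the first k samples and solve the signed three-parameter
model A − B·e^(−t/T1). For fixed T1 the (A, B) subproblem is linear, so
the solver is variable projection: closed-form normal equations inside a
coarse log-spaced T1 grid (100 points), a bracketed 1-D `optimize()`
refinement (tolerance 1e−9 on log T1), and a final `nls()` polish
(port algorithm, tolerance 1e−10, ≤ 200 iterations) that is accepted only
if it does not worsen the residual. For short series (≤ 16 points) every
flip index is tried; for the 50-point train the search is windowed ±3
around the signal minimum. This is more robust than a general 3-parameter
descent: the only nonlinear coordinate is 1-D and the RSS profile in T1 is
smooth.

**Look-Locker correction.** The fitted T1* describes the flip-angle-driven
apparent recovery, e^(−τ/T1*) = cos α·e^(−τ/T1) exactly for the discrete
train. Two corrections are offered. The default inverts that relation
using the nominal flip angle, 1/T1 = 1/T1* + ln(cos α)/τ, which is exact
for this signal model. The classic flip-angle-free amplitude correction
T1 = T1*(B/A − 1) is also provided (`correction = "ratio"`): it is the
right tool when the true flip angle is uncertain (B1 inhomogeneity), but
for a discretely sampled train whose first readout sits a full τ after the
inversion it carries a deterministic bias — closed form:
fitted B/A − 1 = (1 − cE)/(c(1 − E)) with c = cos α, E = e^(−τ/T1), versus
the ideal T1/T1* — of about +3.3 % at α = 20°, τ = 265 ms, T1 = 1000 ms.
The package defaults to the exact correction because the simulation knows
its flip angle; the test suite pins the ratio variant's bias band so the
documented behavior cannot drift silently.

**Rician noise-floor handling.** Magnitude images plateau at the Rayleigh
floor instead of decaying to zero, which inflates short-T2 estimates
drastically once late preparation times fall under the floor (at the
default noise level the plain log-linear fit returns ~400 ms for a 20 ms
tube). `fit_series()` therefore estimates the Gaussian noise component
from out-of-mask background voxels (Rayleigh median = σ√(2 ln 2)), applies
the standard power correction √(s² − 2σ²), and excludes points below
3σ from T2 fits (each voxel keeps its leading run of supra-floor points;
at least two are required). The 13-point IR fit uses the same power
correction; the Look-Locker train does not, because its signal crosses
zero mid-train and clamping corrected magnitudes to zero would distort
exactly the crossing that encodes T1. Standalone `fit_t2_loglinear()`
defaults to no floor handling (`noise_sigma = 0`), keeping the plain
log-linear contract for clean data.

## The digital phantom and what it does (not) emulate

`make_tube_phantom()` lays out equal-area circular tubes on a ring
(areas are exactly equal because one disk template is stamped at integer
pixel shifts). The default eight tubes span T1 300–3000 ms and T2
20–400 ms with unit proton density — the ranges the spin-echo protocols
were designed to sample; the physical phantom's exact tube values are not
public, so these are the package's fixed study condition.

`simulate_series()` adds i.i.d. complex Gaussian noise to every k-space
sample — the physical noise mechanism in MRI — so magnitude images acquire
Rician statistics without any explicit magnitude-noise model. The noise
scale is expressed relative to the DC signal of a unit-M0 tube;
`kspace_sigma = 1/50` (k-space SNR 50) is the default study condition and
all acceptance-level numbers are computed there. NSA signal averages are
simulated as independent draws averaged in k-space.

Not emulated: B0/B1 field inhomogeneity and slice profiles (the main
real-world error sources for matching-based T2 estimates), motion,
temperature dependence, relaxation during the T2 preparation, and
measured-trajectory deviations. Passing tests therefore demonstrate
algorithmic correctness and noise behavior, not robustness to those
physical effects.

## Evaluation layer

ROI statistics use the sample (n−1) standard deviation throughout — with
8 repeats the distinction is material, and the repeatability metric
CV% = SD/mean·100 inherits it. Bland-Altman limits of agreement use the
1.96 multiplier (95 %). Method-comparison regressions run on per-tube
means averaged over repeats (a per-repeat option exists); t-tests are
paired by tube. Nominal scan times follow the sequence structure: spiral
T1 = interleaves × NSA × TR (one inversion train per TR); spiral
T2 = interleaves × preparations × NSA × TR; spin echo = phase encodes ×
frames × NSA × TR. The spin-echo IR preset's published duration is not
reproducible from any obvious factorization of its printed parameters
(the acquisition likely used acceleration that is not described), so no
assertion is made for it; its nominal formula value is used in the
CV%·time efficiency ratios, which only makes those ratios conservative or
not by a constant factor.

## Problem sizes and determinism

The test suite runs the full published geometries where it matters (the
acceptance tests simulate the eight-tube phantom under all four Table-size
protocols at k-space SNR 50 with 8 repeats — about a minute of compute)
and reduced sizes (32–64 matrices, hundreds of spiral points) for
operator-level oracle checks, where the mathematics is size-independent.
Monte-Carlo comparisons against the `minpack.lm` nonlinear oracle use 400
draws; the IR grid-search oracle uses 60 draws × 400-point grids. Every
random draw flows through explicit seeds (`withr::with_seed` inside the
simulator; repeat r uses seed + r − 1), so every table and map in an
experiment is reproducible byte for byte, and the provenance record stores
the config hash, seed and package version.

## Known limitations

* The Look-Locker amplitude-ratio correction bias analysis assumes ideal
  inversion; with ε < 1 both corrections inherit a bias unless ε is known.
* Voronoi weights are grid-discretized; for trajectories with extremely
  nonuniform density the 301² default grid may under-resolve the center.
* The noise-floor threshold (3σ) is a bias/variance compromise: voxels
  whose true signal hovers near the threshold keep a noise-selected subset
  of points, which leaves a small upward bias on very short T2 at low SNR.
* Spin-echo simulation is an instantaneous fully sampled Cartesian FFT;
  sequence timing within the echo train is not modeled, because the
  spin-echo images serve only as the comparator input.
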