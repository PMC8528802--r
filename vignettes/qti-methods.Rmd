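---
title: "Quantitative transient-state imaging: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative transient-state imaging: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative transient-state imaging (QTI) is an MR-fingerprinting-style
technique: instead of waiting for a steady state, the sequence varies the flip
angle every repetition so the magnetization keeps evolving, and the *shape* of
the resulting signal time-series encodes the tissue's T1 and T2
simultaneously, with the signal scale giving relative proton density (PD).
One 3D acquisition therefore yields whole-brain T1, T2 and PD maps, from which
conventional contrast-weighted images (T1w, T2w, FLAIR) can be synthesized at
no extra scan time — attractive for brain-tumor protocols under tight time
constraints, where the same maps also support quantitative ROI analysis of
tumor substructures.

`qtimap` implements this pipeline end to end on synthetic data: sequence
simulation, dictionary and subspace construction, undersampled spiral
acquisition simulation, reconstruction, parameter inference (dictionary
matching and a compact neural network), contrast synthesis, a digital
brain-tumor phantom, and the T1-T2 mixture analysis of tumor core voxels.

## Signal model

The sequence is an inversion-prepared, gradient-spoiled (FISP-type) train:
an adiabatic inversion at t = 0, free relaxation over TI = 18 ms, then 880
repetitions (TR = 7.8 ms, TE = 1.8 ms) whose flip angles ramp from 0.8° up to
70° and back. The exact in vivo flip-angle waveform is not part of the
package; the default is the simplest shape consistent with those constraints —
a symmetric piecewise-linear triangle over the 880 repetitions — and any
waveform can be supplied as a one-column CSV via `load_schedule()`. All
dictionary and test signals use the same schedule, so results are
self-consistent under any fixed choice.

Signals are simulated with the extended phase graphs (EPG) formalism: the
magnetization is tracked as configuration states (F+k, F−k, Zk) under RF
rotation, relaxation, and one unit gradient-spoiler shift per TR (unbalanced
spoiling, constant RF phase, no RF spoiling — the standard convention for
transient-state fingerprinting sequences). The echo is the primary transverse
state immediately after each pulse, decayed by exp(−TE/T2); off-resonance,
B1 inhomogeneity and slice profiles are not modeled. States above order 100
are truncated by default; doubling the order changes the signal by a relative
L2 error below 1e−6 (tested), and the simulator is checked against an
independent isochromat-ensemble oracle (1000 spins spanning 2π of intra-voxel
dephasing per TR) to relative L2 error below 1e−3. With constant RF phase and
an equilibrium start, all states share one global phase, so the recursion
runs in real arithmetic (C++), which is what makes the 52,670-atom dictionary
buildable in minutes on one core.

## Dictionary, subspace, matching

The dictionary samples T1 every 10 ms on [10, 2000] ms and every 100 ms on
[2100, 5000] ms (230 values), and T2 every 5 ms on [10, 300] ms and every
10 ms on [310, 2000] ms (229 values). All combinations are kept, including
T2 > T1 — the grid is a specification, not a physical prior — with an option
to exclude them. Atoms are unit-PD signals, L2-normalized, with the
pre-normalization norm stored.

The temporal basis is the top right singular vectors of the normalized atom
matrix (rank 10 by default), computed from the dictionary rather than from
data so the compressed atoms can be precomputed once. Matching maximizes the
modulus of the complex inner product (phase-invariant, since acquisition
phase is arbitrary) between the compressed signal and compressed atoms that
are *renormalized in the compressed domain*; the PD scale stored with each
atom is the compressed-domain norm of its unit-PD signal. This makes two
identities exact rather than approximate: self-matches score correlation 1,
and a clean signal of proton density s recovers PD = s (both tested at 1e−6).
Ties are broken by the lowest atom index (T1-major, T2-minor order), so
matching is bit-reproducible.

## Neural-network inference

The network mirrors the compact multi-path design used for memory-efficient,
dictionary-free inference: the complex rank-10 input is phase-aligned (by the
conjugate phase of its first coefficient; default encoding keeps the real
parts), L2-normalized, and fed to three independent pathways of three
ReLU-activated layers (200, 100, 1 nodes) producing T1, T2 and θ₃, a
PD-related scale. Because the input is normalized, θ₃ is learned as the
compressed unit-PD signal norm, and the reported proton density is the
*formula* PD = ‖x‖₂/θ₃ — exact by construction, independent of training
quality.

Training minimizes mean absolute percentage error (averaged without weighting
over the three outputs, ε = 1e−6 in denominators) by minibatch SGD. Defaults
follow the reference protocol: up to 1000 epochs, learning rate 1e−4, dropout
0.8 (read literally as the drop probability; both readings are plausible and
it is config-exposed), 80/20 seeded train/validation split, best-validation
checkpoint kept. Two quantities the protocol leaves open were fixed as
package choices: targets are internally rescaled by their training-set means
(MAPE is invariant to this, but it puts all three outputs on comparable
numeric scale for SGD), and the training noise level defaults to complex
white noise with total expected energy 2% of the mean atom norm. The test
suite trains a smaller, faster variant (coarse grid, 400 epochs, learning
rate 0.1, momentum 0.9, no dropout) — the architecture is identical, and the
checks (median held-out percentage error below 5%, median bias below 2%,
median |ΔT1| versus dictionary matching below one grid step) are properties
of the method, not of the training budget.

## Acquisition simulation and reconstruction

Each repetition acquires one variable-density Archimedean spiral interleaf,
rotated by golden-angle increments in-plane (and, in 3D, tilted to a
Fibonacci-sphere direction so the repetitions cover the k-space ball). The
exact rotation schedule and interleaf geometry of the reference acquisition
(undersampling factor 628 at 200³) are not published; the generator is
parameterized so any schedule can be supplied. Desk-scale defaults are 2D
64²–32² matrices with 100–880 repetitions — every property tested
(adjointness, error ordering, recovery) is scale-free.

Sampling is modeled by the exact non-uniform discrete Fourier transform
(Rcpp, separable phase factors), not an approximate gridding NUFFT: at these
problem sizes the exact transform is tractable, and it makes the forward and
adjoint operators exact conjugate transposes — the property the central
adjoint test checks to 1e−6, and which iterative reconstruction relies on.
Voxel signals are projected onto the rank-10 basis *before* sampling
(equivalent to simulating the full time series and projecting afterwards, up
to the tiny subspace residual, and what makes 880-repetition problems fit in
memory).

Three reconstructions are provided:

* **zero_fill** — density-compensated adjoint per component, coil-combined.
  Density compensation uses radial-annulus weights: each sample carries the
  k-space measure of its annulus divided by the sample count there, scaled by
  the Cartesian cell count, so on a fully sampled set the weights reduce to
  1/N and the adjoint matches the inverse DFT amplitude. (A Voronoi
  tessellation would refine this azimuthally; no Voronoi implementation is
  available in the dependency set, and for spiral geometry the radial-average
  weights coincide with the Voronoi areas up to azimuthal variation.)
* **view_share** — k-space sharing across a sliding temporal window with a
  triangular kernel (default ±8 repetitions), implemented equivalently as a
  temporal smoothing of the subspace contraction weights.
* **lrtv** — compressed sensing: minimize ‖A(c) − y‖² + λ·Σⱼ TV(cⱼ) over
  coefficient images constrained to the temporal subspace, with isotropic
  spatial total variation on each (complex) component. The solver is a
  monotone proximal-gradient iteration: step size 0.9/(2·‖AᴴA‖) from a power
  method, TV proximal operator by Chambolle's dual projection extended to
  complex images, warm-started from the zero-fill solution, and a candidate
  step is only accepted if the objective does not increase (so the tested
  monotonicity is guaranteed even with an inexact inner prox). A fixed
  iteration count (default 40) keeps runs deterministic.

Coil sensitivities are estimated by the adaptive (Walsh-style) method: the
dominant eigenvector of the locally box-smoothed coil covariance, normalized
to unit root-sum-of-squares, with the first coil's phase as reference.

One numerical caveat the tests make explicit: a disc-covering spiral carries
no energy in the Cartesian corner frequencies, so the "full sampling recovers
the truth" check uses a band-limited phantom (1-voxel Gaussian smoothing);
with the raw iid-voxel phantom about 1.3% of the spectral energy lies in the
corners, which bounds any disc-limited reconstruction from below.

## The phantom

`make_phantom()` builds a parametric, seeded stand-in for a patient volume:
an ellipsoidal brain with a gray-matter shell, white-matter interior and CSF
ventricles, plus a spherical tumor complex (solid core I containing a
fluid-like core II blob, an enhancing rim, an edema shell). Per-voxel T1 and
T2 are drawn independently from each tissue's normal distribution, truncated
to the dictionary ranges so every voxel is matchable. The tumor and WM/GM
distributions are the cohort means and standard deviations reported for the
annotated ROIs; CSF values (T1 4000 ms, T2 1500 ms) and the per-tissue proton
densities (WM 0.70, GM 0.85, CSF 1.00, tumor classes 0.90–1.00) are not part
of that summary and are implementer defaults from standard 3T literature
ranges, all config-exposed.

What the phantom does *not* emulate: anatomy (the geometry is parametric, not
atlas-based), spatial texture correlation (draws are iid by default; optional
Gaussian smoothing adds texture at the cost of exact draw statistics), and
partial-volume mixing at tissue boundaries. Passing tests on this phantom
therefore demonstrates the correctness of the pipeline's operators and
estimators under controlled statistics — not robustness to anatomy,
partial-volume effects, motion, or B0/B1 imperfections, none of which are
modeled.

## ROI analysis and tumor subclassification

`roi_statistics()` reports per-ROI voxel counts and the mean and *population*
standard deviation of T1 and T2 (the reference table does not state which
convention it used; population SD is the documented package choice).

The necrotic/non-enhancing tumor ROI is subclassified by a two-component
Gaussian mixture on the raw (T1, T2) values in ms (no standardization,
matching the analysis in the T1-T2 plane; z-scoring is available as an
option). The EM fit uses full 2×2 covariances, convergence at a log-
likelihood gain below 1e−6 or 500 iterations, a ridge of 1e−6·trace on
near-singular covariances, and k-means initialization seeded at per-
coordinate quantiles — a deterministic, permutation-invariant starting point,
so the fit depends only on the sample set and the seed. Components are
reordered by ascending mean T1: component 1 is the solid-like core I,
component 2 the fluid-like core II. Back-projection assigns each in-mask
voxel its maximum-posterior component, purely voxelwise (no spatial
regularization — spatial connectivity is an observation, not a constraint).
An independent mixture implementation (mclust) serves as a cross-check in the
test suite, not as the implementation.

## Problem sizes and reproducibility

The package's own test suite runs at desk scale by choice: a 30×15 coarse
dictionary with a 100-repetition schedule for matching and network tests,
32² phantoms with 64 repetitions, 256 spiral samples and 2 coils for
reconstruction, and a full 230×229-atom dictionary (880 repetitions, built in
a few minutes) only where values are compared against the cohort table. Every
stochastic step — phantom draws, acquisition noise, training splits and
initialization, mixture initialization — takes an explicit seed, and
`qti_run()` writes a manifest with config hash and per-product checksums;
rerunning a configuration reproduces every product bit for bit.

## Known limitations

* No off-resonance, B0/B1, slice-profile, motion or flow modeling anywhere in
  the chain; contrast synthesis uses T2 where a T2* map would be needed for
  the spoiled-gradient-echo equation, and is restricted to native
  (pre-contrast) contrasts.
* The trajectory generator exposes interleaf counts and rotation schedules as
  parameters rather than reproducing any scanner's exact geometry.
* Dictionary matching does not interpolate between grid points and carries no
  B1 dimension.
* The LRTV temporal regularization is the hard subspace constraint (rank 10);
  no additional low-rank penalty is applied within the subspace.
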