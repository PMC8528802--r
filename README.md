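# qtimap

Simulation, reconstruction and analysis for **3D quantitative transient-state
imaging (QTI)** — an MR-fingerprinting-style method that maps T1, T2 and
relative proton density (PD) from a single accelerated acquisition, for people
who want to study or prototype the full processing chain without scanner
data: MR physicists, image-reconstruction researchers, and methodologists
working on quantitative brain-tumor imaging.

## The method

An inversion pulse is followed by 880 gradient-spoiled repetitions
(TR = 7.8 ms, TE = 1.8 ms, TI = 18 ms) whose flip angles ramp between 0.8°
and 70°, so the magnetization never reaches a steady state; the temporal
signal shape encodes (T1, T2) and its scale encodes PD. The package
implements:

* **EPG simulation** — extended-phase-graph signal evolution of the
  inversion-prepared FISP-type train (Rcpp core, verified against an
  isochromat-ensemble oracle to relative L2 error < 1e-3);
* **dictionary + subspace** — unit-norm signal atoms on the native
  (T1, T2) grid (230 × 229 = 52,670 atoms), a rank-10 temporal SVD basis, and
  phase-invariant inner-product matching with the PD estimate
  `PD = ||x||₂ / θ₃`, where θ₃ is the atom's unit-PD signal norm;
* **neural-network inference** — the compact three-pathway MLP
  (200/100/1 ReLU nodes per output) on the phase-aligned, normalized rank-10
  signal, trained with MAPE loss and SGD; the PD formula above is applied
  outside the network, so `pd · θ₃ = ||x||₂` holds exactly;
* **spiral acquisition + reconstruction** — golden-angle variable-density
  spiral sampling simulated through an exact non-uniform Fourier operator,
  reconstructed by density-compensated zero-filling, temporal view-sharing,
  or iterative low-rank + total-variation (LRTV) compressed sensing;
* **contrast synthesis** — voxelwise SPGR / spin-echo / FLAIR signal
  equations applied to the quantitative maps;
* **digital tumor phantom + ROI analysis** — a seeded brain-tumor phantom
  drawing per-tissue (T1, T2) from published cohort statistics, ROI
  mean/std tables, and a two-component Gaussian mixture in the T1-T2 plane
  that splits necrotic/non-enhancing tumor into solid-like (core I) and
  fluid-like (core II) voxels with back-projection to the volume.

## Worked example

Simulate a noiseless voxel at the necrotic/non-enhancing core I cohort mean
(T1 = 1550 ms, T2 = 92 ms), compress it to the rank-10 subspace, and match it
against a dictionary; then fit the two-component T1-T2 mixture to simulated
core I + core II voxels:

```r
library(qtimap)

sched <- default_schedule()                  # 880 ramped flip angles
grid  <- build_grid(t1_values_ms = seq(100, 3000, by = 50),
                    t2_values_ms = seq(10, 300, by = 5))
dict  <- build_dictionary(grid, sched)       # unit-norm EPG atoms
basis <- compute_subspace(dict, rank = 10)   # temporal SVD basis
dict  <- compress_dictionary(dict, basis)

sig <- simulate_signal(qti_tissue(t1_ms = 1550, t2_ms = 92), sched)
match_signal(compress_signal(sig, basis), dict)[c("t1_ms", "t2_ms", "pd", "correlation")]
#> $t1_ms
#> [1] 1550
#>
#> $t2_ms
#> [1] 90
#>
#> $pd
#> [1] 1.012254
#>
#> $correlation
#> [1] 0.9999803
```

The matched atom returns the generating T1 exactly (1550 ms is on the grid);
the generating T2 of 92 ms falls between the 5-ms grid steps and snaps to the
nearest atom at 90 ms, which also accounts for the proton density of 1.01
instead of exactly 1 and a correlation marginally below 1. On-grid signals
match with correlation 1 and PD 1 to machine precision (that identity is part
of the test suite).

```r
tissues <- default_tissues(); rownames(tissues) <- tissues$name
set.seed(1)
draw <- function(row, n = 2000) cbind(
  rnorm(n, tissues[row, "t1_mean"], tissues[row, "t1_std"]),
  rnorm(n, tissues[row, "t2_mean"], tissues[row, "t2_std"]))
fit_t1t2_gmm(rbind(draw("core_I"), draw("core_II")), k = 2, seed = 1)
#> T1-T2 Gaussian mixture, k = 2 (loglik -5.302e+04, 28 EM iterations)
#>   component 1: weight 0.503, mean T1 1550 ms, mean T2 93 ms
#>   component 2: weight 0.497, mean T1 2184 ms, mean T2 296 ms
```

Component 1 recovers the solid-like core I distribution (1550 ms, 92 ms) and
component 2 the fluid-like core II (2188 ms, 297 ms); the mixture separates
the two tumor-core populations from their pooled (T1, T2) scatter alone.

The full pipeline (phantom → acquisition → reconstruction → inference →
synthesis → analysis) runs from one configuration:

```r
cfg <- default_config(seed = 1)
qti_run(cfg, out_dir = "qti_demo", verbose = TRUE)
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/qti.R run --seed 1 --out qti_demo
```

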