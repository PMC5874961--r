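# smcproton

Dose calculation for scanned proton pencil beams in voxelized phantoms, built
around a **simplified Monte Carlo (SMC)** transport engine.

Treatment planning for proton pencil beam scanning needs a 3D dose kernel per
beam spot. Analytical pencil beam algorithms (PBA) are fast but consider the
patient only along each spot's straight central axis, so they mis-predict dose
wherever density varies *across* the beam (bone/air/lung interfaces). Full
Monte Carlo resolves this but is far too slow for routine kernel generation.
The SMC model sits in between: it tracks individual protons through the voxel
grid with Gaussian multiple-Coulomb-scattering kicks (Highland
parameterization), but replaces all energy-loss physics with a lookup into a
measured depth-dose curve in water at the proton's accumulated
water-equivalent depth

    w  <-  w + dz * rsp(voxel) * sqrt(1 + theta_x^2 + theta_y^2),

depositing the curve integral over `[w, w + dw]` in each traversed voxel and
kicking the projection angles with rms

    theta_0(w) = (14.1 MeV / pv) * sqrt(w / X0) * (1 + log10(w / X0) / 9),

applied as differences in quadrature so the angular spread is independent of
the step size. Nuclear reactions, straggling and secondaries enter only
through the measured curve. The package is aimed at medical-physics
researchers who want a transparent, testable implementation of this model
together with everything needed to quantify its planning consequences:

* **phantoms** — water tanks, slab heterogeneities, the bone/lung benchmark,
  CT-to-stopping-power calibration, exact ray water-equivalent path lengths;
* **beam model** — effective Gaussian source per binary range-shifter setting
  (bundled table of measured-style parameters), spot sampling, PMMA
  water-equivalent bookkeeping;
* **engines** — the SMC transport core (C++), and the analytical PBA
  comparator with Fermi–Eyges lateral spread and optional 121-subspot
  decomposition;
* **planning** — SFUD spot grids (12 mm lattice / 5 mm WED layers),
  nonnegative spot-weight optimization, cross-engine recalculation;
* **analysis** — laterally integrated depth dose, rms relative dose
  difference, DVH / D95, gamma index (3%/3 mm), isodose difference reports.

## Worked example: the heterogeneity benchmark

The classic stress case for pencil-beam dose calculation: two 10×20×50 mm
blocks — bone-like (rsp 1.46) and lung-like (rsp 0.217) — side by side in a
300×300×400 mm water tank at 150 mm depth, with the block interface exactly
on the beam axis. A single pencil beam (206 MeV, 2 mm range shifter, pristine
curve peaking at 257.5 mm in water) is transported with 10^5 protons:

```r
library(smcproton)
res <- run_benchmark(benchmark_config(n_protons = 1e5, seed = 42))
res$peaks
#>       z      dose
#> 1 234.5 0.5293159
#> 2 257.5 0.5122756
#> 3 296.5 0.2539021
```

The laterally integrated depth dose splits into three Bragg peaks: protons
through the bone block stop 23 mm early (234.5 mm), protons missing both
blocks peak at the water depth (257.5 mm), and protons through the
low-density lung block overshoot to 296.5 mm. An analytical PBA kernel for
the same spot is mirror-symmetric about the axis by construction and cannot
produce this asymmetry — `run_benchmark(benchmark_config(with_pba = TRUE))`
writes the side-by-side isodose difference report.

The planning consequence is reproduced by `run_plan()`: on a slab phantom it
computes kernels with both engines, optimizes SFUD spot weights with each,
and reports D95/D5 for the analytically planned dose (`pba_tp`), its Monte
Carlo recalculation (`smc_recalc`), and direct Monte Carlo planning
(`smc_tp`) — recalculation reveals the wide PTV dose spread the analytical
plan hides, while planning on SMC kernels restores homogeneity.

## Not in scope

No condensed-history/full Monte Carlo comparator, no nuclear-halo or
double-Gaussian lateral model, no absolute dosimetry (kernels are per-proton
relative dose), no DICOM-RT export, no GPU path. Fields are modeled along
the grid z-axis; clinical gantry geometry is out of scope.
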