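---
title: "Simplified Monte Carlo dose kernels for scanned proton beams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified Monte Carlo dose kernels for scanned proton beams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smcproton)
```

## The problem

Pencil beam scanning (PBS) delivers proton therapy as a weighted sum of
thousands of narrow beam spots. The planning system needs, for every spot, a
3D *dose kernel* — the dose per unit spot intensity in the patient — and then
optimizes the spot weights so the summed dose matches the prescription.
Analytical pencil beam algorithms (PBA) compute kernels quickly but see the
patient only along each spot's straight central axis: lateral heterogeneity
(bone next to an air cavity, a tumor at a lung interface) is invisible to
them, and the resulting weight sets can deliver badly inhomogeneous dose.
Full Monte Carlo transport resolves this but is orders of magnitude too slow
for routine kernel generation.

`smcproton` implements the intermediate model: a *simplified Monte Carlo*
(SMC) engine that tracks individual protons through the voxelized patient
with multiple-Coulomb-scattering kicks, but replaces all energy-loss physics
with a lookup into a measured (or analytically generated) depth-dose curve
in water via the water-equivalent depth. The package also provides the PBA
comparator, SFUD (single-field uniform dose) spot-weight optimization, and
the evaluation toolkit (laterally integrated depth dose, rms relative dose
difference, DVH/D95, gamma index) needed to quantify what planning on
analytical kernels costs in heterogeneous anatomy.

## The transport model

Each proton carries a state `(x, y, z, theta_x, theta_y, w)` where the
projection angles are small-angle slopes against the beam axis (+z) and `w`
is the accumulated water-equivalent depth. Per z-step of one voxel:

1. the water-equivalent step is `dw = dz * rsp * sqrt(1 + tx^2 + ty^2)`,
   with `rsp` the relative stopping power of the voxel containing the step
   midpoint;
2. the deposit is the integral of the depth-dose curve over `[w, w + dw]`,
   scored in that voxel ("dose in water-equivalent": no division by local
   density);
3. the angles receive independent Gaussian kicks whose rms follows the
   Highland parameterization
   `theta0(w) = (14.1 MeV / pv) * sqrt(w / X0) * (1 + log10(w / X0) / 9)`
   with `X0 = 360.8` mm (water) and the logarithmic factor floored at 0;
4. the proton terminates when `w` reaches the curve's nominal range or when
   it leaves the grid laterally (remaining dose is lost, as in a finite
   phantom).

Because the depth-dose curve is a *measured* laterally integrated curve, it
implicitly carries range straggling, nuclear attenuation of the primary
fluence and secondary-particle buildup on average — none of these are
sampled explicitly. That single simplification is what makes the method
three orders of magnitude faster than a general-purpose Monte Carlo while
retaining per-proton sensitivity to lateral heterogeneity.

Two numerical choices deserve emphasis:

* **Step-size independence of scattering.** A naive per-step Highland kick
  depends on the step length. The engine instead telescopes: the per-step
  kick variance is the difference of cumulative Highland variances,
  `theta_step^2 = theta0^2(w + dw) - theta0^2(w)`, evaluated at the current
  pv. Summed over any partition of `[0, W]` this reproduces `theta0(W)^2`
  exactly (asserted in the tests), so refining the grid does not change the
  angular spread.
* **pv from residual range.** The kinematic factor is obtained by inverting
  the power-law range-energy relation `R = alpha * E^p` (default
  `p = 1.77`; `alpha` calibrated so the range at the nominal beam energy
  equals the curve's nominal range) and `pv = E(E + 2m)/(E + m)`. Residual
  range and accumulated depth are tied by `r = nominal_range - w`.

Near the very end of range `pv -> 0` and the Highland expression diverges;
the per-step kick rms is capped at 0.1 rad and the projection angles are
clamped to ±0.3 rad (the validity bound of the small-angle transport).
Both limits act only within the last millimeter of residual range, where the
remaining dose is negligible.

## Beam model

The beamline, including the binary PMMA range shifter (0–127 mm in 1 mm
steps, water-equivalent ratio 1.16), is summarized by an *effective source*
per range-shifter setting: Gaussian spatial spreads `sigma_x, sigma_y` (mm)
and angular spreads `sigma_tx, sigma_ty` (mrad) at per-axis effective source
planes located `L_x, L_y` (mm) upstream of the isocenter. The bundled
`default_source_table()` holds the four tabulated settings (2, 32, 64,
96 mm); intermediate settings interpolate linearly and extrapolation is
refused.

Position and angle are sampled independently (the tabulation lists no
covariance; all downstream correlation arises from drift), each spot is a
parallel-shifted aiming ray through its isocenter position, and the drift
from source plane to phantom entrance is ballistic vacuum (no air
scattering). The isocenter is placed at the phantom entrance face. The range
shifter plays two separate roles: its scattering is already inside the
per-setting source parameters, while its energy loss is applied as an
initial water-equivalent offset `rs_wet(t) = 1.16 t`. When the depth-dose
curve was itself acquired downstream of the shifter (the configuration of
the heterogeneity benchmark, whose curve is calibrated to peak at a stated
depth *in the phantom's water*), the offset must not be applied twice:
`compute_kernel(..., rs_in_curve = TRUE)` declares that the curve already
contains it.

## Depth-dose curves

`make_bragg_curve()` generates the pristine curve as a cell-averaged
power-law stopping profile `(R - z)^(1/p - 1)` convolved with a Gaussian
range-straggling kernel. The nominal position `R` is calibrated iteratively
so that the *convolved* curve peaks at the requested depth to within one
grid step (asserted for peaks between 50 and 300 mm). Defaults: straggling
sigma 1.2% of the peak depth (a realistic fractional range spread for
therapeutic protons); tabulation step 0.5 mm, which bounds the linear
interpolation error in the steep distal falloff; total integral normalized
to 100 arbitrary units so integrated quantities are independent of the
tabulation step. Measured curves load from two-column CSV.

## The analytical comparator (PBA)

The PBA kernel accumulates water-equivalent depth on the spot's straight
central axis only, deposits the same curve integral per slab, and spreads it
laterally as a product of normalized Gaussians whose variance is the drifted
source contribution plus the Fermi–Eyges multiple-scattering integral
`sigma_mcs^2(z) = sum (z - u)^2 dtheta0^2(u)` accumulated with the *same*
Highland scattering power as the SMC engine. In homogeneous water the two
engines therefore share one closed-form lateral model — the acceptance tests
exploit this (rms kernel difference below 2% of the maximum) — while in
heterogeneous media the PBA kernel stays exactly mirror-symmetric about its
axis whatever the phantom, which is precisely its clinical limitation.

Optional subspot decomposition splits the source spatial Gaussian into an
11×11 grid of parallel axes over ±3 sigma with product-Gaussian weights
(the conventional 121-subspot refinement); each subspot sees its own column
of the phantom, partially restoring lateral heterogeneity response. Whether
subspot weights should be Gaussian-quadrature or fluence-area splitting is
an open choice; the Gaussian-weight grid was adopted and the cell-width
variance `h^2/12` is added so the decomposed second moment matches the
source.

## SFUD planning

`generate_spot_grid()` lays spots on a 12 mm lateral lattice (anchored at
the footprint minimum corner, plus margin) and 5 mm water-equivalent-depth
layers spanning the target's WED extent — the standard PBS spot geometry for
a large-spot beamline. Each layer is realized by the binary range shifter:
`rs = round((peak_wed - layer_wed)/1.16)`, so one pristine curve serves all
layers. Spot weights minimize a quadratic uniformity objective over the PTV
with optional one-sided OAR overdose penalties and a ridge term, subject to
nonnegativity, solved by a monotone accelerated projected-gradient method
(objective never increases; relative tolerance 1e-6, at most 5000
iterations; initialized at the uniform weight that matches the mean PTV
dose). Tiny systems are verified against an exhaustive active-set
enumeration oracle.

The three-way comparison the package automates (`run_plan()`):
**pba_tp** (PBA kernels, PBA-optimized weights — what the analytical
planner believes), **smc_recalc** (SMC kernels, the same weights — what
that plan actually delivers), and **smc_tp** (SMC kernels, SMC-optimized
weights). On laterally heterogeneous phantoms the recalculated PTV dose
spread (D5 − D95) is markedly wider than the directly optimized one; in
water all three agree.

## What the synthetic phantoms emulate — and what they do not

The generators produce the study conditions: a 300×300×400 mm water tank at
1 mm voxels; the benchmark heterogeneity (10×20×50 mm bone and lung blocks
side by side at 150 mm depth, interface on the beam axis — the hardest case
for a pencil beam algorithm) with stopping powers 1.46 and 0.217 fixed by
the printed Bragg-peak depths (the 23 mm bone shift over a 50 mm slab and
lung rsp close to its density); and scaled planning phantoms. A CT-number
volume can be converted through a piecewise-linear calibration table, but
the bundled table is a stylized placeholder — supply the scanner-specific
calibration for real data.

Passing tests on these phantoms demonstrate the transport, planning and
analysis machinery under controlled heterogeneity. They do not demonstrate
clinical accuracy: real CT anatomy has continuous heterogeneity, the
engine's nuclear-halo and scattering approximations are only checkable
against a full Monte Carlo (out of scope here), and the published clinical
D95 values require patient CTs. Known physics limitations inherited from
the model: no nuclear-interaction lateral halo (a percent-level low-dose
tail near the peak), a single-Gaussian lateral model, and an overestimated
lateral spread behind the Bragg peak relative to condensed-history Monte
Carlo (the Highland and detailed MCS models differ by roughly 15% there).

## Problem sizes and statistics

Kernel statistics scale with available time. The package's own validation
uses: 1e5 protons for the heterogeneity benchmark (peak positions are
stable well below that), 1e6 protons for the water self-consistency and
lateral-spread checks (rms and second-moment tolerances of 1% and 5%), and
3e4 (water) / 6e3 (heterogeneous) protons per kernel for the planning
studies, where ~300–800 kernels enter each optimization and only DVH-level
statistics are asserted. Full-fidelity kernel generation uses 1e6 protons
per spot. The Monte Carlo statistical error of a plan can be estimated with
`estimate_statistical_error()` (batch method); it scales as `1/sqrt(n)`.

## Reproducibility

All stochastic stages consume R's RNG: a seed fixes the sampled ensembles
bit-for-bit (scattering kicks draw Box–Muller pairs from the same stream),
per-spot seeds derive from the base seed via `spot_seed()`, and
`run_benchmark()` / `run_plan()` write manifests with the configuration and
seeds needed to reproduce their outputs identically.
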