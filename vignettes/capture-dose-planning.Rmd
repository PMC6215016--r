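---
title: "Planning thermal neutron capture dose enhancement for ion therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning thermal neutron capture dose enhancement for ion therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captureplan)
```

## The problem

During proton or carbon ion therapy, nonelastic nuclear collisions near the
Bragg peak release neutrons that thermalise in tissue around the beam path.
A tumour loaded with a boron-10 or gadolinium-157 capture agent converts
part of that thermal fluence into additional high-LET dose, preferentially
in the tumour because uptake is tumour-selective. The quantitative
feasibility question has three parts:

1. how much thermal neutron fluence does a realistic treatment plan
   deposit in its own target volume, per GyE of planned dose;
2. what agent concentration converts that fluence into a worthwhile boost
   (here 10% of a 1 GyE target dose);
3. how much extra dose does normal tissue receive, given the agent's
   tumour:normal concentration ratio and its normal-tissue effectiveness.

`captureplan` implements this chain end to end. Parts 2 and 3 are exact
arithmetic on published constants and can be replayed from printed fluence
statistics (the *tables-only path*). Part 1 requires particle transport;
the package replaces it with a calibrated analytic beam model so that the
whole pipeline runs on a desk in seconds rather than cluster-days, at the
cost of absolute fluence fidelity (discussed under *Limitations*).

## The synthetic beam model

Each pencil-beam kernel lives on an isotropic voxel grid over a 250 mm
PMMA cube (default 2.5 mm voxels, `grid_spec()`), with depth z along the
beam. Dose and fluence are intensive per-primary fields sampled at voxel
centres.

**Range.** Ion range follows the Bragg–Kleeman power law R = a·Eᵖ, fitted
by log-log least squares to four reference (energy, Bragg depth) pairs per
species (`reference_beam_points()`, `fit_range_energy()`). The fits
reproduce every reference depth to within 1.4 mm (well inside the 2 mm the
calibration data justify) and give p ≈ 1.77 (proton) and 1.71 (carbon).

**Depth dose.** The pristine curve is built from the stopping-power shape
(R − z)^(1/p − 1), smeared by a Gaussian range-straggling kernel whose
width grows with range (σ = max(1.2, 0.014·R) mm for protons,
max(0.8, 0.009·R) for carbon), then monotonically rescaled so the
peak:entrance dose ratio equals a configurable constant (4 for protons, 6
for pristine carbon — typical clinical magnitudes). Carbon additionally
gets a small exponential fragmentation tail (12% of entrance dose just
beyond the peak, 40 mm decay). The smeared maximum is re-anchored exactly
at R, so a kernel's located Bragg peak always matches the range-energy
curve to within one voxel. Entrance dose on the axis is 4 × 10⁻¹⁰
Gy/primary (proton) and 5 × 10⁻⁹ (carbon); only the product of dose scale
and neutron yield affects any reported per-GyE quantity.

**Lateral profile.** A rotationally symmetric Gaussian of 5 mm FWHM at all
depths. Energy-dependent lateral widening is deliberately out of scope.

**Neutron channel.** Thermal fluence (neutrons below 0.4 eV; the synthetic
model produces only this component) is modelled as an isotropic
exponential falloff, scale 50 mm, centred on the axis at 80% of the Bragg
depth — a broad, peak-centred cloud matching the qualitative behaviour of
transport calculations. The field is normalised so that the in-phantom
track-length integral Σ φᵢ ΔVᵢ equals a per-primary yield constant. The
yields (19.7 n·cm proton, 212 carbon) were calibrated once so that the two
default 100–150 mm plans reproduce reference Monte Carlo mean in-target
fluences per GyE (7.79 × 10⁸ and 3.34 × 10⁸ n/cm²/GyE); they are model
constants, fixed before the test suite was finalised and not revisited.

**Counting noise.** `add_counting_noise()` draws each voxel independently
from a Poisson law with one event per primary allocated proportionally to
the voxel's share of the channel total, so a voxel's relative SD is
1/√(N × share) — the statistics that make the run-count variance analysis
(`determine_min_primaries()`) meaningful. For expected counts above 10⁸
the Gaussian limit is drawn instead. The variance procedure's region of
interest defaults to a 10 mm cube centred on the Bragg peak (the reference
procedure leaves its size unspecified; it is configurable), and noise is
realised only inside the ROI, which is statistically identical to
realising the full grid because the thinning is voxelwise independent.

## The kernel library

Intermediate energies are interpolated with the peak-aligned procedure:
translate the bracketing reference kernels along depth so their peaks
coincide with the highest-energy peak, blend voxelwise linearly in energy,
and translate the blend to the target depth. Three decisions deserve note:

* *Depth curve.* "Second-order polynomial interpolation" through four
  points is overdetermined, so the depth curve is piecewise local
  quadratics — the quadratic through the three lowest references on the
  first interval, through the three highest on the last, and a linear
  blend of the two on the middle interval. This is continuous and exact at
  every reference energy, which the identity tests rely on.
* *Energy blending.* Linear between the two bracketing references. Whether
  a global four-point scheme would be preferable is unknowable from the
  reference description; pairwise-linear is recorded as this package's
  choice, and higher-order schemes are out of scope.
* *Sub-voxel shifts.* Linear resampling along depth with zero fill
  (`shift_axis()`); a nearest-voxel mode exists behind a flag. Aligning
  translations move content away from the entry face and lose under 1% of
  the dose integral; the translation *back* to a shallower depth clips the
  portion of the deeper reference's entrance plateau that would sit
  upstream of the phantom surface, which is the physically sensible
  behaviour and keeps total dose continuous (< 5% change) between adjacent
  1 MeV/u entries.

Querying a reference energy returns the stored kernel bit-identically.

## RBE weighting

Protons use a constant RBE of 1.1. Carbon pencil beams receive a peak RBE
set by their Bragg depth's position in the SOBP — 2.5 at the proximal
edge, 3.0 at the centre, 3.3 at the distal edge, piecewise linear through
the three anchors and clamped outside (a single linear segment between 2.5
and 3.3 would give 2.9 at the centre and contradict the stated centre
value). Voxels with laterally-integrated dose below 60% of the beam's
maximum, proximal to the peak, get the entrance-plateau value 1.5; between
the 60% depth and the peak the RBE ramps linearly in depth — the only
continuous rule consistent with both the plateau and peak specifications.
Distal to the peak the RBE is held at the peak value by default
(`distal_mode = "hold"`), since fragmentation-tail effectiveness is
unspecified; a `"plateau"` mode that falls back to 1.5 below the 60%
threshold is available. RBE is applied per energy layer *before* weight
optimisation, so the optimiser works on BEDₖ maps directly.

## Plan optimisation

Each layer's BED and fluence maps are averaged over the R × C transverse
spot grid (11 × 11 at 5 mm, matching the beam FWHM, spanning the 50 mm
treatment plane). Because the spots form a product grid the average is
computed separably in x and y. The energy layers are those whose
interpolated Bragg depth falls inside the volume's depth range, at a
1 MeV/u step by default (a 6 MeV/u preset mirrors coarser published
plans, at the price of visible depth scalloping for carbon's narrow
peaks).

The per-energy primary counts minimise ‖Σ Nₖ BEDₖ − D‖² over in-volume
voxels subject to Nₖ ≥ 0. The solver is exact active-set non-negative
least squares (`pracma::lsqnonneg`) rather than a damped gradient method:
the objective is a convex quadratic, so the optimum is identical, and the
active-set solution is deterministic with nothing to seed. Afterwards the
weights are rescaled so the in-volume mean BED is exactly D — the raw
optimised mean is recorded separately (`mean_bed_raw`) — and all
fluence-per-GyE statistics refer to the rescaled plan. With default
settings both species deliver mean BED within 0.1% of target with an
in-volume coefficient of variation of about 0.5%.

One geometric caveat the test suite enforces: the spot grid must span the
volume's lateral extent ((R−1) × spacing ≳ lateral size). An
under-covering grid leaves the lateral rim underdosed and no energy
weighting can repair it.

## Capture-agent arithmetic

The boost dose is D_B = φ σ_NCA N_NCA × CBE with σ_NCA the
fluence-to-kerma factor per ppm (8.66 × 10⁻¹⁴ Gy cm² for ¹⁰B,
9.27 × 10⁻¹⁵ for ¹⁵⁷Gd). The reference fluence φ is the *mean* in-volume
fluence per GyE — this choice, and no other statistic, reproduces the
published concentration tables exactly. Required concentrations are
reported unrounded and at 3 significant figures. The normal-tissue dose
increase is 100 · f · (CBE_N/CBE_T) · (φ_margin/φ_ref) / ratio with the
margin-to-reference fluence ratio defaulting to 1 (the fluence at the
treatment-volume margin is taken equal to the in-volume mean; the exact
margin location used in reference calculations is unstated, and the
published liver values sit about 2% from this formula).

Agent constants live in `inst/extdata/nc_agents.csv`. The BSH-brain row is
excluded from default normal-tissue reports (`in_default_report = FALSE`)
because its published uptake ratio is a range (1.2–3.5:1) rather than a
single value; with the lower bound the formula gives 2.57%, close to but
not exactly the published 2.60%. The gadolinium rows carry equal tumour
and normal CBE and a 70:1 uptake ratio, so all scenarios collapse to a
single normal-tissue figure (0.14%). A CBE ≈ 40 DOTA-gadolinium entry is
stored for reference but not reported by default, since the published
concentration scenarios use CBE 1.5–20.

## Numerical choices and degenerate inputs

* Ties in the Bragg-peak search break towards the shallower depth.
* A degenerate SOBP (proximal = distal) assigns every carbon beam the
  centre RBE 3.0.
* All-zero dose grids, empty treatment volumes, non-monotone range
  calibration points, rank-zero BED stacks and mismatched weight/map
  lengths are rejected with informative errors; the variance procedure
  reports its whole SD/mean trajectory on non-convergence.
* Far lateral Gaussian tails underflow to subnormal doubles; consumers
  comparing voxelwise ratios should ignore voxels below ~10⁻¹² of the
  maximum.
* Kernels persist as NIfTI volumes (via `RNifti`) with a JSON sidecar for
  species, energy, Bragg depth, units and seed; NIfTI is the voxel-volume
  format with first-class R support.

## Problem sizes

The default grid is 100³ voxels (2.5 mm over 250 mm), balancing the 5 mm
beam FWHM against memory; plans use 33 (proton) or 66 (carbon) energy
layers for the shallow volume and run in roughly half a minute and a
minute and a half respectively. Unit tests run on 40³ and 10³ grids, which
exercise every code path at a fraction of the cost.

## What the synthetic model does and does not show

Passing tests demonstrate that the *procedures* — interpolation, RBE
weighting, NNLS weighting, fluence accumulation, variance analysis, and
all concentration arithmetic — behave as specified, and that the analytic
beam model is internally consistent (ranges on the calibration curve, flat
SOBPs, 1/√N noise). They do not validate transport physics: absolute
fluence levels are calibrated, not predicted; there is no fast-neutron or
photon component, no heterogeneous anatomy, no energy-dependent lateral
scattering, and no dose-dependence of RBE. Published absolute fluences
from 5 × 10⁷-primary transport runs are matched only at the ±20%
calibration level, which is why every exactly-reproducible number flows
through the tables-only path and why the package reports both paths
separately.
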