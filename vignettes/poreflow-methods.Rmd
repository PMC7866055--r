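---
title: "Methods: collective-diffusion permeability and companion trajectory analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective-diffusion permeability and companion trajectory analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poreflow` post-processes MD trajectories of membrane-protein pores.
This vignette records the models the package implements, the choices
made where the methodology is genuinely open, and what the synthetic
validation systems do and do not establish about real data.

## The collective-diffusion model

Single-channel osmotic permeability cannot be measured from
equilibrium water flux directly — in equilibrium the net flux is zero.
The collective-diffusion approach instead maps all axial water motion
inside the pore onto one dimensionless coordinate

$$n(t+\Delta t) = n(t) + \sum_{i \in S(t,\,t+\Delta t)}
  \frac{\Delta \mathbf r_i \cdot \mathbf e}{L},$$

where $S$ is the set of waters inside the pore cylinder at either end
of the frame pair, $\mathbf e$ the unit axis and $L$ the pore length.
In equilibrium $n(t)$ diffuses; its diffusion coefficient $D_n$ gives
the osmotic permeability $P_f = v_w D_n$. The chain of definitions and
choices:

* **Pore geometry.** The cylinder runs between the mass centres of a
  bottom and a top ring of Cα atoms, recomputed per frame. Under the
  Cα position restraints typically applied during permeability runs
  the region is effectively static; per-frame recomputation is the
  superset behaviour and reduces to it. Presets ship for the two UCP2
  model variants (rings of six Cα for the NMR-based model, five for
  the homology model; radius 2 nm, chosen to enclose all pore waters).
* **Membership and clipping.** A water belongs to $S$ if its tracking
  point (oxygen or COM) lies inside the cylinder — axial coordinate in
  $[0, L]$ *and* radial distance ≤ r — at frame $t$ or $t+\Delta t$.
  The axial displacement of entering/exiting molecules is clipped to
  the fraction of the straight inter-frame segment whose axial
  coordinate lies in $[0, L]$ (equivalently,
  $\mathrm{clamp}(a_1) - \mathrm{clamp}(a_0)$), so clipped segments are
  additive under path refinement and the scripted-path refinement test
  closes to within 2%. Radial excursions within a step are *not*
  clipped: the radius is deliberately generous, and a radial clipping
  rule would add an unobservable parameter.
* **The fit.** The series is cut into disjoint consecutive blocks
  (default 100 blocks of 50 ps, which tiles a 5 ns analysis window
  exactly), each re-zeroed, and $\mathrm{MSD}(\tau)$ fitted through the
  origin over $\tau \in (0, \tau_\max]$; $D_n$ is half the slope. The
  mean-squared statistic $\langle n(\tau)^2\rangle$ is the default; the
  squared-mean variant $\langle n(\tau)\rangle^2$ — which appears in
  some method descriptions but estimates the variance of the block
  mean, smaller by the block count — is exposed as
  `fit_Dn(estimator = "square_mean")` so both readings are available.
  Standard errors come from a 200-resample bootstrap over blocks under
  a fixed seed.
* **Units and constants.** $D_n$ is converted from ps⁻¹ to s⁻¹
  explicitly. $v_w$ defaults to $18.015\,/\,(0.997 \cdot N_A)$ =
  2.99×10⁻²³ cm³ (liquid water at 0.997 g/cm³). The final value is
  divided by 2.87 to correct the low shear viscosity of TIP3P-like
  water models; set `viscosity_scale = 1` to disable.

For $N$ non-interacting waters diffusing with coefficient $D$ inside a
channel of length $L$, $D_n = \bar N D / L^2$ exactly. This identity is
the package's primary oracle: the synthetic open pore recovers it
within statistical error, and the same occupancy predicts the two-way
tracer crossing rate $2 \bar N D / L^2$ observed by the independent
crossing counter.

## The synthetic systems: what they emulate, and what they do not

The generator (`synthetic_spec()` + `make_*_system()`) produces
trajectories whose statistics match the assumptions of each analysis
stage, with closed-form ground truth:

* **Pore systems** place single-bead waters (one tracking point per
  molecule, matching how the analyses count molecules) in a box with a
  reflecting membrane slab pierced by a cylindrical channel. Steps are
  Gaussian with per-axis variance $2 D \Delta t$; the channel wall
  reflects radially, the slab faces reflect axially, and the `barrier`
  variant adds a reflecting mid-plane that forbids traversal. Defaults
  mirror the permeability protocol: frames every 0.5 ps, 5 ns span
  (10001 frames), $L = 2$ nm, $D = 2.3\times10^{-3}$ nm²/ps (a
  TIP3P-like value), and a water count giving mean channel occupancy
  ≈ 10 under the uniform stationary density.
* **Salt-bridge systems** realize a two-state telegraph process (rates
  `k_on`, `k_off` per ps) between a bound (0.45 nm) and an unbound
  (0.95 nm) COM separation with 0.05 nm Gaussian noise, as explicit
  3-atom residues. The stationary occupancy $k_{on}/(k_{on}+k_{off})$
  is exact. Bound/unbound plateaus follow the distance ranges typical
  of formed (≈0.4–0.5 nm) and broken (>0.8 nm) bridges, which is also
  why the formed/broken threshold defaults to 0.6 nm — it bisects the
  gap. Occupancy recovery is tested against
  $\mathrm{SE} = \sqrt{p(1-p)/n_\mathrm{eff}}$ with
  $n_\mathrm{eff} = T(k_{on}+k_{off})/2$: telegraph frames are
  autocorrelated, so the per-frame binomial SE would be far too tight
  for slow rates.
* **Binding systems** tether a bead chain (default 20 beads, the
  carbon count of arachidonic acid) at a controlled distance from a
  static site residue; the contact ground truth is an exhaustive
  pairwise recount on the generated coordinates.

These systems validate the *estimators*, not the physics of real
water: there are no water–water interactions, no electrostatics, no
lipids, and the "membrane" is a hard wall. A passing recovery test
therefore certifies that the pipeline measures what it claims to
measure on data satisfying its assumptions — it does not certify
force-field-level realism, and absolute permeabilities of real proteins
remain a property of the input trajectories.

## The closed/open contrast experiment

A blocked pore at equal water occupancy is *not* distinguishable from
an open one on short observation windows: each half of the blocked
channel still exchanges water with its bulk reservoir, so the
collective coordinate fluctuates freely until it saturates at its
stationary variance ($\mathrm{MSD}_\infty \approx \bar N/6$ in pore
units), on the timescale of the $(L/2)^2/2D \approx 200$ ps
relaxation. Through-origin fitting of a saturated MSD gives
$D_n^{closed} \approx \bar N / (8\tau_\max)$, hence a contrast ratio of
roughly $8 D \tau_\max / L^2$ — independent of occupancy. Resolving a
hundred-fold contrast therefore requires $\tau_\max \gg L^2/ (8D)$: the
contrast experiment uses 1 µs trajectories sampled every 5 ps and 20
fit windows of 50 ns, for a predicted ratio well above 100, while the
open-pore *recovery* experiment keeps the reference 100 × 50 ps
protocol. Crossing counts provide the complementary hard signature:
the reflecting barrier yields exactly zero traversals at any length.

## Numerical and algorithmic choices

* **Superposition** is weighted Kabsch via SVD with reflection
  correction; mass weighting is the default everywhere (the MD-engine
  convention), switchable per call. Collinear references are rejected.
* **RMSF** superposes onto the iterated mean structure (re-averaged
  until the mean moves < 10⁻⁶ nm) rather than frame 0; the frame-0
  reference remains available. **Common PCA** pools all frames of all
  trajectories, superposes onto the pooled iterated mean, and
  diagonalizes the 3N covariance — the only construction under which
  projections of different simulations share axes. Span areas are
  convex hulls: parameter-free, unlike density contours.
* **RMSD reference** defaults to the first trajectory frame
  (configurable): with no universally agreed choice, the first frame
  is reproducible from the trajectory alone.
* **Minimum image** is applied to COM differences and inter-frame
  displacements under orthorhombic boxes only; triclinic input is
  rejected explicitly rather than mishandled. Residue COMs assume
  molecules are whole (not split across the boundary).
* **Crossing events** use two-plane hysteresis with lateral gating: a
  molecule must pass from beyond one plane to beyond the other while
  staying within the gating radius during the traversal. Boundary
  jitter and aborted entries count nothing; a below↔above transition
  with no visit between the planes is ignored because it is
  indistinguishable from a path around the periodic boundary.
* **Occupancy maps** are per-voxel presence fractions in [0, 1],
  matching isovalues such as 0.2; channel continuity is 6-neighbour
  connectivity touching both z faces.
* **Replica ensembles** default to analyzing the last half of each
  replica (the 20 ns / last-10 ns convention); across-replica spread
  is the sample SD (n−1), stated in the output metadata.
* **Determinism.** One seed governs generation and bootstrap; derived
  stage seeds are deterministic, and a pipeline run embeds its
  resolved configuration in `report.json` so it can be reproduced
  bit for bit.

## Problem sizes

The test suite runs ~100-atom systems: 10001-frame pore recoveries
(five seeds), one 2 × 200001-frame contrast pair, 10⁴-frame telegraph
grids, 5000-frame PCA ensembles, and scripted few-molecule cases for
the exact oracles. These sizes put every statistical check at ≥ 3
standard errors of resolution while keeping the full suite and the
acceptance script each within a few minutes on one CPU core.

## Known limitations

* XTC trajectories are not read; DCD, GRO and multi-frame PDB are.
  DCD output carries no unit cell or times, so the box and frame
  spacing come from the caller.
* Selections support name/resname/resid/water algebra, not distance-
  based or within-style selections.
* The density profile's "inside the protein" region is a configurable
  cylinder (default radius 2 nm about the chosen axis), consistent
  with the permeability region — a protein-surface-conforming region
  is out of scope.
* Salt-bridge occupancy uses a plain per-frame threshold without
  hysteresis; kinetic quantities (on/off rates from distance series)
  are not estimated.
* All analyses assume orthorhombic periodic boxes and whole molecules.
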