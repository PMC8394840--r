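---
title: "A cellular Potts model of alpha-particle dose response in 2D and 3D tumor models"
author: "bnctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cellular Potts model of alpha-particle dose response in 2D and 3D tumor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bnctsim)
```

## The model

`bnctsim` simulates the multicellular response to boron neutron capture
therapy (BNCT) on a lattice. Three coupled pieces run per Monte Carlo step
(MCS):

1. **Cellular Potts dynamics.** Each biological cell is the set of voxels
   carrying its id; one MCS performs `nx*ny*nz` copy attempts. An attempt
   copies a random neighbor's id onto a random voxel and is accepted with the
   Metropolis rule at temperature `T` applied to the Hamiltonian
   $$H=\sum_{\langle a,b\rangle} J(k_a,k_b)\,[id_a\neq id_b]
     +\lambda\sum_{\text{cells}}(A-A_t)^2,$$
   with contact energy $J = 8$ per unit contact area for every pair involving
   a cell, target area $A_t = 25$ voxels, and fixed (non-periodic) walls.
   Attempts that would annihilate a cell are rejected, so death can only
   happen through the damage rule.
2. **Alpha-particle field.** Cells loaded with boronophenylalanine (BPA⁺,
   a fraction `f_dose` of the population, placed at random) secrete an
   alpha-particle density that diffuses at the propagation constant
   `D` (0.1–0.2 px²/MCS), decays at `mu` = 0.01/MCS, and is re-emitted every
   MCS from the source cells' voxels (release starts at MCS 1 and persists;
   emitters keep emitting after their own death). The update is an explicit
   6-point stencil with zero-flux boundaries, run in `substeps` sub-iterations
   so that `D/substeps <= 1/6` (stability and positivity).
3. **Threshold death.** Every live cell accumulates, per MCS, the mean over
   its voxels of $\max(c-\text{floor},0)/E_{\text{ref}}$ and dies the moment
   the cumulative total strictly exceeds the radioresistance threshold
   `theta` (study values 0 and 0.5). Dead cells stay on the lattice as inert
   objects with unchanged adhesion.

## Exposure units, the detection floor, and calibration

The paper-scale thresholds (0 and 0.5) are dimensionless, so the package
fixes the exposure unit as $E_{\text{ref}}$, the steady concentration at a
voxel face-adjacent to one isolated, continuously emitting source voxel in an
open lattice (`steady_state_reference()`). `theta = 0.5` therefore means
"half of one MCS spent face-adjacent to a saturated source". Both
$E_{\text{ref}}$ and the floor scale linearly in the emission rate `s`, so
`s` is a pure gauge (default 1).

Diffusion delivers a nonzero field everywhere, so a literal `theta = 0` would
kill 100% of cells. The detection floor `eps_floor` (in $E_{\text{ref}}$
units) encodes the finite alpha track length: field below
`eps_floor * E_ref` registers no damage. The floor is the model's one free
parameter. It is **calibrated once** with `calibrate_floor()` on the 3D
spheroid, high-dose (15%), zero-threshold condition — averaged over both
propagation constants, which is how that condition's plateau is reported —
to a mean plateau death fraction of 60%, and then frozen for every other
condition. The search is a log-scale bracketed regula-falsi with bisection
safeguard; the response is steep (several percentage points per floor unit),
so it converges in a handful of evaluations. Calibration and validation are
thereby explicitly separated: the raised-threshold and monolayer outcomes
are computed with no further tuning.

## Geometries

Both arrangements live on a 3D lattice and use the same field solver, so
2D-vs-3D differences come only from cell packing:

* **Spheroid** — the `n_cells * 25` voxels nearest the lattice center
  (a digitized ball), partitioned by nearest-seed assignment of randomly
  drawn seed voxels (exact integer distances, ties to the lower id), with a
  connectivity repair pass so every cell starts as one face-connected
  component. Default 500 cells in 64³.
* **Monolayer** — a one-cell-thick sheet of 5×5×1 footprints, filled
  row-major in a centered near-square grid. A 500-cell sheet of 5×5
  footprints spans 115×110 px and cannot fit a 64-voxel edge, so the default
  monolayer box is 136×136×16 (the sheet on the central plane, field free to
  leave the plane).

Default margins keep cells at least 8 voxels (3D) from the fixed walls.

## Parameters at a glance

| parameter | meaning | default | units |
|---|---|---|---|
| `J` | contact energy per unit contact area | 8 (cell pairs), 0 (medium–medium) | energy |
| `lam_area` | area-constraint strength | 2 | energy/voxel² |
| `temperature` | Metropolis temperature | 10 | energy |
| `neighborhood_order` | contact shell (1 = faces, 2 = +edges) | 1 | – |
| `D` | propagation constant | 0.1 | px²/MCS |
| `mu` | decay constant | 0.01 | 1/MCS |
| `s` | emission per source voxel | 1 (gauge) | field/MCS |
| `substeps` | diffusion substeps | 2 | – |
| `f_dose` | source-cell fraction | 0.15 high / 0.05 low | – |
| `theta` | radioresistance threshold | 0 / 0.5 | $E_{\text{ref}}$·MCS |
| `eps_floor` | detection floor | calibrated (~30–40) | $E_{\text{ref}}$ |
| `max_mcs` | run cap | 1000 | MCS |
| `plateau_eps`, `plateau_window` | plateau rule | 1 cell / 50 MCS | – |

The CPM temperature, area strength, neighborhood order, lattice sizes and
plateau rule are declared package defaults — values a CPM practitioner would
pick for mobile-but-cohesive 25-voxel cells — not quantities inferred from
data.

## Numerical choices

* Discrete decay is multiplicative, `c <- c * (1 - mu)` per MCS; at
  `mu = 0.01` this differs from `exp(-mu)` by under 0.01% per step.
* Operator order within an MCS: diffuse (substeps) → decay → secrete.
  The steady state therefore solves
  $(I-(1-\mu)A^{n})\,c = s\,e$ with $A = I + (D/n)L$ — the scheme-consistent
  fixed point, which is what the tests verify against a direct sparse solve.
  (The continuum resolvent $(\mu I - DL)c = se$ differs at order $\mu D$,
  larger than the 1e-6 comparison tolerance.)
* Zero-flux field boundaries conserve mass exactly when `mu = 0`, which the
  conservation test exploits; lattice margins keep boundary effects off the
  tissue.
* `steady_state_reference()` iterates the actual update on a 41³ open
  lattice until the adjacent-voxel value changes by under 1e-12 per step
  (the slowest mode contracts at `1 - mu` per MCS, so this bounds the error
  near 1e-10); results are memoized per parameter set.
* Nearest-seed ties in the spheroid partition are broken toward the lower
  cell id on exact integer squared distances, so geometry construction is
  fully reproducible.
* The run loop starts plateau checking only after the first death: before
  any death the windowed rule would fire trivially while the field is still
  ramping (the ramp time constant is `1/mu` = 100 MCS). A run with no
  deaths reports its value at `max_mcs`.
* Seeds: one base seed expands deterministically (affine map, kept below
  2³¹) into per-condition, per-replicate streams; a run is bit-identical
  given its seed because all randomness — including inside the C++ kernels —
  draws from R's RNG.

## What the generator emulates, and what it does not

The synthetic configurations reproduce the study conditions: ~500 cells of
25 voxels, sources assigned uniformly at random at 15% or 5%, spheroid vs
sheet packing, runs to the death plateau with 10 replicate seeds per
condition (4 per propagation constant per calibration probe, at least 5
seeds per probed floor). They do not attempt: cell growth or division,
spheroid self-assembly, heterogeneous BPA uptake, hypoxia, repair kinetics,
discrete particle tracks, or dosimetry in Gy. Passing tests therefore show
that the lattice model reproduces (or fails to reproduce, see below) the
published *simulation* outcomes — they say nothing about the wet-lab
measurements.

## Design decisions that were genuinely open

* **Threshold semantics** — cumulative (integrated) exposure, not
  instantaneous level; the raised threshold then acts as a latency filter:
  cells with brief or weak supra-floor contact are spared.
* **Exposure statistic** — the mean over the cell's voxels (a cell-level
  "particle count"), not the max.
* **Source persistence** — emission continues after the host cell dies
  (physical release, not a biological activity), switchable via
  `persist_sources`.
* **Dead cells** — keep adhesion J and area constraint (inert corpses), are
  never removed.
* **J matrix** — the single published contact energy is applied to every
  pair involving a cell; medium–medium contact is 0.
* **Monolayer box** — the sheet sits in a 3D box with the same solver; see
  the limitation below.

## Known limitations

* **The 2D monolayer under the calibrated floor.** With the floor fitted on
  the 3D condition, the field over a planar sheet in a 3D box spreads
  vertically and its in-plane level stays well below the floor: the
  simulated monolayer death fraction is near zero, a much stronger
  architecture effect than the published 2D outcome (~30% at threshold 0.5).
  Confining the field to a one-slice lattice overshoots in the opposite
  direction (the sheet saturates and 2D death exceeds 3D). The package keeps
  the shared-3D-box design — it preserves the qualitative ordering
  (3D > 2D) and the omnidirectional-exposure mechanism — and reports the 2D
  number as computed.
* **Propagation-constant sensitivity.** The single-voxel reference scales
  like 1/D while the superposed tissue field does not, so the calibrated
  floor cuts the two propagation constants at different effective depths:
  deaths at D = 0.2 run well above deaths at D = 0.1 under a floor
  calibrated to their joint mean. No principled reference unit removes this
  (a D-independent absolute floor reverses the split), so the published
  insensitivity to the propagation coefficient is not reproduced by this
  model class; the package reports the split honestly.
* Death plateaus at high floors are partly shaped by cell motility (source
  halos sweep through the population), so plateau values depend mildly on
  `max_mcs`; 1000 MCS is the declared readout horizon.
* The explicit solver is first-order in time; with `mu` and `D` at study
  values the per-step error is far below the biological variability between
  seeds.

## Problem sizes used by the tests

Unit and property tests run on lattices up to 26³ with up to 60 cells
(sub-second each). The acceptance-level checks use the full study scale —
500 cells, 64³ (3D) or 136×136×16 (2D), up to 1000 MCS, 10 seeds per
condition and 8 per calibration probe — chosen to match the study conditions
while keeping a full replicate sweep at desk scale.
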