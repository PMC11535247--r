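---
title: "mrtvasc: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mrtvasc: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrtvasc)
```

`mrtvasc` simulates the action of microbeam radiation therapy (MRT) on
brain capillary networks, following the multiscale chain: vasculature
geometry, tumor-driven vascular redistribution, dual-field oxygen
perfusion, spatially fractionated irradiation, and oxygenation outcome.
This vignette explains the model, the parameters that matter, the design
choices made where the design was genuinely open, and the limits of what
the synthetic-data runs can show.

## The Potts (GGH) engine

Cells are sets of voxels on a 3-D lattice (`VoxelLattice`), evolving by
Metropolis voxel-copy attempts: a random voxel proposes to copy its cell
identifier onto a random neighbor, and the move is accepted with
probability $\min(1, e^{-\Delta H/T})$. One Monte-Carlo step (MCS) is one
sweep of as many attempts as lattice voxels. The energy combines

* **adhesion**: contact energies $J(\tau_i,\tau_j)$ between unlike cells
  over the Moore (26-voxel) neighborhood;
* **volume**: $\lambda_{vol}(v_c - V_c)^2$ toward a target volume;
* **elongation**: $\lambda_{len}(\ell_c - L_c)^2$ for vascular cells,
  where the major-axis length $\ell_c = \sqrt{12\lambda_{max} + 1}$ voxels
  comes from the largest eigenvalue of the cell's voxel-coordinate
  covariance (exact for a straight one-voxel-thick rod);
* **chemotaxis**: a per-move work term $-\mu\,(f_{src} - f_{tgt})$ on a
  concentration field (used with the autocrine VEGF field).

Two local *face-connectivity* rules accompany the dynamics (default on):
an expansion must place the new voxel face-adjacent to its cell, and a
retraction must leave the cell's face-neighbors of the lost voxel locally
face-connected. These are the standard GGH connectivity constraint
adapted to 6-connectivity, which matters here because the perfusion
fields exchange flux across voxel faces only: without the rule, the
elongation term drives cells into diagonal strings that are intact to the
Potts dynamics but invisible to perfusion.

The paper-scale lattice is $117^3$ voxels of 6 µm (0.7 mm cube); the
package's calibrated desk scale is $64^3$, with $48^3$/$32^3$ used for
smoke runs. Contact energies and stiffnesses are not printed in the
source methodology (they live in simulation scripts), so the package
ships two calibrated sets — `remodelingParams()` (cold and stiff:
$\lambda_{len} = 100$, $\lambda_{vol} = 6$, $T = 1$, $\mu = 5$,
$J_{VV} = 2 J_{VM}$ so the vascular phase has no differential-adhesion
drive to coalesce) and `growthParams()` (moderate adhesion with cohesive
tumor contacts, $T = 5$) — chosen once to reproduce the qualitative
contract: cell count and vascular volume fraction conserved, mean
vascular cell length in the measured range, vessels displaced but not
destroyed by the growing tumor. Under the connectivity constraint the
volume equilibrium sits a few percent above target (retractions are
rejected more often than expansions); the vascular volume fraction
consequently drifts up by up to ~1 percentage point over a long
remodeling run, within the ±6% variation the reference workflow itself
reports across stages.

## Synthetic angioarchitecture

The generator replaces an external whole-brain segmentation with a
statistical emulation. Biased random walks cross the cube face-to-face
(cycling the three axes, so each pair of opposite faces is spanned by
construction), and branch walks seeded on the existing network either
dead-end inside the volume (70%, geometric length with mean ~40% of the
lattice edge) or run to a face and anastomose. Paths are dilated to at
least the 6 µm minimum capillary diameter (a 15% minority at ~18 µm), and
walks are added until the vascular volume fraction is within half a
percentage point of the 14.8% target. Tortuosity defaults to 1.1 —
cortical capillaries are fairly straight between branch points — and the
walk statistics (fraction, diameter, connectivity, clusterability) are
the only contractual properties; the topology itself is plumbing.

Clustering partitions capillary voxels into cells by recursive geodesic
banding: within each 6-connected component, voxels are banded by geodesic
distance from a component endpoint in slabs of the target length (20
voxels), bands are split into connected chunks, and chunks that are still
too extended or too massive are re-banded from their own endpoints.
Chunks shorter than half the target, or with fewer voxels than the target
length (which could never reach the target length), merge into an
adjacent chunk. On a straight tube this reduces to exact division into
target-length segments.

Remodeling then runs the Potts dynamics with autocrine VEGF secretion
(diffusion 10 µm²/s, decay 0.65 h⁻¹, secretion 1 a.u./MCS into the
secreting cell's voxels), chemotaxis on that field, and the 20-voxel
elongation target. Because the VEGF field is far from its ~90-minute
equilibrium during a few hundred MCS, the chemotaxis strength is
effectively mild and stabilizing (it holds vascular mass on existing
vessel tracks). Small capillary discontinuities opened by the dynamics
are closed by a bridging repair (6-connected staircase paths across gaps
of up to 3 voxels during the run, up to 8 in a final cleanup), the
package's operationalization of the reference workflow's qualitative
artifact-removal step. At $64^3$ this yields ~300–360 vascular cells with
a mean major-axis length of 118–121 µm against the experimentally
measured 124 ± 7 µm.

## Tumor growth and staging

A single tumor cell (3375 µm³ target, ~16 voxels) is seeded at the
lattice center, displacing normal but never vascular voxels. Tumor cells
grow their target volume by $r_{max}\,p/(p + K_m)$ per MCS (mean cellular
pO₂ $p$ over the cell; defaults $K_m = 5$ mmHg, $r_{max}$ 6.75 µm³/MCS at
full scale) and divide on reaching 6750 µm³. Division splits the cell by
a connected sweep along its major axis (the discrete centroid-plane
split), with perturbed-axis retries, breadth-first half-ball fallbacks
and single-voxel rebalancing so daughters stay contiguous and within 20%
of each other's volume.

During growth the vascular pO₂ is clamped at the arterial value — the
growth stage's oxygen model in the source methodology — and the full
perfusion machinery runs only in the evaluation phases. Growth stages are
defined by geometry, not wall-clock: snapshots are taken when the tumor
volume fraction first reaches the stage milestones (5.5%, 13.5%, 27.6%,
46.5%, 56.5% for D12–D20), so scaled runs with a compressed growth rate
reach the same morphological stages. Growth refuses to continue past 60%
tumor fraction (lattice crowding). Vessels are displaced toward the
tumor contour; at $48^3$ the spatial-uniformity SD rises monotonically
with stage (by ~30% at D20 on a seeded run), the qualitative signature
the model exists to produce. No angiogenesis is simulated and vascular
cell count is conserved exactly through growth.

## Dual-field oxygen model

Two fields share the lattice geometry:

* **Vascular pO₂** diffuses only across faces shared by two vascular
  voxels. Donor cells — a virtual clamped ghost layer at every vascular
  voxel touching the three low lattice faces — hold 90 mmHg; acceptors on
  the three opposite faces hold 0, creating directed perfusion whenever a
  path connects them.
* **Cellular pO₂** is sourced at vascular voxels (set equal to the
  vascular value each step), diffuses tissue-wide at 2000 µm²/s with
  periodic wrap on all axes, and is consumed by cells.

The per-step *leak* — the drop of cellular pO₂ at vascular voxels between
sourcing and end of step — is debited from the vascular field. Only
positive leak is debited: tissue never re-oxygenates a vessel, so a
severed segment drains monotonically, reproducing the three
severed-capillary scenarios (donor-connected segments hold their level;
acceptor-only segments drain fastest; isolated segments decay by tissue
leakage alone). `runCapillaryDemo()` packages the 50-cell single-tube
demonstration of exactly these scenarios, deterministically, in lattice
units.

Uptake follows Michaelis–Menten kinetics with a maximum of 0.6 mmHg/s per
normal cell (ten-fold for tumor cells) and $K_m = 1$ mmHg, applied as the
cell's total consumption distributed over its voxels. This reading of the
per-cell maximum is the one consistent with the model's tens-of-minutes
oxygenation timescales; reading it as a per-voxel rate makes the late
tumor stages infeasible (anoxic before irradiation), contradicting the
normoxic pre-irradiation state the model requires.

All diffusion uses an explicit 6-neighbor finite-difference stencil with
automatic sub-stepping at $\alpha = D\,\Delta t_{sub}/h^2 \le 0.15$, so
any macro time step is stability-safe; periodic diffusion conserves mass
to rounding, and the vascular stepper's boundary flux enters the same
explicit update as the neighbor flux, so its steady state matches the
analytic Dirichlet chain exactly. Equilibration runs a bidirectional
vessel/tissue phase first (filling the tissue and finding the coupled
equilibrium) before settling the directional drain-only state; without
that, the cold-start transient under the one-way rule strands poorly
supplied vessels at artificially low values.

## Irradiation and response

The parametric dose model builds a 1-D lateral profile — a valley floor
plus one flat-top/Gaussian-penumbra bump per beam with FWHM exactly the
nominal 50 µm (penumbra $\sigma$ = 8 µm) — normalized so the maximum
voxel equals the 350 Gy peak and the mid-spacing valley is 6 Gy, then
replicated along the other axes (depth-dose variation over the
sub-millimetre cube is neglected). Externally scored grids can be
imported from a plain-text scorer CSV with declared binning; geometry
mismatches are errors and the round trip is exact.

Vascular cells die stochastically with the probability of their mean
dose under the endothelial apoptosis dose–response: linear interpolation
over measured points in 0–25 Gy, linear extrapolation through the two
highest points beyond, clamped to 1. The default table
(`defaultDoseResponse()`) is a synthetic monotone placeholder — it is
*not* a transcription of the measured curve and should be replaced via
`doseResponseTable()`/`readDoseResponse()` where fidelity to the
measured response matters. Non-vascular cells whose centroid lies within
any beam's FWHM band (half-open, $[c - 25\,\mu m, c + 25\,\mu m)$) are
removed deterministically; with three 50 µm beams on the 0.7 mm lattice
this ablates ~21% of uniformly seeded cells. Oxygen-dependent
radiosensitivity is deliberately not modeled (cells are normoxic at
irradiation time).

## Outcomes

Per-cell mean cellular pO₂ below 5 mmHg classifies a cell hypoxic
(reversible), below 1 mmHg necrotic (absorbing: the cell counts as dead
and stops consuming, but keeps its voxels). The unperfused fraction is
the share of *surviving* vascular cells whose mean vascular pO₂ has
fallen below 1 mmHg. Spatial uniformity is the population SD of local
vascular densities over an exact tiling of cubic subregions (default
edge: the divisor of the lattice edge closest to a fifth of it); the
relative increase of that SD over the normal-tissue reference is the
"decrease in uniformity". `summarizeRun()` pairs relative pO₂ depletion
with uniformity decrease across scenarios and reports their Spearman
correlation.

## What the synthetic runs do and do not show

The synthetic generator emulates the vascular volume fraction, minimum
diameter, face-to-face connectivity and clusterability of a real
cortical angioarchitecture — not its true branching hierarchy, diameter
distribution or flow topology. Desk-scale boxes (≤ 0.4 mm) are
boundary-dominated: every tissue point is within ~10 capillary spacings
of a donor face. Consequently:

* The mechanistic pieces all reproduce: no unperfused vessels before
  irradiation; ~45–50% vascular death at the reference dose; 20–30%
  of surviving vessels unperfused after irradiation; positive global
  pO₂ depletion; monotone uniformity decrease with tumor stage.
* The *stage ordering* of depletion (later tumor stages depleting more)
  does not express at desk scale with the faithful 0.6 mmHg/s per-cell
  uptake: supply is not limiting in a small box, and beam-path ablation
  of central tumor cells (the largest consumers) offsets the supply
  loss. The original workflow's ordering lives in a supply-limited
  regime whose uptake calibration is not printed; the package does not
  inflate the printed uptake to force it. The machinery for the
  comparison (staged scenarios, `summarizeRun()`) is in place for users
  running at full scale with their own calibration.

Problem sizes used throughout the package's own tests and acceptance
checks — $64^3$ for remodeling statistics, $117^3$ for dose and ablation
geometry, $32^3$–$48^3$ for end-to-end runs — are the package's chosen
desk-scale study conditions; the full $117^3$ pipeline is available via
`simulationConfig(scale = "full")`.

## Numerical and degenerate-input choices

* Voxel indices are 0-based linear (column-major) in the public API,
  matching the compiled kernel.
* $T = 0$ accepts exactly the non-positive energy changes.
* Empty cells are removed after each MCS; donor/acceptor rows never are.
* A lattice whose vascular network fails to touch a donor face refuses
  donor placement (network not spanning).
* The generator fails with a diagnostic if the target fraction is
  unreachable; a target fraction of 0 returns an empty lattice.
* Resampling selects foreground blocks by occupancy rank, preserving the
  global volume fraction to one part in the number of blocks; all-binary
  input is enforced.
* Isolated single capillary voxels become single-voxel cells; division
  of a cell below the division volume is an error.
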