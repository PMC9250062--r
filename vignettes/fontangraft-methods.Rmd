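---
title: "Graft construction and hemodynamic benchmarking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graft construction and hemodynamic benchmarking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontangraft)
```

## The problem

In the Fontan procedure, the third stage of single-ventricle palliation, a
vascular conduit is sutured between the inferior vena cava (IVC) and the
pulmonary arteries so that systemic venous blood reaches the lungs by
passive flow. The geometry of that conduit matters: a poor configuration
raises hydraulic power loss (exercise intolerance), leaves regions of low
wall shear stress (thrombosis risk), and splits hepatic venous flow
unevenly between the lungs (pulmonary arteriovenous malformations).
`fontangraft` is a headless toolkit for the two computational halves of
planning such a conduit: building tube-shaped and bifurcated graft
surfaces parametrically as watertight triangle meshes, and scoring flow
data for a candidate graft against three clinical benchmarks.

## Graft geometry

### Pathways

A graft centerline is a piecewise cubic Bezier path. Each segment is the
standard Bernstein cubic

$$P(t) = P_0 (1-t)^3 + 3 P_1 t (1-t)^2 + 3 P_2 t^2 (1-t) + P_3 t^3,
\qquad t \in [0, 1],$$

where the anchors $P_0, P_3$ are the centers of two cross-sections (the
curve interpolates them exactly) and the handles $P_1, P_2$ set the
direction and strength of the pathway. Inserting an extra anchor for
finer control splits one segment into two by de Casteljau subdivision,
which is shape-preserving: the traced curve is unchanged and the two new
handles flank the new anchor. The suite verifies evaluation against an
independent recursive de Casteljau implementation (agreement well below
$10^{-12}$ mm) and shape preservation below $10^{-9}$ mm.

A path also carries an arc-length-normalized global parameter, computed
from a dense chord-length table (200 samples per segment). This is an
approximation — the inversion is piecewise linear between table entries —
but it is only used to place lofting rings and to truncate branch paths,
where sub-micrometre parameter accuracy is irrelevant.

### Cross-sections and girth interpolation

An anastomosis (suturing) region is an ellipse given by a center and two
semi-axis vectors. Boundary radii are sampled by the polar form
$r(\theta) = ab / \sqrt{(b\cos\theta)^2 + (a\sin\theta)^2}$ measured from
the first axis. Because a user-placed second axis need not be exactly
perpendicular, the second axis is projected onto the orthogonal
complement of the first before use; a deviation beyond 30 degrees raises
a warning rather than an error, since small grab errors are expected
input noise while large ones usually indicate a mistaken control point.

Girth blends between the start and end sections per angle:
$\Delta = r_1 - r_0$ and $r_t = r_0 + \Delta f(t)$ with an adjustment
factor $f : [0,1] \to [0,1]$, $f(0)=0$, $f(1)=1$, monotone. The default
is smoothstep, $f(t) = 3t^2 - 2t^3$; its zero end slopes make the graft
girth tangent-continuous where it meets the native vessels, which is the
behaviour a surgeon would expect of a suture line. A linear option
(`f = "linear"`) is selectable everywhere the adjustment enters. The
choice of default was genuinely open; smoothstep was chosen once for the
end-slope argument and is not tuned per case.

### Sweep lofting and frames

`loft_tube()` places `n_rings` cross-sections at arc-length-uniform path
positions. Ring orientation uses rotation-minimizing frames computed by
the double-reflection method, which avoids the twist artifacts of
Frenet frames on low-curvature or inflected paths. Since the end section
has its own user-given frame, the residual in-plane angle between the
transported frame and the end frame is distributed linearly along the
sweep, so both end rings lie *exactly* on their given sections while no
ring-to-ring twist jump occurs. Rings are joined by quad strips split
into triangles; caps are triangle fans to the ring centers. Defaults are
`n_rings = 32`, `m_samples = 32`; both are plain arguments, and the
randomized integrity sweeps in the tests run 3–16 rings and 8–24 angular
samples. A capped loft is checked watertight (every edge shared by two
faces), genus 0 ($V - E + F = 2$) and outward wound (positive signed
volume); the capped-cylinder volume error at 64 angular samples is about
0.16%, within the polygonal deficit bound.

### The bifurcation junction

A bifurcated graft is a trunk (IVC to first anastomosis) plus a branch
(second anastomosis to a split region on the trunk at path position
`split_point`). Joining two independently meshed tubes is the one place
where the construction was genuinely underdetermined. We do **not** use a
boolean surface union: a robust exact union is a large, failure-prone
component, and a voxel-based fallback would destroy the exact ring/radius
structure that the loft-consistency checks rely on. Instead the trunk is
kept as a structured ring grid, the branch path is truncated where it
first enters the trunk surface, a rectangular window of grid cells sized
to the branch girth is removed around the landing point, and the
branch's final ring is stitched to the window perimeter with an
arc-length-keyed triangle "zipper". The result is watertight and genus 0
*by construction* (each rim edge acquires exactly one bridging face);
winding consistency is restored afterwards by region growing plus a
global flip to positive volume. On a symmetric Y of cylinders the capped
volume agrees with a 0.25 mm voxelization of the union of the two
cylinders to within a few percent (5% tolerance asserted).

Limitations: the window must not touch the trunk's end rings, so a split
region very close to an end is rejected with a clear error; and no global
triangle–triangle self-intersection sweep is performed — sharply
recurved paths can produce self-overlapping (though still watertight)
surfaces. Degenerate inputs are rejected early: radii below 0.1 mm and
segment chords below 0.01 mm.

### Boundary preparation for CFD

`extrude_boundary()` translates a tagged rim along its mean (Newell)
normal, oriented away from the mesh, and triangulates the side wall.
This implements the standard preparation steps: the native IVC surface
extruded 10 mm inferiorly, inlets extended by 10 times their largest
diameter (`largest_boundary_diameter()`, the maximum pairwise rim vertex
distance), outlets by 50 mm, so a stable velocity profile can develop in
a simulation. A zero-length extrusion is the identity rather than a ring
of degenerate faces.

## Hemodynamic benchmarks

All boundary quantities are SI; WSS values are dyne/cm² (1 Pa = 10
dyne/cm²), the unit of the physiologic venous range 1–10 dyne/cm².
Fluid defaults are Newtonian blood, $\rho = 1060$ kg/m³,
$\mu = 3.5\times10^{-3}$ Pa·s, overridable.

**Indexed power loss.** Hydraulic power loss is the total-pressure energy
balance over the flow boundaries,
$PL = \sum_{in} (\bar p + \tfrac12 \rho \bar{v^2}) Q -
\sum_{out} (\bar p + \tfrac12 \rho \bar{v^2}) Q$, and
$\mathrm{iPL} = PL \cdot \mathrm{BSA}^2 / (\rho Q_s^3)$ with $Q_s$ the
sum of inlet flows and BSA the body surface area. This is the
established indexed form in the Fontan CFD literature. Mass conservation
is asserted within 1% before computing; by conservation, adding any
constant to all static pressures leaves $PL$ unchanged (tested). On the
analytic Poiseuille fixture $PL$ matches $8\mu L Q^2/(\pi R^4)$ to
machine precision across a 3×3×3 grid of $(R, L, Q)$.

**Nonphysiologic WSS fraction.** $\%\mathrm{WSS} = 100\, N_A / N$ where
$N_A$ counts values strictly below the threshold (default 1 dyne/cm²).
The equation counts samples while the motivating description speaks of
areas; the count fraction is the default (it is what the formula says)
and an area-weighted variant is available by passing per-point weights.
Threshold conventions throughout are literal: strictly below 1 dyne/cm²,
strictly below 0.03 for iPL, strictly below 10% for %WSS, and an
inclusive 40–60% band for HFD — documented so results are reproducible.

**Hepatic flow distribution.** Massless particles are seeded on a square
grid over the IVC inlet (count scales with inlet area; a pitch larger
than the inlet degenerates to the single center point) and advanced by
fixed-step RK4 through a velocity-field sampler until they cross a named
outlet or exhaust the step budget (default 50,000).
$\mathrm{HFD}_{LPA} = 100\, N_{LPA}/N_{IVC}$, likewise for the RPA; the
denominator is the seeded count, so stranded particles deflate both
shares — the stranded fraction is always reported and warns above 5%.
Conservation $N_{LPA} + N_{RPA} + N_{stranded} = N_{IVC}$ holds on every
trace including early termination. The integrator's observed order on a
rigid-rotation field is 4.0 (asserted ≥ 3.5). The sampler contract
(vectorized `velocity`, `inside`, `outlet` over N×3 mm positions,
velocities in m/s) is deliberately minimal so user plug-ins can wrap any
interpolated CFD field.

**Reynolds check.** $Re = \rho \bar v D / \mu$ with
$\bar v = Q/(\pi D^2/4)$, flagged laminar below 2300, the standard
pipe-flow transition.

## Synthetic fixtures: what they do and do not show

No patient anatomy or flow solution ships with the package, and the
package deliberately contains no Navier–Stokes solver — it consumes flow
fields, it does not produce them. Validation therefore runs on analytic
fixtures whose ground truth is exact:

* `make_poiseuille()` — laminar pipe flow with closed-form pressure drop,
  wall WSS, and centerline velocity; boundary records constructed to be
  exactly consistent. The metrics pipeline must recover the closed forms
  to $10^{-6}$ relative, and the wall WSS crossing of 1 dyne/cm² flips
  %WSS between exactly 0 and 100.
* `make_y_junction()` — piecewise unidirectional flow whose dividing
  plane is placed by solving the disc-chord area equation for the
  prescribed split $s$, so the true split is known analytically. At
  10,000 grid-seeded particles the recovered LPA share lands within the
  seeding quantization (measured ±0.1 points; ±2 asserted).
* `make_wss_field()` — exactly `round(n·f)` values strictly below
  threshold, seed-deterministic.
* `make_toy_anatomy()` — open cylinders posed as an IVC stub (10 mm
  inferior extension applied) plus a T-shaped Glenn, enough to exercise
  the graft builders against realistic targets.

These fixtures establish that the *operations* are correct on fields
with known answers. They do not establish clinical accuracy on real
anatomies: real TCPC flow is three-dimensional, sheared, and unsteady,
real inlets are not perfect discs, and CFD-derived WSS carries mesh and
model error. Passing tests here mean the arithmetic and geometry are
right, not that a particular patient's numbers are.

## Exchange formats

The sketch CSV stores, in fixed order, the scene transforms (heart,
Glenn, graft; translation, unit quaternion w-x-y-z, scale), the Bezier
control-point records (trunk path first), the per-section frame and
radius records, and the build parameters; parsing is strict,
top-to-bottom, with line-numbered errors. Numbers are written with 17
significant digits, so save → load → rebuild reproduces the original
vertex array bit-exactly on the same platform — asserted in the tests,
for both shapes.

Simulation results arrive as HDF5 and are converted to a single
three-part CSV (sizes; per-design iPL/%WSS/HFD summaries; raw per-point
x, y, z, WSS). Dataset names are configurable through a mapping (YAML or
list); defaults are `/summaries`, `/wss/points`, `/wss/values`, plus
`/wss/design` for multi-design files. Raw dataset I/O is delegated to a
small bundled Python helper built on h5py; the R side owns mapping,
validation (summary row count = design count, per-design point counts
sum to the stated total) and CSV assembly. Point-cloud thresholding for
display keeps nonzero WSS values within a window defaulting to
[0, 1] dyne/cm², with the requested maximum clamped to the largest value
present; enlarging the window never removes points.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; particle seeding is a
deterministic grid. The test and validation workloads were sized once as
a desk-scale validation study: 1000 random segments for the Bezier
oracle, 200 randomized lofts for the integrity sweep, a 3×3×3
Poiseuille grid, 10,000 particles per junction split, 0.25 mm voxels for
the junction volume oracle. The `scripts/acceptance.R` entry point
recomputes all of these from scratch and writes them as JSON.
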