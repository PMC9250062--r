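# fontangraft

Parametric design and hemodynamic benchmarking of Fontan vascular
grafts, headless and scriptable.

Patients with single-ventricle heart defects receive a Fontan conduit —
a graft sutured from the inferior vena cava (IVC) to the pulmonary
arteries — so venous blood reaches the lungs passively. How well a
candidate conduit performs is judged on three quantities:

* **iPL**, indexed power loss: the hydraulic power lost across the
  connection, `iPL = PL · BSA² / (ρ Qs³)` with
  `PL = Σ_in (p̄ + ½ρv̄²)Q − Σ_out (p̄ + ½ρv̄²)Q`, benchmark `< 0.03`;
* **%WSS**, the fraction of wall-shear-stress samples strictly below
  1 dyne/cm² (thrombosis-prone regions), benchmark `< 10%`;
* **HFD**, the hepatic flow distribution `100·N_LPA/N_IVC` estimated by
  massless Lagrangian particle tracking, benchmark 40–60% to either
  lung.

`fontangraft` provides, for surgical-planning and CFD-adjacent research
workflows:

* **geometry** — tube-shaped and bifurcated graft surfaces lofted along
  cubic Bezier pathways through elliptical anastomosis cross-sections
  (polar-ellipse sampling, smoothstep girth interpolation,
  rotation-minimizing frames), emitted as watertight triangle meshes
  with tagged boundary rims; boundary extrusion (10 mm IVC extension,
  10× largest-diameter inlet / 50 mm outlet extensions) and OBJ/STL
  exchange;
* **hemodynamics** — the three benchmark metrics plus a Reynolds-number
  laminarity check and benchmark classification, computed from boundary
  flow records, WSS point clouds, and pluggable velocity-field samplers;
* **io formats** — a design-sketch CSV that rebuilds the exact mesh
  (bit-identical round trip), and an HDF5 → three-part CSV converter for
  simulation result bundles with WSS point-cloud thresholding;
* **fixtures** — analytic Poiseuille and Y-junction flows and synthetic
  WSS fields with exact ground truth, so everything is testable without
  patient data or a flow solver;
* **cli** — `build` / `evaluate` / `convert` subcommands over YAML
  configs (`inst/cli/fontangraft.R`).

The package consumes flow fields and CFD summaries; it does not solve
the Navier–Stokes equations.

## Worked example

Design a tube graft from an 8 mm IVC stump to a 5 mm circular
anastomosis 33 mm up and 30 mm to the left, then check a candidate
split on an analytic junction field:

```r
library(fontangraft)

ivc   <- circular_section(center = c(0, 0, 0), normal = c(0, 0, 1),
                          radius = 8, m = 32)
anast <- anastomosis_ellipse(center = c(-30, 0, 33),
                             axis_a = c(5, 0, 0), axis_b = c(0, 5, 0))
path  <- bezier_path(bezier_segment(c(0, 0, 0), c(0, 0, 15),
                                    c(-30, 0, 15), c(-30, 0, 33)))
graft <- build_tube_graft(ivc, anast, path)
graft
#> <graft_mesh> V=1024 F=1984 open loops: IVC_inlet, PA_anastomosis_1
largest_boundary_diameter(graft, "IVC_inlet")
#> [1] 16
cap_mesh(graft)
#> <graft_mesh> V=1026 F=2048 closed, watertight=TRUE, volume=6348.993 mm^3
write_obj(graft, "graft.obj")

fx    <- make_y_junction(s = 0.65)            # exact 65/35 split
seeds <- seed_particles(fx$inlet_section, spacing = 0.25)
tr    <- trace_particles(fx$sampler, seeds, step = 0.01, max_steps = 2000)
tr
#> <particle_trace> 2809 seeded; LPA: 1847, RPA: 962; 0 stranded
h <- hfd(tr)

hemo_report(ipl = 0.0086, pct_wss = 55.36,
            hfd_lpa = h$hfd_lpa, hfd_rpa = h$hfd_rpa, bsa = 1.2)
#> Hemodynamic performance report
#>   iPL   : 0.0086     benchmark < 0.03    -> within
#>   %WSS  : 55.36      benchmark < 10%     -> outside
#>   HFD   : 65.75% LPA / 34.25% RPA, benchmark 40-60% -> outside
```

The mesh is watertight with Euler characteristic 2; the inlet rim
measures its full 16 mm diameter; the traced split (65.75% LPA) lands on
the fixture's prescribed 65% up to seeding-grid quantization; and the
report flags each metric against its clinical range.

The same flows run from a shell:

```sh
Rscript inst/cli/fontangraft.R build    --sketch design.csv --out graft
Rscript inst/cli/fontangraft.R evaluate --fixture poiseuille --out run
Rscript inst/cli/fontangraft.R convert  --h5 results.h5 --out run
```

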