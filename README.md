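# atriafit

Locally personalised left-atrium electrophysiology models from
multi-electrode catheter recordings.

During an S1S2 pacing study (a drive train at s1 = 470 ms followed by a
premature beat whose coupling interval descends in 2% steps from 343 ms
to 200 ms or loss of capture), a multi-spline mapping catheter records
bipolar electrograms across the atrial body. `atriafit` turns those
recordings into a patient-specific simulation model and checks how well
that model predicts activation:

1. **Electrogram processing** — local activation times (first
   supra-threshold electrogram deflection), per-electrode conduction
   velocity restitution CV(s2) via a piecewise-linear LAT gradient on a
   Delaunay triangulation (median-pooled within 2.5 cm, 200 cm/s
   physiological cut-off), and the effective refractory period (largest
   s2 without local capture).
2. **Cell model** — the modified Mitchell–Schaeffer (mMS) model,
   \(I_{ion} = h\,v_m(v_m - v_{gate})(1-v_m)/\tau_{in} - v_m/\tau_{out}\),
   with no pacemaker behaviour for any parameter combination, linked to
   observable markers (CVmax, APDmax, h_min) by exact leading-order
   formulas and their algebraic inverse.
3. **Restitution database** — CV restitutions and ERPs pre-computed with
   a 1D monodomain cable (operator splitting: forward-Euler reaction,
   Crank–Nicolson diffusion) over the published marker grid of
   30 × 11 × 10 × 16 × 11 = 580,800 combinations (desk-scale subsampling
   built in).
4. **Fitting** — per-electrode nearest-database-row least squares with
   interval-censored ERP residuals and a second pass regularised toward
   the cohort marker medians.
5. **Mapping & simulation** — nearest-neighbour extrapolation of fitted
   parameters over a triangulated surface, 200 conductivity bins, and a
   heterogeneous isotropic monodomain simulation (P1 finite elements,
   lumped mass, CN/CG diffusion) of the full pacing protocol.
6. **Onset search** — a graph-eikonal (Dijkstra) exhaustive search for
   the effective stimulus location that best explains the measured LATs
   after mean-offset correction, implemented by reciprocity (one solve
   per electrode).
7. **Validation** — regression line (q, m), Pearson r, covariance
   slender ratio, and the functional-block error
   \(100 \cdot \sum N^{block}_{s2} / \sum N^{meas}_{s2}\).

A synthetic-data module generates ground-truth heterogeneous sheet
"patients" with virtual five-spline catheter recordings, so the entire
pipeline is testable without clinical data.

## Worked example

Fit one electrode's restitution against a small database and inspect
the recovered tissue parameters:

```r
library(atriafit)

# a 99-row slice of the marker grid (about a minute to simulate)
spec <- marker_grid(cv_max = seq(40, 140, 10), tau_in = 0.28, h_min = 0.3,
                    tau_open = 105, apd_max = seq(150, 270, 15))
db <- build_database(spec, cable_config(preset = "desk"), pacing_protocol())

# a synthetic homogeneous patient, virtually mapped and fitted
case <- make_sheet_case(size_cm = 8, n_regions = 1, edge_mm = 1, seed = 11,
                        cv_pool = 80, apd_pool = 180)
ladder <- s2_ladder(case$protocol)
s2_fit <- ladder[unique(round(seq(1, length(ladder), length.out = 6)))]
res <- end_to_end_case(case, db, s2_fit = s2_fit, s2_valid = s2_fit[1:3],
                       cfg = sim_config(preset = "desk"))

fits_to_table(res$fits)[1, c("cv_max", "apd_max", "h_min", "D")]
#>   cv_max apd_max h_min         D
#> 1     80     180   0.3 0.0142892

res$reports$B
#> validation: (q, m) = (2.31, 1.00), r = 1.000, sl = 0.000, fblock = 0.00% (n = 138)
```

The fitted markers recover the ground truth (80 cm/s, 180 ms) exactly.
The held-out pacing site — whose recordings never entered the fit — is
predicted with Pearson r = 0.9997, regression slope 0.997 (1 is
perfect), a covariance slender ratio of 0.0002 (0 is perfectly
collinear agreement), and no functional block; the eikonal search
localises the entry site of the held-out wave to within a couple of
millimetres.

## Command-line tools

Thin wrappers over the exported functions live in `inst/cli/`:
`build_db.R` (database builds, YAML-configurable), `synth_case.R`
(synthetic cases exported as electrode CSV + VTK + manifest) and
`validate.R` (agreement indices from measured/computed LAT tables).

## Scope

Isotropic monodomain shell only — no fibre anisotropy, no transmural
structure, no bidomain extracellular fields, single-onset search, and
prepared meshes are taken as given. See `vignettes/methods.Rmd` for the
models, numerical choices and their rationale.
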