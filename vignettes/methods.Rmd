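---
title: "Locally personalised atrial electrophysiology: models, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally personalised atrial electrophysiology: models, fitting and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriafit)
```

`atriafit` builds locally personalised models of left-atrial
electrophysiology from multi-electrode catheter recordings of an S1S2
pacing protocol, and validates them by comparing measured against
simulated activation times. This vignette explains the models, the
numerical choices, and the judgement calls a maintainer would want
justified. Everything quantitative stated here is computed by the test
suite or the acceptance script; nothing is quoted from external data.

## The cell model

Local electrophysiology is described by a modified Mitchell–Schaeffer
(mMS) two-variable model: a dimensionless transmembrane potential $v_m$
(rest 0, plateau near 1) and a recovery gate $h \in [0,1]$,

$$\partial_t v_m = D\,\Delta v_m + \frac{h\,v_m (v_m - v_{gate})(1 - v_m)}{\tau_{in}} - \frac{v_m}{\tau_{out}},
\qquad
\partial_t h = \begin{cases}
(1-h)/\tau_{open} & v_m < v_{gate}\\
-h/\tau_{close} & v_m \ge v_{gate}.
\end{cases}$$

The factor $v_m$ (rather than $h$ alone) in the cubic term makes the
resting state unconditionally stable: no parameter combination produces
pacemaker behaviour, which the test suite asserts for 100 random
parameter sets. The four time constants (ms) control depolarisation
($\tau_{in}$), repolarisation ($\tau_{out}$), gate recovery
($\tau_{open}$) and action-potential duration ($\tau_{close}$); the
threshold is fixed at $v_{gate} = 0.1$.

## Markers and the leading-order inversion

The restitution database is swept not over raw time constants but over
five observable markers: the conduction velocity at the longest tested
coupling interval (`cv_max`, cm/s), the maximum action potential
duration (`apd_max`, ms), the minimum of the gate null-cline (`h_min`),
and $\tau_{in}$, $\tau_{open}$ carried through. Closed forms connect
markers and parameters:

* $h_{min} = 4\tau_{in} / (\tau_{out}(1-v_{gate})^2)$ — the minimum of
  the null-cline $h(v) = \tau_{in}/(\tau_{out}(v-v_{gate})(1-v))$,
  verified in the tests against a numerical minimisation;
* $APD_{max} = \tau_{close}\,\ln(1/h_{min})$;
* the front speed. For gate level $h$ the fast subsystem is a cubic
  bistable reaction whose outward linear term shifts the resting and
  excited roots to
  $v_\pm = \tfrac12[(1+v_{gate}) \pm (1-v_{gate})\sqrt{1-h_{min}/h}]$,
  giving the exact travelling-wave speed
  $CV = \sqrt{D h/(2\tau_{in})}\,\kappa$ with
  $\kappa = \tfrac12[3(1-v_{gate})\sqrt{1-h_{min}/h} - (1+v_{gate})]$.
  The textbook prefactor $1-2v_{gate}$ is the limit
  $h_{min}\to 0,\ h\to 1$; at the upper end of the `h_min` grid the
  difference approaches a factor of two, so using the exact roots is
  not a refinement but a necessity.

`cv_max` is deliberately protocol-referenced: it is the speed of the
premature beat at the longest coupling interval (343 ms), because that
is what the clinical protocol can observe. The gate level at that beat
is estimated in closed form by stepping the leading-order drive-train
dynamics once (gate before the last drive beat, its shortened APD, the
diastolic interval, the recovered gate). `invert_markers()` /
`leading_order_markers()` are exact algebraic inverses of each other —
a round-trip property tested to $10^{-9}$ — and the simulated plateau
CV agrees with the nominal marker to within 20% across random grid
rows. Two caveats define the domain of validity: rows whose ERP ends up
within about three ladder rungs of 343 ms have no capture plateau at
all (the whole curve is decremental), and rows combining the smallest
$\tau_{in}$ with slow CV produce depolarisation fronts thinner than any
practical mesh. Both kinds are stored in the database as simulated
(their curves are still valid data for fitting); they are simply
outside the plateau-agreement statement.

## The 1D cable and the restitution database

The pacing protocol is the clinical one: a 2-beat drive train at
$s_1 = 470$ ms followed by one premature stimulus, with the coupling
interval descending in 2% steps from 343 ms to 200 ms or loss of
capture (27 rungs). The cable is 10 cm long, stimulated at one end over
0.5 mm with a 2 ms pulse of amplitude 4 ms$^{-1}$ (the clinical
stimulator's pulse width, delivered well above threshold so capture is
tissue-limited). Four recording poles sit centred in the domain: two
bipolar pairs, 2 mm within a pair and 7 mm between pair barycentres.

Numerics follow the standard splitting: forward-Euler reaction substeps
and Crank–Nicolson diffusion on a tridiagonal Neumann system, assembled
once and solved by the Thomas algorithm. Two presets exist —
`"reference"` (dx = 200 µm, dt 10/100 µs, the published discretisation), and `"desk"` (dx = 500 µm, dt
20/200 µs) used by default in tests and database builds; halving dx at
the desk preset moves the plateau CV by under 3%. The drive train is
simulated once and the state checkpointed at every premature-stimulus
time, so a full 27-rung ladder costs one trunk plus 27 short branches
(about 0.6 s per parameter set at the desk preset).

The extracellular potential of the 1D monodomain cable with the
zero-mean convention has the closed form
$\phi_e = (\overline{v_m} - v_m)/2$, so the bipolar electrogram is
$(v_m(b) - v_m(a))/2$. Because this surrogate retains the slow
repolarisation deflection that clinical front-end filters remove, the
cable annotation exploits the known propagation direction: a
depolarisation front passing the proximal pole first deflects the
bipolar trace valley-first, while the preceding beat's repolarisation —
which can fall inside the premature search window at short couplings
and mimics a plausible wave — deflects it peak-first. Valley-only
detection (threshold 5% of the drive train's valley depth) therefore
annotates the activation wave regardless of the repolarisation
deflection's amplitude, and the annotated time is refined to sub-sample
resolution at the half-depth leading edge, because pair CVs over a 7 mm
baseline would otherwise be quantised by the PDE output step (about
2.5 cm/s at the desk preset — comparable to the curve difference
between adjacent database rows).

On the surface, where the wave direction at a bipole is unknown, the
synthetic electrograms are conditioned by a first difference (a
discrete high-pass emulating the clinical filter chain) and the
premature deflection must match the drive beat's polarity — morphology
matching: the premature wave leaves the same source as the drive wave,
so its deflection has the same sign and the opposite-signed
repolarisation is rejected.

The published database sweeps a Cartesian grid of
$30 \times 11 \times 10 \times 16 \times 11 = 580{,}800$ marker
combinations; the enumerator reproduces that count exactly. Building
all rows is a cluster-scale computation, so the shipped tooling builds
strided subsamples; the tests and the acceptance script use a
99-row slice over `cv_max` (40–140 cm/s) × `apd_max` (150–270 ms) with
mid-grid values for the remaining markers, which builds in about a
minute and spans the range of the synthetic cases. Infeasible or
unstable rows are flagged and skipped, never silently dropped.

## Electrogram processing

Per catheter placement (a five-spline, ten-bipole layout), LATs at one
coupling interval are interpolated piecewise-linearly over a Delaunay
triangulation of the electrode positions projected onto their best-fit
plane; the speed is the inverse gradient magnitude per triangle, and
each electrode receives the median over triangles whose centroid lies
within 2.5 cm. The estimator is exact on affine LAT fields (tested to
$10^{-6}$), accurate within 10% on radial waves from a distant focus,
and the median step bounds the influence of a single corrupted
electrode. Speeds above 200 cm/s are discarded as non-physiological —
the conventional mean + 2 SD cut-off of pooled atrial CV
distributions. The ERP at an electrode is the largest coupling interval
that produced no local activation; a non-monotone capture pattern
triggers a warning but the literal definition is applied.

## Fitting with interval-censored ERPs

Each electrode's measured restitution is matched against database rows
by normalised least squares: CV residuals scaled by 200 cm/s, the ERP
residual by the ladder span, plus (in a second pass) a penalty
$\lambda \sum_k ((m_k - \mathrm{med}_k)/s_k)^2$ pulling markers toward
the cohort medians of the first pass ($\lambda = 0.1$ by default —
small enough to flip only near-ties; tie-breaks go to the lowest row
index, making the fit order-invariant and deterministic).

One design choice deserves emphasis: an ERP observed on a discrete
ladder is *interval-censored*. "No capture at 248 ms, capture at
280 ms" locates the refractory boundary anywhere in [248, 280); a
measurement that never lost capture bounds it below the tested floor.
The ERP residual is therefore the gap between the measurement's and the
row's censoring intervals — zero whenever they overlap or touch. A
point-wise ERP difference would penalise physically indistinguishable
observations; in practice it pushed fits one APD grid step away
whenever the surface and cable stimulus geometries disagreed about the
exact capture boundary by a few milliseconds. Rows that are refractory
at a coupling where a CV was measured contribute that full measured CV
as residual (the row predicts no propagating beat there).

On noiseless in-grid synthetic restitutions recovery is exact; with
5 cm/s CV noise, `cv_max` is recovered within one grid step (10 cm/s)
and `apd_max` within one step (15 ms) in at least 90% of seeded trials.

One bias deserves its own correction. The premature front from a remote
entry site is convex, and a convex monodomain front travels slower than
a planar one by `D/r` (the eikonal curvature relation), so the
LAT-gradient estimator reads `c_plane - D/r` at distance `r` from the
source. At realistic mapping distances (4–6 cm) this is 2–3 cm/s —
comparable to the curve difference between adjacent `apd_max` rows, and
enough to pull the fit one grid step off even without noise. The
pipeline therefore refits after correcting each electrode's CVs by
`+D/r`, with `D` taken from the provisional fit and `r` from the
eikonal onset search that the workflow performs anyway. With the
correction, marker recovery on the noiseless homogeneous case is exact.

## Surface model, mapping and simulation

The atrium is an isotropic 2D monodomain shell with heterogeneous
properties. Fitted parameters are extrapolated by Euclidean
nearest-neighbour assignment — per vertex for the cell constants, per
element centroid for the diffusion coefficient, ties to the lowest
electrode id — and element conductivities are binned into 200
equal-width element sets whose representatives are member means, so the
per-element binning error is bounded by range/200. Nearest-neighbour
mapping is idempotent and reproduces the planar Voronoi partition.

Space is discretised with linear (P1) finite elements on the
triangulated surface embedded in 3D, with lumped mass and natural
zero-flux boundaries; stiffness row-sums vanish and the mass sums to
the surface area (both asserted). Time stepping splits as in 1D:
forward-Euler reaction, Crank–Nicolson diffusion solved with
Jacobi-preconditioned conjugate gradients on the constant SPD system.
Presets: `"reference"` (dt 5/50 µs; edge length 215 µm is the published
resolution) and `"desk"` (dt 20/200 µs on ~1 mm meshes). A planar wave
on a uniform desk-scale sheet propagates within 5% of the 1D cable at
matched resolution. The stimulus is the published disk: radius 1 cm,
amplitude 4 ms$^{-1}$, 0.6 ms, membership by Euclidean distance. The
simulated LAT of a vertex is its first upward crossing of $v_{gate}$
during the premature-beat window; vertices that never cross are
blocked. Full drive train plus premature beat is always simulated.

## Eikonal onset search

The effective entry site of a remote pacing wave is found by an
exhaustive graph-eikonal search: per-vertex speeds are the
nearest-neighbour extrapolation of electrode CVs at the longest
coupling; edge traversal time is length over the harmonic mean of the
endpoint speeds; and the mesh graph is augmented with the
opposite-vertex edge of every interior edge, which brings the
worst-case metrication error of arrival times below 8% (tested against
the analytic field). Every vertex is scored as candidate onset by the
mean absolute error of its offset-corrected predicted LATs at the
electrodes; by symmetry of the metric this needs one Dijkstra solve per
electrode rather than one per candidate, and the tests verify equality
with the naive per-candidate loop. The mean-offset correction (computed
LATs shifted by the mean measured-minus-computed difference) removes
the transit time from the real pacing site, exactly as in validation.

## Validation indices

Measured and simulated LATs, pooled over electrodes and coupling
intervals with one global offset per pacing site, are summarised by
the regression line $y = mx + q$ (computed on measured), the Pearson
correlation $r$, the covariance *slender ratio* (minor/major eigenvalue
of the 2×2 covariance — 0 means perfectly collinear agreement), and the
functional-block error: 100 × (simulated-blocked electrode
observations) / (measured LATs), pooled over couplings. Electrode pairs
blocked in simulation are excluded from the regression indices and
counted only in the block error.

## The synthetic study

Because clinical recordings are not public, a synthetic module
generates ground-truth cases: an 8 × 8 cm sheet (1 mm desk mesh) with
Voronoi-patch heterogeneity in `cv_max` (60–120 cm/s pool) and
`apd_max` (150–240 ms pool) at mid-grid values of the other markers;
two boundary pacing sites emulating remote entry (site A, mid-left,
"CS-like", used for fitting; site B, mid-top, "HRA-like", held out);
and five catheter placements (50 bipoles) spread over the sheet with at
least 4 cm stand-off from site A — echoing the clinical finding that a
model needs on the order of 50 well-distributed points, and keeping the
fitted electrodes where the premature front is locally planar so the
gradient CV estimator sees negligible curvature bias. Virtual
electrograms are the conditioned $v_m$-difference surrogate at the
pole pairs; optional LAT jitter and dropout emulate measurement noise;
everything is reproducible bit-for-bit under a fixed seed.

The end-to-end acceptance run fits site-A recordings at six ladder
rungs (343 down to 203 ms, so the ERP is bracketed), maps, localises
each site's onset from its own measured LATs, simulates, and scores
both sites at the three supra-refractory rungs. Predicted LATs are
annotated through the same virtual-electrogram chain as the
measurements: the lag between an electrogram-extremum annotation and a
threshold-crossing time varies with local CV, and comparing across the
two conventions tilts the pooled regression slope by a few percent
even for a perfect model, whereas within one convention it cancels. Validating at shorter
rungs is deliberately avoided in the homogeneous self-consistency
check: near the capture boundary the stimulus-geometry difference
between the ground-truth disk and the localised-onset disk flips
individual electrodes between captured and blocked, which measures the
stimulus representation rather than the personalisation. On the
homogeneous noiseless case the held-out site reproduces measured LATs
with $r > 0.95$, slope within 2% of unity and zero functional block,
and the onset lands within a centimetre of the true entry point.

What the synthetic study does *not* emulate: real atrial anatomy and
wall curvature, fibre anisotropy, fractionated or low-voltage
electrograms, catheter contact noise, far-field ventricular artefacts,
and registration error between electrode positions and the mesh.
Passing these tests therefore demonstrates internal consistency of the
pipeline — generator and simulator share the monodomain physics — not
clinical accuracy.

## Known limitations

* The curvature correction assumes a single onset and takes `D` from
  the provisional fit; with strongly heterogeneous tissue or multiple
  wavefronts the residual bias grows, and without the correction
  `apd_max` can land one grid step off even noiselessly.
* ERP information is limited by the ladder resolution (~5 ms near the
  floor) and by stimulus geometry; the censored-interval treatment
  makes the fit honest about this rather than more precise.
* The eikonal search assumes a single onset; simultaneous breakthroughs
  would be averaged into one effective site.
* Desk-scale meshes (1 mm, dt 20/200 µs) trade a few percent of CV
  accuracy for tractability; the reference (full-fidelity) presets are available
  through configuration wherever a higher-fidelity run is wanted.
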