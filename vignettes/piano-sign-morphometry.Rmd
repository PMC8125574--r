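---
title: "Quantifying the grand piano sign: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the grand piano sign: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pianoSign)
```

## What the pipeline computes

`pianoSign` simulates the femoral cuts of mechanically aligned total knee
arthroplasty on a distal-femur surface mesh and quantifies the shape of the
anterior resection surface — the "grand piano sign" that surgeons use as a
visual check of femoral component rotation. The pipeline is deterministic
given a mesh, six anatomical landmarks, and a configuration:

1. a canonical knee frame is built from the landmarks (origin at the knee
   center, $+z$ proximal along the mechanical axis to the femoral head
   center, $+x$ medial from the projected epicondylar segment, $+y$
   anterior); left knees produce a left-handed anatomical triad, so
   expressing geometry in frame coordinates mirrors them onto a single
   right-knee convention and all medial/lateral logic is single-pathed;
2. a rotational reference axis is computed (sTEA, Whiteside's line's
   perpendicular, FEA, or PCA);
3. the distal cut is taken perpendicular to the mechanical axis at a depth
   of 9 mm above the most distal vertex, and the anterior flange cut is
   flexed 3° and placed tangent to the anterior cortex within a band
   25–45 mm above the distal cut;
4. the anterior cut face is reduced to a height profile $h(u)$ — the
   in-plane perpendicular distance from the distal cutting line to the
   proximal boundary of the face at mediolateral coordinate $u$ (medial
   positive) — from which the measurements `LatL`, `MedL`, `MedL/LatL`,
   `ML`, `M'L'`, `M'L'/ML`, `LD`, `LD/ML` and the double/single-peak class
   are derived.

## Anterior plane placement

The placement of the anterior flange along the anteroposterior direction is
the one step a planning system normally ties to a specific implant's flange.
The package instead uses **anterior-cortex referencing**: the flange plane
passes through the most anterior mesh vertex (in the flange-normal
direction) whose height above the distal cut lies in a configurable band
(default 25–45 mm). This is the standard "no notching" surrogate — by
construction the plane does not violate the cortex within the band — and it
is fully deterministic without any implant geometry. Absolute lengths on the
cut face depend on this choice; the dimensionless ratios are much less
sensitive, which is why the ratio `MedL/LatL` carries the shape
classification. A posterior resection depth is recorded in the configuration
for completeness but not applied: under anterior referencing it cannot
affect the anterior section.

The distal section that defines `ML` is measured along the anatomical
mediolateral axis, so `ML` is identical for every rotational reference; the
anterior section is expressed in the component's own frame ($u$ along the
component ML axis, $v$ along the flexed proximal axis), which is the
coordinate language of all profile measurements.

## Profile measurements and the peak/inflection rule

The profile is rasterized on a $u$ grid with 0.25 mm step and smoothed with
a 2 mm moving average. The central valley is the minimum of the smoothed
profile over the middle third of the section. The lateral peak is the
highest local maximum lateral of the valley (a profile with no lateral
maximum cannot be classified and raises an error). A medial local maximum
with topographic prominence of at least 0.5 mm is a *definite medial peak*
(shape class `double_peak`); otherwise the medial feature falls back to the
most medial concave-to-convex transition of the smoothed second difference
medial of the valley (`single_peak`). The 2 mm window and the 0.5 mm
prominence threshold operationalize the otherwise subjective phrase
"definite medial peak"; both are configurable, and the defaults are well
below the millimetre-scale spread reported for these measurements in the
clinical literature, so they act as noise guards rather than as substantive
cutoffs. "Distance to the distal cutting line" is measured within the
anterior plane; measuring along the mechanical axis instead would differ by
the factor $\cos 3^\circ \approx 0.9986$, so the convention matters only
for exactness, and it is fixed once here.

`LD` is signed, lateral positive (published cohorts include negative
values), and is the offset between the midpoints of the `ML` and `M'L'`
intervals.

## The synthetic femur

Clinical meshes used in the motivating work are private, so the package
ships a parametric generator whose outputs carry exact ground truth. The
bone is an implicit solid (negative inside), the smooth union of

* a shaft whose anterior cortex is a convex parabolic bow (apex 24 mm
  proximal of the knee center) — convexity matters: it guarantees that the
  3°-flexed tangent plane touches the cortex at one point and stays clear
  of it everywhere else, which is what produces the classic two-lobed face;
* two condylar spheres whose sagittal great circles are the true
  flexion–extension circles (their centers are the FEA ground truth), set
  back 3 mm behind the cortex line;
* two anterior facet prisms meeting at the midline, of heights `hAntMed`
  and `hAntLat` above the trochlear groove floor, receding proximally at
  0.55 mm/mm;

minus a V-groove wedge (the trochlear groove, default depth 5 mm over a
20 mm proximal run, apex angle 125°) and an intercondylar notch box, plus
band-limited surface noise. The condyles and facets are blended with a
1.2 mm soft-minimum; the shaft joins crisply so that the anterior cortex is
exactly the analytic bow — a soft blend there would bulge bone through the
tangent flange plane and contaminate the face with a spurious central
tongue. The noise is a sum of six random-direction sinusoids with
wavelengths drawn from 8–14 mm and amplitudes summing to one, so
`noiseAmplitude` bounds the maximum surface displacement; it emulates
smooth, osteophyte-free cortical undulation only.

The mesh is the zero level set extracted by marching tetrahedra on a
regular grid (default voxel pitch 0.8 mm — the single fidelity knob; the
six-tetrahedra cube decomposition tiles space consistently, so the mesh is
watertight whenever the field is positive on the grid boundary, which the
builder asserts). Landmarks are placed analytically: epicondyles on the
condylar spheres (with small angular offsets emulating landmark
variability), the groove-deepest point on the wedge apex line, the
notch-highest point on the notch roof, the knee center at the origin and
the femoral head center 400 mm proximal.

Two sex archetypes draw parameters from truncated normals. Their means echo
published sex contrasts — mediolateral width 73 vs 84 mm, condylar radii
about 21 vs 24 mm, anterior facet heights 6.1/6.7 mm (medial/lateral,
female-like) vs 6.7/8.3 mm (male-like), so the female-like archetype has
the larger medial-to-lateral facet ratio — but they are documented
stand-ins for testing, not population claims. What the generator does *not*
emulate: osteoarthritic deformity and osteophytes, cartilage, the
lateralized trochlear groove of real femurs (its groove is on the midline,
so the generator's lateral deviations scatter around zero rather than
around the positive values seen clinically), patellar anatomy, and cortical
thickness. Passing tests on synthetic cohorts therefore validate the
geometry and statistics of the pipeline, not anatomical realism.

## Reference axes

* **sTEA** and **Whiteside's line** come directly from landmarks;
  Whiteside's rotation reference is the line rotated −90° about the
  mechanical axis in the axial plane, oriented medially.
* **FEA**: for each condyle the posterior apex seeds two orthogonal Kåsa
  circle fits — a coronal fit over the posterior belt in a thin axial slab
  (restricted to within 10 mm of the apex so a large contralateral condyle
  crossing the midline cannot contaminate it), which fixes the condyle's
  mediolateral position, and a sagittal fit over the posterior-distal arc
  in a 2.5 mm slab through that position (with one trimmed refit pass at
  twice the rms residual). The closed-form Kåsa fit is used rather than an
  iterative geometric fit: on the dense, nearly-noise-free condylar arcs
  its algebraic bias is negligible. How the original study selected the
  support points of its "best-fitted circles" is not stated anywhere; the
  slab-and-arc rule here is an explicit, configurable assumption, validated
  against generator ground truth (sub-millimetre recovery in the test
  suite).
* **PCA**: the tangent line through the most posterior vertex of each
  condylar band.

Signed axial angles are positive for external rotation (the medial end of
an ML axis moving anteriorly); the convention is defined once in
`axialAngleBetween` and used everywhere, including the rotation sweep.

## Statistical conventions

The cohort layer fixes the conventions that the clinical-statistics
vocabulary leaves open: Student's t is the pooled-variance form (two
identical constant samples give $t = 0$, $p = 1$ by convention); the
chi-square for shape-type proportions is Pearson's without continuity
correction on the 2×2 counts; the reference comparison is a one-way ANOVA
across references (with the documented caveat that references are paired
within knees, so this is conservative); Bonferroni correction multiplies p
by the number of pairs, capped at 1, and the ordering string joins
mean-sorted groups with ">" when the corrected p of the adjacent pair is
below α and "=" otherwise; reliability uses ICC(2,1) — two-way random
effects, absolute agreement, single measurement — since "the intraclass
correlation method" does not pin down a form. Every test is checked against
a hand-computed textbook oracle in the test suite. On the published
shape-type counts (119/83 women, 32/33 men) neither the corrected nor the
uncorrected Pearson p equals the p printed in the motivating study, whose
row totals are also internally inconsistent; the package reproduces the
computation, not the printed value.

## Numerical choices and degenerate inputs

* Mesh–plane sectioning intersects triangle edges exactly and chains
  segments by shared-edge keys; vertices exactly on the plane are nudged by
  $10^{-12}$; open chains (non-watertight patches) are bridged when the gap
  is below 0.5 mm and dropped otherwise; loops under 1 mm² are discarded
  (this also removes the measure-zero tangency sliver of the anterior
  plane). Binary STL round-trips can collapse near-duplicate vertices
  through float32 rounding; welding drops the resulting degenerate
  triangles, which preserves closedness.
* The distal clip of the anterior face is exact polygon clipping against
  the distal plane's trace (a horizontal line in flange coordinates), not a
  mesh re-cut — the two are mathematically identical for sections.
* Meshes with a bounding box above 1000 units are rejected with a unit hint
  (metre-scale input); watertightness is warned about, not fatal.
* Collinear circle-fit input, coincident landmarks, empty condylar bands,
  a rotational reference parallel to the mechanical axis, planes that miss
  the mesh, and monotone profiles all raise typed errors
  (`pianoSign_schema_error`, `pianoSign_geometry_error`,
  `pianoSign_stats_error`), which the command-line interface maps to exit
  codes 2/3/4.

## Validation scales

The test suite and the acceptance script validate on sizes chosen for a
single CPU: sectioning-vs-implicit-oracle agreement (3 % tolerance) on 8–10
femurs at 1.0 mm pitch; FEA recovery on 6 noise-free and 10–12 noisy femurs
(1.0 and 2.0 mm tolerances); the rotation sweep over −5…+5° in 1° steps;
type-I calibration over 1000 null t tests; and planted-effect power over
12–20 cohort replicates of 24 + 24 knees at 1.6 mm pitch with a +1.0 mm
shift planted on the female-like medial facet height. The planted shift is
a configured experimental effect on top of the archetype defaults; at these
cohort sizes it is recovered essentially always, and the acceptance
criterion asks for at least 80 % of replicates.

## Known limitations

* The anterior-cortex referencing rule, the distal-face convention for
  `ML`, and the FEA point-selection rule are explicit assumptions where the
  clinical workflow is under-specified; all are configurable.
* The generator's lateral deviation distribution is centered near zero
  (midline groove), unlike clinical cohorts; absolute lengths depend on the
  flange placement rule.
* Generated cohorts rarely produce single-peak (boot-shaped) faces under
  default parameters; the inflection fallback is exercised with constructed
  profiles in the tests.
* Segmentation is out of scope: the pipeline starts from meshes and
  landmarks, and landmark uncertainty is taken as given input.
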