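# pianoSign

Virtual femoral resection and anterior resection-surface morphometry for
mechanically aligned total knee arthroplasty (TKA).

## The problem

In mechanically aligned TKA, the femoral component must be rotated correctly
about the femur's long axis; malrotation causes flexion-gap asymmetry,
patellar maltracking and anterior notching. After the anterior (flange) cut,
surgeons inspect the shape of the cut face: with proper external rotation the
face shows the **grand piano sign** — a two-lobed outline with a larger
lateral and a smaller medial lobe. The judgment is subjective, so a
quantitative version of it is useful both for surgical planning studies and
for implant design.

`pianoSign` implements that quantification as a reproducible pipeline:

1. **Rotational references** on a distal-femur surface mesh: the surgical
   transepicondylar axis (sTEA, lateral epicondylar prominence to medial
   epicondylar sulcus), Whiteside's line (WSL, deepest trochlear groove
   point to highest intercondylar notch point) with its perpendicular
   rotation reference, the flexion–extension axis (FEA, the line joining
   the centers of circles fitted to each condyle's sagittal posterior
   profile — Kåsa least squares), and the posterior condylar axis (PCA).
2. **Virtual resection**: a distal cut perpendicular to the mechanical axis
   9 mm above the most distal condyle, and an anterior flange cut flexed 3°,
   referenced to the anterior cortex (tangent within a 25–45 mm band above
   the distal cut — the no-notching surrogate for implant-driven flange
   placement).
3. **Morphometry** of the anterior cut face, reduced to a height profile
   h(u) above the distal cutting line: lateral length `LatL`, medial length
   `MedL` (peak, or inflection when no definite medial peak exists, with a
   0.5 mm prominence criterion), `MedL/LatL`, the mediolateral widths `ML`
   (distal cut) and `M'L'` (anterior cut), `M'L'/ML`, the lateral deviation
   `LD` of the midlines, `LD/ML`, and the double/single-peak shape class.
4. **Cohort statistics**: pooled Student t, Pearson chi-square (no
   continuity correction), one-way ANOVA with Bonferroni pairwise ordering
   strings (e.g. `FEA > sTEA > WSL`), and ICC(2,1) reliability.
5. **A synthetic distal-femur generator** — an implicit-surface model
   (smooth union of shaft, condylar spheres and anterior facet prisms,
   minus trochlear groove and intercondylar notch, plus bounded smooth
   surface noise), polygonized by marching tetrahedra — with analytic
   landmark and axis ground truth, female-like/male-like sex archetypes,
   left/right sides and randomized rigid pose. Every pipeline stage is
   validated against this ground truth.

## Worked example

```r
library(pianoSign)

## a synthetic knee with known ground truth
params <- sampleFemurParams("female-like", seed = 42, noiseAmplitude = 0.4)
knee <- buildFemur(params, pitch = 0.8)

## measure the anterior resection surface for three rotational references
m <- measureKnee(knee$mesh, knee$landmarks, references = c("stea", "wsl", "fea"))
print(m, digits = 4)
#>       LatL  MedL MedL_LatL    ML  MpLp MpLp_ML_pct      LD LD_ML_pct
#> stea 25.35 16.48    0.6503 68.06 55.53       81.59  0.4810    0.7068
#> wsl  25.45 16.39    0.6442 68.06 55.52       81.58 -0.3036   -0.4461
#> fea  25.45 16.41    0.6448 68.06 55.52       81.58 -0.3055   -0.4489
#>            shape reference
#> stea double_peak      sTEA
#> wsl  double_peak       WSL
#> fea  double_peak       FEA
```

`LatL` and `MedL` are the heights (mm) of the lateral and medial lobes of
the cut face above the distal cutting line; their ratio `MedL_LatL` is the
shape index of the grand piano sign (larger lateral lobe → ratio < 1, and
external rotation of the component lowers it further). `ML` and `MpLp` are
the mediolateral widths (mm) of the distal and anterior cut faces, `LD` the
lateral offset of their midlines, and `shape` the double/single-peak class
(this knee has a definite medial peak).

Published anterior condylar heights reproduce their medial-to-lateral
ratios:

```r
medLatRatio(6.7, 8.3)   # 0.81 (men)
medLatRatio(6.1, 6.7)   # 0.91 (women)
```

A cohort study over synthetic knees, with summary tables:

```r
records <- runCohortStudy(24, 24, seed = 1, references = c("stea", "wsl", "fea"))
summarizeCohort(records)   # MedL/LatL by sex and reference, widths, shape counts
```

A command-line interface (generate / measure / cohort / sweep) ships in
`inst/scripts/pianoSign-cli.R`.

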