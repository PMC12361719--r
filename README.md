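# mtlseg

Landmark-based segmentation protocol for the **anterior medial temporal
lobe (MTL) cortices** — entorhinal cortex (ERC) and Brodmann areas 35
and 36 — on coronal slices.

The anterior MTL cortices, and BA35 (transentorhinal cortex) in
particular, are among the first sites of tau pathology in Alzheimer's
disease, yet their cytoarchitectonic borders are invisible on MRI.
A practical protocol therefore expresses each border as a rule relative
to anatomical landmarks that *are* visible on MRI: the superior edge and
crown of the parahippocampal gyrus (PHG), the medial edge, banks and
fundus of the collateral sulcus (CS), and the crown of the fusiform
gyrus (FG), with everything anchored anterior-posteriorly to the
anterior tip of the hippocampus.

`mtlseg` implements that whole workflow as testable code:

1. **Geometry** (`SliceContour`, `deriveLandmarks`): coronal pial
   contours parameterized by arc length; all protocol landmarks,
   including bank and crown fractions measured *along the cortical
   ribbon*; CS depth (fundus to mouth-chord midpoint) with the
   shallow/deep dichotomy at 7 mm.
2. **Synthetic cohort** (`cohortConfig`, `generateCohort`): a seeded
   phantom generator emulating per-case anterior extents (median/SD
   parameterized; defaults ERC 4.75/1.58, BA35 9.25/2.60, BA36
   10.25/3.84 mm relative to the hippocampus tip), anchor-structure
   positions, shallow/deep sulcal anatomy, and ground-truth borders
   placed by a rule table plus between-case noise.
3. **Measurement** (`measureCohort`, `signedBorderDistance`): signed
   arc-length distances from borders to landmarks on the six reference
   levels (10, 9, 7, 5, 4, 2.5 mm anterior) and on each region's first
   slice; anterior-extent distances to five candidate anchors.
4. **Rule derivation** (`summarizeDistances`, `selectAnchor`,
   `quantizeToGrid`, `roundOffset`, `deriveRuleTable`): anchor selection
   by summed between-subject SD with an MRI-identifiability tie-break;
   start distances quantized to the slice grid
   (4.75 → 5.2, 9.25 → 9.1, 10.25 → 10.4 mm at 1.3 mm); offsets rounded
   to whole millimetres (7.19 → 7, 9.96 → 10, −5.40 → 5).
5. **Segmentation engine** (`segmentCase`, `applyRulesSlice`): a
   deterministic rule engine that turns a landmark-annotated slice
   stack plus a `RuleTable` into non-overlapping labeled arc-length
   intervals (with the medial BA35 flank embedding the emerging ERC on
   its first slice), plus rasterization and NIfTI/ITK-SNAP export.
6. **Evaluation** (`dsi`, `reliabilityExperiment`, `compareGroups`):
   Dice Similarity Index in interval and raster modes, label
   area/volume, landmark-perturbation reliability (a stand-in for
   re-tracing variability), and descriptive group comparisons
   (shallow vs deep CS, disease vs no disease).

The published protocol itself ships as `defaultRuleTable()`.

## Worked example

Generate a zero-noise phantom cohort from the protocol, re-measure it,
re-derive the rules, segment it, and probe reliability:

```r
library(mtlseg)

rt  <- defaultRuleTable()
coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 20, seed = 101))
coh
#> MTLCohort: 20 cases, 20 contour stacks, 560 truth borders (0 clamped)

m   <- measureCohort(coh)
drt <- deriveRuleTable(summarizeDistances(m$distances),
                       summarizeExtents(m$extents))
drt
#> RuleTable (anchor: hippocampus, thickness 1.30 mm, posterior bound 2.60 mm)
#> starts: ERC 5.2, BA35 9.1, BA36 10.4 mm
#> levels: 10, 9, 7, 5, 4, 2.5 mm; 28 border rules, 1 flank rule(s)
rulesEqual(rt, drt)
#> [1] TRUE

maps <- segmentCohort(coh, rt)
maps[["case001"]]
#> LabelMap case001: 17 intervals on 7 slices
#> total ribbon length (mm): BA35 110.6, BA36 77.0, ERC 29.7

rel <- reliabilityExperiment(coh, rt, sigma_mm = c(0, 0.5),
                             n_reps = 5, seed = 1)
rel
#>  sigma_mm label  mean_dsi      sd_dsi   n
#>       0.0  BA35 1.0000000 0.000000000 100
#>       0.5  BA35 0.9750020 0.006087946 100
#>       0.0  BA36 1.0000000 0.000000000 100
#>       0.5  BA36 0.9668558 0.008842967 100
#>       0.0   ERC 1.0000000 0.000000000 100
#>       0.5   ERC 0.9494664 0.015549347 100
```

Reading the output: the derivation recovers the generating rule table
exactly (starts at the protocol's 5.2 / 9.1 / 10.4 mm with the
hippocampus re-selected as anchor), the engine reproduces the
ground-truth label maps (DSI 1 at zero jitter), and a 0.5 mm landmark
jitter costs a few percent of Dice overlap — most for ERC, the smallest
label, which the DSI penalizes hardest.

A thin CLI over the same functions lives at `inst/cli/mtlseg.R`
(`generate`, `measure`, `derive-rules`, `segment`, `evaluate`).

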