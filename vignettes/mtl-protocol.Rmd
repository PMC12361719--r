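---
title: "Deriving and applying a landmark-based protocol for anterior MTL cortices"
author: "mtlseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a landmark-based protocol for anterior MTL cortices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlseg)
```

## The problem and the model

The anterior entorhinal cortex (ERC) and Brodmann areas 35 and 36 are
early targets of tau pathology, but their cytoarchitectonic borders are
invisible on in vivo MRI. A usable segmentation protocol therefore has
to re-express each border through anatomical landmarks that *are*
visible: the superior edge and crown of the parahippocampal gyrus
(PHG), the medial edge, banks and fundus of the collateral sulcus (CS),
and the crown of the fusiform gyrus (FG). Anterior-posterior placement
is anchored to a reference structure; the anterior tip of the
hippocampus is the natural choice because region-to-hippocampus
distances have low between-subject variability and the hippocampus is
easy to delineate on MRI.

`mtlseg` models one coronal slice as a polyline contour of the pial
surface, ordered medial to lateral and parameterized by arc length
(`SliceContour`, `arcLengthPositions`). All landmark positions and
border placements are arc-length positions on this contour
(`LandmarkSet`); a segmentation is a set of labeled, non-overlapping
arc-length intervals per slice (`LabelMap`). The protocol itself is a
`RuleTable`: region start distances on the slice grid, six reference
levels (10, 9, 7, 5, 4 and 2.5 mm anterior to the hippocampus tip),
and per (level, region, side) either a landmark rule — landmark name,
whole-millimetre offset, direction — or a reference rule stating that
the border is shared with an adjacent region (e.g. BA36's medial border
*is* BA35's lateral border on posterior slices).

Two structural features deserve mention. First, on the first slice on
which ERC appears, it is embedded between two segments of BA35; the
engine emits a medial BA35 "flank" interval between an offset rule
(5 mm medial to the superior PHG edge) and the ERC medial border. The
anatomical window for this configuration is about 1 mm, less than one
1.3 mm slice, so the flank is applied on exactly one slice. Second,
labels end posteriorly at 2.6 mm by default — the first slice strictly
anterior to pre-existing posterior labels that begin 1.3 mm anterior to
the hippocampal head; this bound is configurable.

## Design choices where the procedure was genuinely open

* **Bank and crown fractions are arc-length fractions.** "Halfway point
  of the medial bank" or "midpoint of the crown" could be read as
  Euclidean or depth fractions; we measure them along the pial contour
  because the borders being placed live on the cortical ribbon.
* **CS depth** is the Euclidean distance from the fundus vertex to the
  midpoint of the chord joining the two sulcal mouths; the
  shallow/deep dichotomy is strict at 7 mm (a depth of exactly 7 mm is
  deep, since "shallow" means *below* 7 mm).
* **FG crown midpoint** is realized as the arc-length midpoint between
  the lateral CS mouth and the lateral contour terminus (which the
  phantom places at the medial mouth of the next sulcus); no
  operational definition exists elsewhere.
* **Offset directions.** The measurement stage reports signed
  distances (positive = border lateral of the landmark). For the
  offset-bearing BA35 medial cells the measured signs and the
  protocol's verbal direction ("medial to the superior PHG edge")
  disagree at two levels; the emitted rule follows the protocol wording
  by default (`direction_policy = "template"`), and a `"measured"`
  policy derives the direction from the sign of the median instead.
  The medians are preserved in the rule table's provenance either way.
* **BA36's medial border on its first level** follows the "halfway
  point of the *medial* bank" definition, which matches both the
  measured cells and the qualitative description; the alternative
  "lateral bank" reading contradicts them.
* **Only the offset-bearing cells are numerically derived.** Start
  distances and the three BA35 medial offsets are computed from
  medians; the remaining borders are qualitative landmark assignments
  whose measured medians (often a millimetre or two from zero) are
  recorded as provenance but deliberately do not perturb the rules —
  the protocol trades that residual bias for simplicity and
  reproducibility. A consequence is that derivation is idempotent for
  rule tables sharing this offset structure (the shipped protocol),
  not for arbitrary tables.
* **Reference-rule fallback.** If a slice's level carries a reference
  rule to a region absent on that slice (possible only off the
  canonical grid), the dependent region absorbs the absent region's
  territory by chaining to its medial rule, keeping the ribbon
  partitioned.

## The synthetic cohort: what it emulates, and what it does not

`generateCohort()` draws phantom cases with:

* **Anterior extents** per region, location-scale distributions with
  location = configured median and scale = configured SD (defaults
  ERC 4.75/1.58, BA35 9.25/2.60, BA36 10.25/3.84 mm). The default is a
  shifted normal matched to median and SD; a shifted log-normal matched
  to the same median and SD is available because measured extent means
  and medians differ, suggesting skew. All three extents share a latent
  per-case component (`extent_shared_sd`, default 1 mm) representing
  overall anterior MTL scale.
* **Anchor structures** as scalar axial positions: hippocampus tip at
  0 (the axis origin), amygdala tip near 4 mm anterior (tracking the
  shared extent component, which makes region-to-amygdala SDs slightly
  the lowest), temporal pole, limen insulae and the CS anterior tip
  with progressively larger SDs. This reproduces the anchor-comparison
  structure: amygdala wins on SD but is flagged hard to identify on
  MRI, so anchor selection falls to the hippocampus. Anterior anchors
  are measured as position − extent (hence negative limen distances
  for BA35/BA36); the limen sign convention is a config switch.
* **Sulcal anatomy**: each case is shallow (depth drawn on 3–6.5 mm)
  or deep (7.2–11 mm) with probability `fraction_deep_cs` (default
  0.5, matching a 10/10 split at n = 20; a stratified option makes the
  split exact), and per-case contour shape parameters (crown widths,
  bank bowing, fundus tilt) drawn from ranges chosen so that every
  contour keeps at least 12 mm of ribbon medial of the superior PHG
  edge — medial offsets up to 10 mm must stay on-contour.
* **Ground-truth borders** at rule positions plus independent Gaussian
  noise (`border_sd_mm`, default 2 mm, the order of the posterior
  border-cell SDs); off-contour draws are clamped to the terminus and
  counted. A disease flag (default fraction 11/20) is sampled but has
  no effect on borders, making the generator an exact null for the
  group comparisons.

Each case has its own RNG substream derived from the cohort seed
(Mersenne-Twister, inversion sampling), so cohorts are reproducible
byte-for-byte and enlarging `n_cases` never changes earlier cases.

The phantom is deliberately schematic: in-plane anatomy is constant
along the anterior-posterior axis within a case, there is a single
collateral sulcus with no branching, no histology/MRI registration
error, and rater variability enters only through the landmark-jitter
model. Passing tests therefore demonstrate that the *pipeline* —
measurement arithmetic, derivation rules, engine determinism, DSI
behavior — is correct under the stated statistical structure; they say
nothing about segmenting real MRI, and the published cross-validation
accuracy of automated segmentation on real scans is explicitly not
reproduced here.

## Numerical choices

* Start distances quantize to the slice grid as
  `thickness × round(median / thickness)` with exact half-grid ties
  away from zero; offsets round magnitudes to whole millimetres, ties
  away from zero. These are the only roundings consistent with the
  three printed quantizations (4.75 → 5.2, 9.25 → 9.1, 10.25 → 10.4 at
  1.3 mm) and the printed offsets (7.19 → 7, 9.96 → 10, −5.40 → 5).
* Medians use the midpoint of the central pair for even n; SDs use the
  sample (n − 1) formula.
* A slice maps to its nearest reference level; equidistant ties
  resolve posterior, consistent with the protocol's posterior
  anchoring. The same posterior tie-break picks the measurement slice
  nearest each reference level.
* Landmark ordering is enforced to 1e-9 mm; degenerate (inverted)
  intervals are an error in the engine and are dropped with a count in
  noisy ground truth. Perturbed landmark sets are re-sorted and clamped
  to the contour domain to preserve the ordering invariant.
* Rasterization assigns each voxel to the nearest arc-length sample
  within half the ribbon thickness, which guarantees adjacent intervals
  never double-label a voxel; interval-mode and raster-mode DSI then
  agree to within a few voxel widths over the shortest interval.
* Both-empty DSI is defined as 1 (flagged): two segmentations agreeing
  that a region is absent agree.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the
statistics decisive while keeping a laptop-scale run: distributional
recovery of the extent medians at n = 2000 (±0.1 mm), zero-noise
round-trip and engine-vs-truth Dice at n = 20, derived-offset recovery
under 2 mm border noise at n = 200 (±1 mm, the integer-rounding
resolution), reliability monotonicity on 6 cases × 5 repetitions over
jitter SDs 0–1 mm, and 300–1000-draw property checks for the DSI
axioms and landmark perturbation.

## Limitations

* Contours arrive with key vertices tagged; detecting them on raw MRI
  or unannotated polylines is out of scope, as is 3-D reconstruction
  between slices and any multi-atlas machinery.
* The generator's anchor positions are scalars; no amygdala or
  temporal-pole geometry is drawn, so anchor selection is tested on
  distance statistics only.
* Hemisphere effects have no synthetic analogue: all contours are
  processed in a canonical medial-to-lateral orientation
  (`mirrorContour` brings the opposite handedness into it).
* Intracranial-volume normalization of label volumes is not modeled.
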