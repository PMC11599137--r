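---
title: "Methods: cell-shape morphometrics, morphoclass dynamics and gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-shape morphometrics, morphoclass dynamics and gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscmorph)
```

# Scope and model

`gscmorph` implements the quantitative arm of a glioblastoma-stem-cell (GSC)
morphology study as a reusable pipeline.  Its inputs are integer label masks
from an external segmentation step (the segmentation network itself is out
of scope), tabular time-lapse tracks, and gene × cell-line expression and
CRISPR-dependency tables.  Three analysis layers sit on top:

1. **Per-cell morphometrics** — whole-cell shape descriptors (area,
   perimeter, moment-ellipse axes, eccentricity), skeleton-based protrusion
   metrics (primary/total counts, geodesic lengths, branching index) and
   Sholl profiles.
2. **Morphoclass dynamics** — rule-based assignment of the four GSC
   morphoclasses (nonpolar, flat polar, circular multipolar, elongated),
   interphase transition and mitotic inheritance matrices from tracks,
   mitotic somal translocation (MST), tumor–tumor-connection (TTC) density
   and the neurosphere invasion index.
3. **Gene prioritization** — the data-driven selection statistics that
   single out a candidate morphoregulator from omics tables: gene-list
   intersection, upper-tail hypergeometric (one-sided Fisher) enrichment,
   bimodal expression gating by a two-component Gaussian mixture, anchored
   dependency scaling with core-fitness exclusion, and a
   signature-correlation consistency test.

A first-class synthetic-data module plants exact ground truth for every
layer, so the whole pipeline is testable without microscopes or external
databases.

# Morphometrics

## Coordinates and rasterization

All images are `(row, col)` matrices with 1-based indices, the R
convention; a pixel is "inside" a shape when its center is.  Physical
calibration is carried as micrometres per pixel; because the TIFF writer
available in this stack does not persist resolution tags, the pixel size
round-trips through a JSON sidecar next to each mask (a missing sidecar
falls back to 1 µm/px with a warning).

## Crops

Each labelled cell is re-centered in a square crop whose side is the
largest bounding-box side over all kept cells (plus 2 px padding, forced
odd so an exact center pixel exists); the cell centroid sits at the crop
center within 1 px.  Labels under `min_area_px` (default 50 px, a
segmentation-fragment filter) are dropped; labels touching the image
border or consisting of several components are kept but flagged, and the
default pipeline skips flagged cells.

## Shape descriptors

Axis lengths follow the moment-equivalent-ellipse convention: four times
the square root of the eigenvalues of the central second-moment matrix of
pixel centers, so a disk of radius *r* reports major = minor = 2*r*.
Eccentricity is computed from the axis ratio
(`sqrt(1 - (minor/major)^2)`), 0 for a circle, approaching 1 for a line;
degenerate one-dimensional masks are capped at `1 - 1e-12`.  The
perimeter is the traced 8-connected boundary with √2 weighting of
diagonal steps; on a digital circle of radius 20 px this estimator sits
within 5% of 2π·20.  Masks with fewer than 5 pixels are rejected
(degenerate moments), as are multi-component masks.

## Soma and skeleton

The soma center is the arg-max of the Euclidean distance transform (ties
broken toward the smallest row, then column — a deterministic total
order); the soma mask is the connected component containing the center
after morphological opening with a disk of half the inscribed radius.
Masks nowhere thicker than 3 px cannot carry a soma and are returned
whole, flagged.

Protrusions are measured on a topology-preserving thinning (Guo–Hall,
8-connected) of the mask.  Spurs — endpoint-to-junction chains shorter
than `prune_um` — are removed iteratively; only chains that genuinely end
in a junction are eligible, so real branch ends are never nibbled.  The
skeleton is then split at the soma boundary: every outside component
touching the soma becomes a primary protrusion rooted at the crossing
pixel (attachment sites within 4 px merge into one root, so skeleton
wobble along the boundary cannot double-count a protrusion), and skeleton
endpoints are tips.  **"All protrusions" counts tips**, so one bifurcation
adds one protrusion and the branching index (tips/roots) is ≥ 1 whenever
defined; this operationalizes a ratio that is qualitative in the source
taxonomy and is configurable in principle via the skeleton graph.

Root-to-tip lengths are geodesics along the skeleton.  Two numerical
choices matter here.  First, raw 8-connected chain lengths overestimate
straight lines by up to ~8% (worst at 22.5°), so paths are resampled
every 4 px and chord lengths summed, which brings the bias under ~1% for
the gentle curvatures of cell processes.  Second, the soma-boundary
crossing lies midway between the root pixel (first pixel outside the
soma) and its soma-side neighbour, so each geodesic gains 0.5 px;
without it lengths are systematically half a pixel short.  A detection
floor `min_protrusion_um` (5 µm in the validation panels) discards tips
whose geodesic falls below it: at 1 px skeleton resolution, shorter pokes
at the soma boundary are thinning artefacts, not processes.

Defaults: `prune_um = 1` µm, Sholl step 5 µm — both unstated in the
source procedure and freely configurable.  The validation panels use
`prune_um = 4` µm, matched to the sub-pixel boundary jitter of the
phantoms; real data with heavier segmentation noise would warrant similar
tuning.

## Sholl profile

For radii `inscribed_radius + k·step`, the profile counts 8-connected
components of skeleton pixels on the **digital circle** of that radius —
the pixel ring of half-width √2/2.  A naive 1-px band (|d − r| ≤ 0.5)
is wrong on a pixel skeleton: a diagonal run changes radius by up to √2
per step and can hop such a band entirely, silently undercounting.  Any
path crossing the circle must intersect the digital ring.  Circles are
centered on the distance-transform maximum, not the centroid, which can
fall outside concave cells.

The suite validates profiles against a continuous-geometry oracle (planted
centerlines crossed with each circle).  Equality is asserted only where
the count is well-posed: at least 2 px from any skeleton node (roots,
joints, branch points, tips — a tip is the degenerate limit of a branch
point) and from tangency radii, and outside the stroke merge zone
downstream of branch attachments (strokes of half-widths w₁, w₂ diverging
at angle θ remain one foreground blob until the centerlines separate by
w₁ + w₂, i.e. up to (w₁+w₂)/(2 sin(θ/2)) ≈ 5 px past the junction for
panel geometries; the test excludes [−2, +8] px around branch radii).
Within those zones no finite-resolution method can pin the count.

# Morphoclass assignment and dynamics

The four class definitions are qualitative in the source taxonomy; the
classifier operationalizes them as a first-match rule cascade whose
thresholds are explicit configuration:

1. **nonpolar** — no primary protrusion;
2. **elongated** — eccentricity ≥ 0.85, or longest protrusion ≥ 2 × the
   soma equivalent diameter;
3. **circular multipolar** — ≥ 3 primaries, sub-threshold eccentricity and
   area < 1000 µm²;
4. **flat polar** — everything else (large, flat cells with some
   protrusions).

The precedence mirrors the specificity of the verbal definitions and
makes the function total and deterministic.  Because the source scores
are manual, the acceptance surface is agreement with the *intended* class
of synthetic panels (≥ 90% on 48 class-designed cells), not with human
labels.

Track statistics follow the column contract `cell_id, parent_id, frame,
class, x_px, y_px, mitosis`: a mitosis flag marks a mother's last row and
her daughters reference her via `parent_id`, starting the next frame.
Interphase transition counts exclude the step *into* a mitosis-flagged
frame; "acquiring a new morphology" counts any frame-to-frame class
change (sustained or not — the distinction is unstated in the source and
any debounce window would be arbitrary).  Mitotic inheritance reads the
mother class at the mitosis-flagged frame and the daughter class at her
first frame; denominators per mother class are reported, and the mother
counts sum to the number of mitosis rows by construction.  MST is the
Euclidean nucleus displacement over the single step preceding mitosis.
TTC density is connections per 100 µm of perimeter (TTC identification
itself is manual and enters as a count).  The invasion index is
total neurosphere area over core area (≥ 1, growing with invasion); the
source states both orientations in different places, and the package
follows the figure-legend orientation with a `reciprocal` flag for the
other.

# Gene prioritization

The enrichment of a gene family among k selected genes is the upper-tail
hypergeometric probability P(X ≥ x) with population N, family size n —
identical to the one-sided Fisher exact test; with N = 19,396, n = 3,
k = 30, x = 3 it reproduces the printed 3.34 × 10⁻⁹.  The implementation
wraps R's exact log-space distribution function and is checked against
exhaustive enumeration of all C(N, k) draws for every parameter
combination with N ≤ 12.

The expression gate fits a two-component Gaussian mixture to per-gene
mean log₂(TPM+1) by EM: k-means++-style seeded initialization, best of 10
restarts by likelihood, variance floor 10⁻⁶, iteration cap 500 with a
convergence flag, deterministic given the seed.  "High" genes are those
with posterior > 0.5 for the higher-mean component — the source describes
the gate only as genes "seemingly generated" by the upper distribution,
so the posterior threshold is the natural operationalization, and a
manual cutoff (`manual_threshold`) is exposed since a visual threshold
cannot be excluded.  Identical values raise a degeneracy error rather
than a meaningless gate.

Dependency values are scaled per cell line by
`s(x) = (x − m_non)/(m_non − m_ess)`, where the medians over
non-essential / essential (core-fitness) anchor sets map to 0 / −1.  Only
the −1 anchor is stated in the source; the 0 anchor at the non-essential
median is the conventional second point and is documented as such.  The
full prioritization gates on expression, excludes core-fitness genes,
scales dependency, and ranks by minimum scaled depletion across lines;
"context-specific essentiality" is operationalized as
`median(scaled) − min(scaled)` (high when one line dominates).  Both
catalogue choices — the core-fitness list and the anchor sets — enter as
inputs, since the source cites external resources for them.

The signature-correlation test standardizes expression per gene,
takes the upper triangle of the all-pairs Pearson matrix as the null, and
compares the focal gene's correlations with the up- and down-regulated
signature sets against that null with two-sample t tests (Welch).
Constant-expression genes are excluded with a warning.

# The synthetic-data module

The generator is the package's source of ground truth, not a fixture: it
plants known topology and parameters and records them exactly.

**Cells** are an elliptical soma (minor semi-axis 8–14 px, aspect ≤ 1.5)
with 0–6 protrusions: stroked polylines (half-width 1.4–2 px) starting on
the soma boundary, total centerline length 10–60 px, at most two branch
points per cell.  Protrusions are rendered by stroking the centerline
with a disk, so the centerline length *is* the geodesic ground truth;
boundary jitter (Gaussian, SD 0.4 px) applies to the soma polygon only,
never to centerlines.  Branch-carrying protrusions are planted as single
30–60 px segments with branches of 15–30 px at 0.8–1.3 rad, attached so
that ≥ 9 px of parent remains beyond the junction — a 2–4 px parent stub
past a branch point is unresolvable at 1 px skeleton resolution and would
not be scored as a separate protrusion by a human either.  Primary
origins occupy distinct angular slots, since two protrusions emerging
fused are one protrusion by any operational definition.  Rendering is
bit-reproducible given (spec, seed).

**Tracks** follow a per-frame Markov chain over the four classes, with
per-frame division probability 0.005 (≈ 40% of cells dividing over a
100-frame movie, matching the live-imaging observation), daughter classes
drawn from an inheritance matrix, and Gaussian nucleus steps (SD 2 px).
The default transition matrix concentrates interphase dynamics in
nonpolar cells (diagonal 0.94 vs 0.98 elsewhere) and the default
inheritance matrix mostly conserves the mother class — the qualitative
behavior reported for the control condition; the exact per-frame rates
are not published and these defaults are the package's calibration.

**Omics tables** draw per-gene mean expression from a two-component
mixture (low N(1, 0.25²), high N(6, 1²), high fraction 0.6 — matching the
reported 18-of-29 high split), scatter per-line values around the means
(SD 0.25, clipped at 0 as log₂(TPM+1) must be), and plant anchor sets at
−0.8 / 0 depletion plus one highly expressed, non-core gene holding the
strict minimum of a designated line.  The essential anchors double as the
core-fitness set.

**What the phantoms do not emulate:** optical blur and camera noise,
touching or overlapping cells, intensity variation (masks are binary),
protrusions that genuinely merge or cross, 3-D structure, and
segmentation errors.  Passing the recovery tests therefore demonstrates
the correctness of the measurement chain on resolvable geometry, not
robustness to segmentation failure modes — the flagged-cell mechanism and
the configurable pruning floor are the intended handles for real data.

# Validation problem sizes

The test suite and the acceptance script work at these scales, chosen so
the full suite runs in a few minutes on one core: 200 synthetic cells for
count/length recovery (counts exact on ≥ 95% of cells; ≥ 95% of tip
lengths within max(2 px, 5%), median error ≤ 1 px — the same confidence
framing for both, as a hard supremum over hundreds of random rasterized
tips is not a property any pixel-level method can promise); 50 cells for
Sholl oracle equality at every well-posed radius; ellipse sweeps at
semi-major 20/40/80 px under 5 rotations for eccentricity (±0.02 against
pixel moments, ±0.03 against the continuous value); 500 × 100-frame
tracks for transition/inheritance recovery within 3 binomial SE per
entry; 20 seeds × 500 genes at 4σ separation for the mixture gate
(≥ 95% accuracy); and exhaustive hypergeometric enumeration for all
N ≤ 12.  A 3 SE bound on 16 matrix entries is exceeded by chance in
roughly 4% of seeds; the suite pins the planted-seed conditions, and the
acceptance script reports the observed maximum z so a reader can judge
any single run.

# Known limitations

* The skeleton cannot separate protrusions that merge for most of their
  length, and counts them as one — matching what a human tracer sees,
  but diverging from planted truth if phantoms were built that way.
* Geodesic lengths assume the skeleton tracks the process midline;
  for very wide, short protrusions (length ≲ 2 × width) the medial axis
  geometry distorts lengths.
* The classifier thresholds are calibrated on the synthetic panels'
  geometry; real µm-calibrated data may need different `ecc_threshold`
  and `flat_area_um2_threshold`.
* The EM gate assumes exactly two components; strongly trimodal
  expression would need a model-selection step that is deliberately out
  of scope.
* Transition matrices treat frames as equidistant; irregular time-lapse
  intervals would need resampling before `interphase_transitions()`.
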