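# gscmorph

Quantitative analysis of glioblastoma stem cell (GSC) morphology, its
dynamics, and the omics statistics used to prioritize candidate
morphoregulator genes.

Glioblastoma stem cells exist in four morphoclasses — nonpolar, flat
polar, circular multipolar, and elongated — that echo the morphotypes of
fetal basal radial glia, and their protrusions (including tumor–tumor
connections) shape proliferation and therapy resistance.  Studying this
quantitatively needs three things `gscmorph` provides for users of
segmentation-based imaging pipelines:

* **Per-cell morphometrics** from integer label masks (TIFF):
  centered single-cell crops; area, perimeter, moment-ellipse axes and
  eccentricity; skeleton-based protrusion counts (primary and total),
  geodesic protrusion lengths, branching index; Sholl profiles.
* **Morphoclass dynamics** from time-lapse track tables:
  rule-based class assignment, interphase transition matrices, mitotic
  inheritance matrices, mitotic somal translocation (MST), microtube
  density per 100 µm perimeter, and the neurosphere invasion index.
* **Gene prioritization** from expression / CRISPR-dependency tables:
  gene-set intersection, upper-tail hypergeometric enrichment
  (one-sided Fisher), bimodal expression gating by a two-component
  Gaussian mixture, dependency scaling anchored at the core-fitness
  median (−1) and non-essential median (0), core-fitness exclusion, and
  a differential-expression signature-correlation test.

The key shape statistics, in the field's standard conventions:
eccentricity `e = sqrt(1 − (b/a)²)` from the moment-equivalent ellipse
semi-axes (`regionprops` convention, 0 = circle); branching index
`= n_total / n_primary` (tips over soma-attachment roots, ≥ 1 when any
primary exists); Sholl intersections = skeleton crossings of concentric
circles stepping outward from the soma's inscribed radius; enrichment
`P(X ≥ x)` for `X ~ Hypergeom(N, n, k)`; scaled depletion
`s(x) = (x − m_non) / (m_non − m_ess)`.

A synthetic-data module generates cell masks, tracks and omics tables
with exact planted ground truth (protrusion topology and centerline
lengths, Markov transition/inheritance matrices, mixture components,
anchor medians, a planted context-dependent gene), making every stage of
the pipeline testable end to end.

## Worked example

Build a synthetic cell — a soma of radius 10 px carrying three
protrusions (45, 30 and 35 px), one of which branches — then measure it:

```r
library(gscmorph)

branch <- list(segment = 1L, offset = 0.6,
               spec = protrusion_spec(0.9, lengths = 20))
spec <- cell_spec(soma_radius_px = 10,
                  protrusions = list(
                    protrusion_spec(0.2, lengths = 45, branches = list(branch)),
                    protrusion_spec(2.3, lengths = 30),
                    protrusion_spec(4.4, lengths = 35)),
                  boundary_jitter_px = 0.4, image_shape = c(151L, 151L))
cell <- generate_cell_mask(spec, seed = 42)

res <- analyze_protrusions(as_cell_crop(cell$mask), prune_um = 4)
res$metrics
#> <protrusion_metrics> 3 primary / 4 total, avg 39.4 um, max 48.1 um, branching 1.33

shape <- compute_shape_features(as_cell_crop(cell$mask))
shape
#> <shape_features> area 794.0 um^2, perimeter 342.3 um, axes 87.2 x 56.8 um, eccentricity 0.759

classify_morphoclass(shape, res$metrics, res$soma)
#> [1] "elongated"
```

The three planted primaries and the branch are recovered exactly
(3 primary / 4 total, branching index 4/3), the measured lengths sit
within ~1 px of the planted 45/30/35 + branch centerlines, and the cell
is called elongated because its longest protrusion (48 µm) exceeds twice
the soma equivalent diameter.  The same session reproduces the study's
one desk-checkable statistic, the enrichment of the three-member adducin
family among 30 selected genes out of 19,396:

```r
hypergeom_upper_tail(N = 19396, n = 3, k = 30, x = 3)
#> [1] 3.338935e-09      # printed as 3.34e-9
```

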