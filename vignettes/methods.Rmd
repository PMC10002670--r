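---
title: "Models and methods behind atlasquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atlasquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the geometric and
statistical models it implements, the conventions it fixes where upstream
tools leave them unstated, and what its synthetic-data validation does and
does not establish.

# Geometry: slicing a labeled volume

A section image is placed in atlas space by nine numbers: the origin `o`
(atlas coordinate of the image's top-left corner, voxel units) and two
spanning vectors `u` (width) and `v` (height). Pixel `(x, y)` — 0-based, x
rightward, y downward — samples the atlas at

```
p = o + ((x + 0.5) / width) * u + ((y + 0.5) / height) * v
```

**Conventions fixed here** (upstream registration tools do not publish
whether their anchorings are corner- or center-referenced, so we state ours
explicitly and test against it):

* *Pixel centers*: the `+0.5` terms. This avoids half-pixel drift when maps
  are produced at different resolutions; the test suite includes a
  downscaling-commutation check.
* *Voxel centers at integer coordinates*: voxel `(i, j, k)` (0-based) is
  centered at continuous coordinate `(i, j, k)`, so nearest-voxel lookup is
  `floor(p + 0.5)` per axis (ties round half-up). The axis-aligned
  anchoring `o = (-0.5, -0.5, k)`, `u = (nx, 0, 0)`, `v = (0, ny, 0)`
  reproduces stored slice `k` exactly at native resolution — this identity
  is a unit test.
* Points outside the volume map to region 0 (background). Region IDs are
  categorical, so all resampling is nearest-neighbor; no interpolation of
  IDs ever occurs.

Slicing is verified against a brute-force per-pixel loop on random oblique
anchorings (100 anchorings in the acceptance suite).

# Nonlinear refinement: the anchor-point deformation field

Nonlinear in-plane refinement is specified by anchor pairs: a *target*
position (where tissue actually is) and a *source* position (where the
linear atlas map should be sampled). The published description of the
interactive tool states only that a continuous field covering the whole
image is built from the anchors; the actual interpolant is unpublished. The
model implemented here is a declared stand-in, chosen for being continuous,
exact at anchors, and identity at the image frame:

1. Nodes = anchor target points, each carrying displacement
   `d = source − target`.
2. The four image corners and four edge midpoints are added as
   zero-displacement frame nodes — but only those *not* on or inside the
   convex hull of the targets (and not coinciding with a target). This
   makes the field decay to identity toward uncovered image borders while
   keeping affine anchor configurations exact: four corner anchors
   translated uniformly yield an exactly uniform field, which would be
   impossible if zero-displacement midpoints were retained on the hull
   boundary.
3. Delaunay triangulation of the nodes (via `deldir`), barycentric
   piecewise-linear interpolation of displacements within each triangle.
   Points outside all triangles (only possible outside the frame) get zero.

Exactness at anchors (`≤ 1e-9`), the zero-anchor identity, the
uniform-translation closed form, and label closure under warping (no new
IDs, zero-field conserves per-label pixel counts) are all tested. Warping
is *backward*: output pixel `(x, y)` samples the input at
`(x+0.5, y+0.5) + d(x, y)`, nearest-neighbor. Do not expect
bit-compatibility with the interactive tool's output; the contract is the
stated model, not that binary.

Anchor *targets* must lie within the image (they define the triangulation);
*sources* may fall outside it — they then sample background — because
realistic corrections near the image border displace sources beyond the
frame (the uniform-translation example requires this).

# Quality control scores

Assessments use stereology-style systematic grids: points at
`(ox + i·s, oy + j·s)` strictly inside the image, spacing `s` stated in
atlas voxels and converted via `s_px = s_vox · width / |u|`. Damage uses a
5-voxel grid; registration accuracy a 15-voxel grid (separate grids, as in
practice). The grid origin defaults to `floor(s/2)` in both axes —
deterministic "systematic" sampling; a random origin can be supplied for
systematic-*random* sampling.

Per region and assessment (one rater × one brain):

* `accuracy = acc / (acc + inacc)` — **undefined** when no marker was
  verifiable (e.g. a region marked entirely uncertain). Undefined entries
  are excluded from the mean accuracy and its `n`; this is the documented
  aggregation rule, not a numerical convenience.
* `uncertainty = unc / (acc + inacc + unc)` — always defined when markers
  exist; high uncertainty flags that the accuracy score speaks for a small
  verified part of the region.
* `damage = damage markers / total markers` per section; sections with
  damage **strictly greater** than 0.30 are excluded (a section at exactly
  30% is kept). The filter is order-preserving and idempotent.

Aggregates are means over assessments (not pooled counts — pooling is
offered separately), with SEM = sample SD / √n (n−1 denominator), `NA` for
n < 2. Markers are tallied against the *atlas-registered* region under the
point, since that registration is what is being audited; the alternative
(the rater-identified region) is not implemented.

# Hierarchy collapsing and masks

A customized intermediate hierarchy is a selected set of ontology nodes;
every atlas label maps to its *nearest* selected ancestor-or-self. Nearest
wins when the selection contains both a node and its descendant — the rule
consistent with iteratively moving "one level up" only where verification
fails. Labels with no selected ancestor map to a reserved `UNMAPPED` ID
(−1), are carried through quantification as an explicit row, and appear as
an explicit row in the exported TXT. Background (ID 0) is never mapped.
This also honors the convention that pixels not assigned to any subregion
are labeled by their parent region: selecting the parent pools them with it.

Hemisphere masks split the volume along a declared medio-lateral axis
(configuration, not inference — raw volumes carry no orientation; default:
first axis) at a half-open midline: left = coordinate < midline, right =
the rest, so left and right partition the volume for every midline.

# Regional load and object splitting

`load = 100 · stained px / region px`, where only pixels that are inside
the mask *and* carry a nonzero atlas label contribute to either numerator
or denominator. Stained objects are maximal connected components
(8-connectivity by default — stained somata touch diagonally; 4 is
available). An object overlapping k regions is split: each region receives
exactly its own pixel share and increments its object count by one (no
fractional objects; the upstream tool's split-count semantics are not
published, so this choice is documented rather than asserted). Pixel
conservation — region areas summing to the counted mask, stained sums
matching, UNMAPPED included — is a tested invariant.

Per-brain pooling uses pixel sums over kept sections:
`100 · Σ stained / Σ area`. That is the only definition consistent with
"percent stained area per region area" at the brain level;
mean-of-section-loads is available behind a flag for sensitivity analysis.
Damaged sections are removed before pooling; a region present only in
excluded sections is reported with `NA` load.

# Statistics

* **Method comparison** (linear vs refined registration): paired Wilcoxon
  signed-rank on per-animal regional loads. The source description ("a
  two-way Wilcoxon with strain and age factors") names no defined
  procedure; the paired interpretation is ours and is documented as such.
  Zero differences are dropped (all-zero → p = 1, flagged); for n ≤ 25
  untied |differences| the two-sided p is exact from the signed-rank null
  distribution (verified against full sign enumeration at n = 6: all
  shifts positive gives p = 2/64); otherwise a tie-corrected normal
  approximation (no continuity correction).
* **Age effect**: additive two-factor fixed-effects ANOVA (age + strain),
  Type-II sums of squares — `SS(age | strain)` via model comparison —
  because strain cells are small and unbalanced (1–4 animals per strain).
  Single-strain designs degrade to one-way ANOVA (F = t²); age perfectly
  confounded with strain is flagged, not reported. Age p-values are
  BH-adjusted across regions.
* **FDR**: own Benjamini–Hochberg step-up (`q(i) = min_{j≥i} m·p(j)/j`,
  capped at 1), tested against a brute-force rank-loop oracle and
  `stats::p.adjust`.
* **Expression filter**: keep genes with counts strictly above 10 in
  strictly more than 50% of samples. Both inequalities are strict: a gene
  at exactly 10 everywhere, or above 10 in exactly half the samples, is
  removed.
* **Load–expression correlation**: Pearson r with the t-transform
  (`df = n − 2`) unadjusted; the "multilevel" age-adjusted variant centers
  both variables within age groups and uses `df = n − g − 1`. This is the
  standard construction behind partial/multilevel correlation calls; the
  original analysis's package internals (and its exact df) are unknown, so
  exact p agreement with published values is explicitly not a goal.
  Zero-variance inputs return `NA` with a flag. Groups with fewer than two
  observations are dropped with a warning.
* **Classification**: by the two *uncorrected* p-values at α = 0.05 —
  significant only before adjustment = age-dependent; only after =
  age-independent; both; neither. FDR-adjusted q values are reported
  alongside but do not drive the classification, matching the source
  analysis's rule.

# The synthetic world: what it emulates and what it does not

Generators are deterministic per seed (Mersenne-Twister via a state-saving
wrapper; subsystems derive child seeds by a fixed map). Every emitted file
parses back through the package's own readers — a tested invariant.

* **Atlas**: nested axis-aligned boxes — root, divisions, leaf regions that
  tile the brain exactly, ≥3 ontology levels. Per-leaf voxel counts are
  recorded by box arithmetic, independently of the labeling code.
* **Brain series**: 40 µm sections at the every-24th sampling interval
  (spacing 960 µm; the every-12th variant gives 480 µm), three sections by
  default at desk scale. Objects are axis-aligned blocks (default 3×3 px)
  placed wholly inside leaf regions; ground-truth per-region areas and
  stained pixels are tallied directly from the emitted maps, pixel by
  pixel. Pipeline-recovered loads must be **bit-equal** to this truth (50
  seeded brains in the acceptance suite) — the same validation strategy
  used for the original quantification tool, generalized to the whole
  chain. Optional seeded anchor-point deformations exercise the nonlinear
  path under the same exactness requirement.
* **Raters**: per-marker labels drawn with stated probabilities
  (`p_uncertain`, then `p_correct` among verifiable); aggregated mean
  accuracy must converge to `p_correct` within 3·SEM.
* **Animals**: two age groups of 17 and 20 (the study's group sizes);
  default loads are `N(5, 0.5)` at 6 m shifted by 8 within-group SDs at
  14 m — the stated world for amyloid/glial-like stains, whose age
  increases are near-global and very strong relative to within-group
  spread.
* **Expression**: three gene classes. *Null*: noise. *Load-driven* (the
  age-independent archetype): `beta·z(load | age) + noise` with `beta = 1`
  against noise SD 1 (within-group r ≈ 0.71) and **no marginal age term**
  — by construction, load rises with age while expression does not, which
  is exactly the published phenotype of age-independent correlates.
  *Age-driven* (the age-dependent archetype): a 2-SD expression shift with
  age, conditionally independent of load given age.

**Why these effect sizes (a priori dilution analysis).** For a load-driven
gene the pooled (unadjusted) correlation is the within-group correlation
diluted by the age spread of load: `r_pooled ≈ r_within / sqrt(1 + δ²·p(1−p)·(n/(n−1)))`
with δ the standardized age shift of load. At δ = 8 and r_within ≈ 0.71,
r_pooled ≈ 0.17, comfortably below the n = 37 significance threshold
(≈ 0.33) most of the time, while the adjusted correlation is nearly always
significant — so the expected classification is age-independent. For an
age-driven gene the pooled correlation flows through the shared age factor
(≈ 0.7 here) while the adjusted one centers on zero. These defaults were
fixed by this analysis before the calibration tests were run, and the
acceptance criterion (≥ 80% correct classification over 200 replicates)
measures the pipeline at these stated values; it is not a tuned target.

**What a green suite does not establish.** The generators emulate shapes
and effect structures, not histology: no staining texture, no segmentation
error (masks are consumed as given, as in the real workflow where a pixel
classifier produces them), no curved region boundaries, no section-to-
section registration drift, no real rater psychology, no count overdisperson
beyond the simple log-normal stand-in, and no batch structure in expression
(batch correction and count normalization are out of scope; the package
consumes a normalized matrix). Bit-exact load recovery shows the
bookkeeping chain is exact, not that registration of real tissue is
accurate — that is precisely what the QC scores are for.

# Numerical and I/O choices

* Volumes: raw little-endian int32 + JSON sidecar (shape, voxel size, axis
  order). No NIfTI reader is bundled (none is available in the supported
  dependency set); the sidecar route is the supported interchange format.
* Registration descriptors: the JSON dialect with nine-number `anchoring`
  and optional `markers` `[tx, ty, sx, sy]`; an anchoring of arity ≠ 9, or
  markers without an anchoring, is rejected. Round-trips are lossless.
* Segmentations: 8-bit PNG, 0 = background, 255 = label.
* Custom hierarchy TXT: `custom_name<TAB>custom_id<TAB>member_ids`
  (semicolon-separated member labels), `UNMAPPED` row with ID −1.
* Barycentric inside-tests use a 1e-9 slack so pixels on triangle edges are
  assigned exactly once (first containing triangle wins); triangle order is
  the deterministic `deldir` output.
* Degenerate inputs: empty marker sets give `NA` damage (never 0); empty
  section lists triage to two empty sets; all-background volumes are valid
  with an empty region set.

# Known limitations

* The deformation interpolant is a documented stand-in for an unpublished
  one; anchor-rich refinements may differ from the interactive tool's
  output even though both are exact at anchors.
* The paired signed-rank reading of the "two-way Wilcoxon" and the
  `n − g − 1` df of the multilevel correlation are documented
  interpretations, not reproductions of the original scripts.
* Whether grids share an origin across sections of a brain is unstated
  upstream; here each section gets the same deterministic default origin.
* Object counts for split objects are per-region (an object in k regions
  counts k times across regions); brain-level object totals are therefore
  not additive across hierarchies.
* Performance targets desk-scale validation (pure R with vectorized
  kernels); production-size section images (10⁷–10⁸ px) would warrant a
  compiled connected-components and warping path.
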