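---
title: "Lesion-wise comparison of paired delineations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-wise comparison of paired delineations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntax)
```

# The problem

A single global Sørensen–Dice index (SDI) between two lesion masks hides
*how* the masks differ: whether the raters disagree about lesion
existence, about boundaries, or about how contiguous tissue decomposes
into discrete lesions. `cntax` decomposes a mask pair into connected
components, links them through a bipartite overlap graph, and classifies
every component so that those three failure modes are separated. It was
designed for paired delineations of multiple sclerosis white-matter
lesions — co-registered masks on a common (typically 0.8 mm isotropic
template) grid — but applies to any paired 3D binary segmentations that
already share a grid. Registration, resampling and intensity processing
are deliberately out of scope: masks entering a comparison must agree in
shape, spacing and orientation, and mismatches are an error, not a
warning.

# Classification model

Let the components of delineations $G$ and $H$ be $g_1 \dots g_I$ and
$h_1 \dots h_J$. The overlap graph has an edge $(g, h)$ iff
$g \cap h \neq \emptyset$ — a strict one-voxel threshold, with no fuzzy
matching — weighted by the exact voxel intersection count. The degree of
a node is the cardinality of intersection $|\cap_X(y)|$: the number of
opposite-side components it touches.

Two classifications are computed from the same graph:

* **Six-class taxonomy** (per connected subgraph, by the X–Y component
  counts): Correct Detection 1–1, Detection Failure 1–0, False Alarm 0–1,
  Split 1–N, Merge M–1, Split-Merge M–N.
* **Condensed taxonomy (CNT)** (per node): degree 0 → Disagreement;
  degree 1 with a degree-1 partner → Agreement (recorded as a matched
  pair); otherwise → Checkered.

The two views must coincide under the condensation map (Correct
Detection → Agreement; Detection Failure, False Alarm → Disagreement;
Split, Merge, Split-Merge → Checkered). Both are implemented
independently — the six-class path via subgraph decomposition, the CNT
path via the literal degree rules — and the equivalence is enforced in
the test suite exhaustively over every bipartite topology with up to
three components per side, plus a thousand random 3D mask pairs. Keeping
both routes live is a deliberate redundancy: any future change that
breaks one view against the other fails loudly.

## Connectivity

The field rarely states the voxel connectivity behind "a lesion".
Default is 26-connectivity (the common convention for 3D lesion
counting); 6 and 18 are available, and every report records which was
used, since component counts — and therefore class counts — depend on it.
Component numbering is deterministic (raster order of first-encountered
voxel) so repeated runs are byte-identical.

# Per-lesion metrics

* **Agreement**: one record per matched pair with the symmetric pairwise
  SDI. The record's volume is the *mean* of the two members' volumes — a
  symmetric choice; no convention is established in the field for which
  member's volume represents a pair.
* **Checkered**: one record per component per side, scored against the
  union of its overlap partners. Component-vs-union is a design choice
  (component-vs-single-partner and subgraph-vs-subgraph are defensible
  alternatives); the union rule has the property that a component fully
  covered by its partners scores 1, and every Checkered record has
  SDI > 0 because Checkered components always overlap something.
* **Disagreement**: one record per component per side, SDI 0 by
  definition; analyses of this class use volumes only. Disagreement
  counts and volumes pool both sides by default (reported per side too).

Volumes are voxel count × voxel volume, reported in mm³ everywhere (on a
0.8 mm isotropic grid one voxel is 0.512 mm³). Since both masks share a
grid, all intersection/union cardinalities reduce to sums of edge
weights and component sizes; no voxel set is revisited after the graph
is built.

Degenerate inputs: the SDI of two empty sets is mathematically
undefined, so `sdi()` raises a typed error (`cnt_undefined_sdi`) rather
than silently returning 0 or 1; `cnt_compare()` flags such subjects as
`no_lesions` and reports `NA`.

# Statistics battery

All tests are two-sided and return a classed result with the statistic,
p-value, effect size, and exactness flags.

* **Wilcoxon signed-rank** (paired): zero differences are dropped and
  tied absolute differences receive mid-ranks — conventions that matter
  at cohort sizes of ten. The exact signed-rank null is used for
  n ≤ 25 without ties, otherwise the tie-corrected normal approximation
  with continuity correction.
* **Hodges–Lehmann interval**: the median of the Walsh averages with
  Bauer-style endpoints — order statistics of the Walsh averages at
  ranks from inverting the exact signed-rank distribution. The discrete
  procedure's achieved confidence level is attached to the interval. A
  95 % interval needs n ≥ 6; smaller samples error with the minimal n.
* **Mann–Whitney U** with η² = Z²/(n₁+n₂), Z being the tie-corrected
  standardized statistic without continuity correction (the continuity
  correction belongs to the p-value approximation, not the effect size).
  η² has no single agreed convention, so the rank-biserial correlation
  1 − 2U/(n₁n₂) is emitted alongside.
* **Linear fits** of per-lesion SDI on log₁₀ volume are ordinary least
  squares with the pointwise confidence band for the mean response.
* **MANOVA** on (log₁₀ volume, SDI) between two conditions uses Pillai's
  trace — in the two-group case a monotone transform of Hotelling's T²
  (the identity Pillai = T²/(T² + N − 2) is verified in the tests against
  a closed-form T² oracle, and the F p-value against a permutation
  oracle).

## Calibration-study design

The test suite verifies each exact p-value against full enumeration
(all 2ⁿ sign patterns; all $\binom{N}{n_1}$ group assignments) and then
checks null calibration empirically. Discreteness means an exact test's
achievable size is below 0.05 by an amount that depends on n, so the
calibration sample sizes were fixed *analytically in advance* from the
exact null distributions: signed-rank at n = 25 pairs (exact size
0.0483), Mann–Whitney at 20 + 20 (0.0491), and the 95 % Hodges–Lehmann
interval at n = 15 (achieved level 95.21 %) — all within ±0.01 of
nominal by construction. The suite then confirms the empirical rejection
rate and coverage over 10,000 null/shifted replicates.

# The phantom

Real paired-delineation cohorts are generally unshareable, so validation
runs on a phantom that emulates the *geometry* of such a study, not its
images:

* **Truth**: n ellipsoidal lesions with log-normal base radius (default
  median 3 mm, σ_log = 0.35 — a plausible white-matter-lesion size
  distribution) and mild per-axis anisotropy, placed uniformly with a
  minimum inter-lesion gap (default 2 voxels) so true lesions never
  touch.
* **Raters**: each true lesion is independently missed with probability
  1 − p_det; retained lesions get smooth boundary jitter of scale σ_b mm
  (random center shift and radius perturbation — a smooth affine
  boundary change, chosen over voxel-level noise so jittered lesions
  stay connected and degradation is monotone in σ_b); with probability
  p_split a 1-voxel-thick interior plane is removed (which provably
  disconnects a convex digital ellipsoid under 26-connectivity); with
  probability p_merge a 1-voxel bridge is drawn to the nearest retained
  lesion; false positives arrive as a Poisson count per mask (`fp_rate`
  is an expected blob count, not a density) and are placed clear of true
  lesions so they are genuinely Disagreement.
* **Seeding**: one master seed, with named substreams for the truth and
  each rater; in cohort mode the rater substreams are condition-independent
  (common random numbers), so low- vs high-noise contrasts are paired
  within subject, mirroring the paired design of intra-rater
  inter-scanner studies.

Because events are logged, expected class counts follow in closed form:
a lesion detected by exactly one rater contributes one Disagreement
component (probability $p_1(1-p_2) + p_2(1-p_1)$); both-detected,
event-free lesions contribute one Agreement pair; a both-detected lesion
with a single split event contributes three Checkered components. The
compound split+merge accounting is approximate (events can interact) and
is documented as such; the parameter-recovery tests use settings where
the accounting is exact.

The stock `phantom_conditions()` pair — low noise (p_det 0.97, σ_b
0.4 mm, ~1 false positive) vs high noise (p_det 0.85, σ_b 1.2 mm, ~4
false positives, more splits/merges) — was chosen once as a plausible
harmonized-like vs original-like contrast; the package makes no claim
that these match any particular cohort's noise levels.

**What the phantom does not model**: MRI intensities, scanner or
harmonization effects, anatomically realistic lesion shapes or spatial
distributions (periventricular clustering etc.), rater biases correlated
across lesions, or partial-volume boundary ambiguity. Passing
parameter-recovery tests therefore validates the *comparison machinery*
and the direction of noise effects — not any claim about real raters.

# Spatial maps

Cohort heat maps store, per voxel, the percentage of contributing
subjects with a marked voxel there; a conservation identity (voxel sum ×
voxel volume / 100 = mean per-subject volume) ties them to the volume
accounting and is tested exactly. Thin-slab maximum intensity
projections default to 11 slices (8.8 mm at 0.8 mm spacing); slabs
extending past the volume are clipped with a warning rather than padded,
and the slab axis is resolved from the mask's anatomical orientation
string (the axis labelled S/I), falling back to the third array axis.
Overlays alpha-blend the projection over a grayscale template slice
above a threshold and are deterministic (byte-identical re-renders).

# Problem sizes in the shipped tests

The suite exercises: the exhaustive topology sweep (≤ 3 components per
side, 749 graphs) plus 1,000 random 3D mask pairs; 1,000 random SDI
oracle pairs; 10,000-replicate calibration runs per test; 200 phantom
seeds for detection-deficit recovery (50 lesions, 64³ voxels) and 50
seeds × 4 jitter levels for the degradation trend; and a 10-subject
paired cohort for the direction-of-effect check. These sizes were chosen
to make binomial/Monte-Carlo error small relative to the tested bands
while keeping the whole suite around a minute on a laptop-class machine.

# Known limitations

* Components are never weighted by boundary distance; a one-voxel graze
  links components as firmly as a deep overlap (by design — the strict
  nonempty-intersection rule — but worth remembering with very noisy
  masks).
* The Checkered union-rule SDI is one of several defensible comparands;
  cross-study comparisons should state the rule.
* η² from the normal approximation is slightly conservative for tiny
  samples (where the exact p-value is used but Z is still approximate).
* The phantom's closed-form class expectations assume events do not
  interact; with high simultaneous split and merge rates, use simulation
  rather than the closed form.
* No multiple-comparison machinery is provided; the battery reports raw
  p-values.
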