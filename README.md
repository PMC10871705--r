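# cntax — lesion-wise comparison of paired delineations

`cntax` compares two co-registered binary lesion masks — typically manual
delineations of multiple sclerosis white-matter lesions made by the same
rater on images of the same subject from two scanners — on a *per-lesion*
basis rather than by a single global overlap score. It is aimed at
neuroimaging researchers evaluating delineation consistency (intra-rater,
inter-rater, or before/after image harmonization) and at developers of
segmentation methods who need lesion-level truth-model diagnostics.

## The method

Given two delineations *G* and *H* on the same voxel grid, their connected
components (the lesions *g₁…g_I*, *h₁…h_J*, 26-connectivity by default)
are linked in a bipartite **overlap graph**: an edge (g, h) exists exactly
when the two components share at least one voxel. The degree of a node is
the cardinality-of-intersection |∩_X(y)| — how many components of the
opposite delineation it touches.

Components are classified two ways:

* the **six-class object-detection taxonomy** over connected subgraphs —
  Correct Detection (1–1), Detection Failure (1–0), False Alarm (0–1),
  Split (1–N), Merge (M–1), Split-Merge (M–N);
* its **three-class condensation (CNT)** for the symmetric two-ground-truth
  setting — **Agreement** (one-to-one pairs), **Disagreement** (no overlap
  at all), **Checkered** (everything overlapping but not one-to-one).

The condensation of the six-class labeling provably coincides with the
direct per-node CNT rules; the package computes both and the test suite
enforces the equivalence exhaustively.

Overlap is quantified by the Sørensen–Dice index

    SDI(A, B) = 2|A ∩ B| / (|A| + |B|)  ∈ [0, 1],

applied globally per subject, and per lesion: Agreement pairs get their
pairwise SDI, Checkered components their SDI against the union of their
overlap partners, Disagreement lesions are 0 by definition. Disagreement
volume (lesion volume present in one delineation with no overlap in the
other, summed over both sides) quantifies what the raters outright
disagree on. Cohort-level spatial structure is rendered as per-voxel
disagreement-percentage heat maps with 8.8 mm thin-slab maximum intensity
projections (11 × 0.8 mm slices).

The statistics battery bundles the paired two-sided Wilcoxon signed-rank
test (exact null for n ≤ 25), a Hodges–Lehmann-style confidence interval
for a median difference (signed-rank inversion over Walsh averages), the
Mann–Whitney U test with η² = Z²/(n₁+n₂), per-class least-squares fits of
SDI on log₁₀ volume with confidence bands, and a two-group MANOVA
(Pillai's trace).

Because real paired-delineation cohorts are rarely shareable, the package
includes a **phantom generator**: ellipsoidal lesions with log-normal
sizes and two simulated raters with controllable detection probability,
boundary jitter, split/merge rates and false-positive counts — with
closed-form expected class counts for validation.

## Worked example

```r
library(cntax)

spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing = c(0.8, 0.8, 0.8),
                     n_lesions = 12, radius_meanlog = log(2.5),
                     radius_sdlog = 0.3, seed = 7,
                     raters = phantom_conditions()$high_noise)
sim <- simulate_pair(spec)
cmp <- cnt_compare(sim$rater1$mask, sim$rater2$mask)
cmp
#> <cnt_comparison> subject phantom
#>   components: G = 13  H = 11  (26-connectivity)
#>   global SDI: 0.336
#>   CNT components (G/H): Agreement 6/6, Disagreement 3/2, Checkered 4/3
#>   disagreement volume: 296.448 mm^3 (G 220.160, H 76.288)
```

The two simulated raters marked 13 and 11 lesions; six lesions matched
one-to-one (Agreement), five (3 + 2) have no counterpart at all in the
other mask (Disagreement, 296.4 mm³ of it), and seven components overlap
ambiguously (Checkered) — split/merge events and heavy boundary jitter at
work. `summary(cmp)` adds the per-class range/median/mean(±SD) rows for
SDI and volume, e.g. here the Agreement-class per-lesion SDI spans
[0.185, 0.645] with median 0.381. `plot(cmp)` draws per-lesion SDI against
log₁₀ volume with per-class linear fits and confidence bands.

Subject-level inference works on vectors of per-subject values:

```r
orig <- c(0.52, 0.48, 0.55, 0.60, 0.44, 0.51, 0.58, 0.47, 0.50, 0.53)
harm <- c(0.69, 0.71, 0.64, 0.75, 0.70, 0.66, 0.73, 0.68, 0.72, 0.65)
wilcoxon_signed_rank(harm, orig)
#>   Paired Wilcoxon signed-rank test (normal approximation)
#>   V = 55  p-value = 0.005793
#>   n = 10
```

File-based pipelines go through `read_mask()` / `run_compare()` (NIfTI in,
CSV/JSON reports and NIfTI class maps out) or the CLI at
`inst/cli/cnt.R` with subcommands `components`, `classify`, `report`,
`stats`, `heatmap`, `simulate`.

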