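Package: cntax
Title: Lesion-Wise Comparison of Paired Segmentations with the Condensed
    Nascimento Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing two co-registered binary lesion
    delineations (for example intra-rater delineations of multiple
    sclerosis white matter lesions) on a per-lesion basis. Connected
    components of the two masks are linked through a bipartite overlap
    graph and classified under the six-class Nascimento object-detection
    taxonomy and its three-class condensation (Agreement, Disagreement,
    Checkered). Includes per-lesion Sorensen-Dice analysis, disagreement
    volume accounting, cohort disagreement heat maps with thin-slab
    maximum intensity projections, a nonparametric statistics battery
    (exact Wilcoxon signed-rank, Hodges-Lehmann intervals, Mann-Whitney U
    with eta-squared, per-class linear fits, two-group MANOVA), and a
    synthetic lesion phantom generator with known ground-truth class
    structure for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
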