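Package: striatparc
Title: Connectivity-Based Parcellation of the Striatum into Striosome-Like
    and Matrix-Like Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectivity-based parcellation of the striatum into
    striosome-like and matrix-like voxel sets from classification-targets
    tractography output, and for quantifying compartment-specific bias in
    insulo-striate structural connectivity across insular subregions.
    Includes scoring of seed-voxel streamline-count tables against
    striosome-favoring and matrix-favoring bait-region groups, equal-volume
    most-biased mask construction (including leave-one-out and
    nucleus-proportional variants), anatomic validation (compartment
    abundance, centroid-relative voxel location with two-factor ANOVA),
    bundle-map thresholding and Dice overlap, per-subregion volume-percent
    bias with hemisphere quality control and center-of-gravity geometry,
    permutation-based voxelwise inference with familywise error control,
    per-subregion ANCOVA with Bonferroni families, voxel-jitter and
    proportional-mask controls, and a synthetic connectome phantom generator
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
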