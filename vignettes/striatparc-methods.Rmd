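---
title: "Connectivity-based striatal parcellation and insulo-striate bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based striatal parcellation and insulo-striate bias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatparc)
```

## The scientific problem

The striatum is built from two interdigitated tissue compartments. The
striosome occupies roughly 15% of striatal volume as a thin, connected
labyrinth enriched in the rostral, ventral and medial striatum; the matrix
fills the remaining ~85% and dominates caudal, dorsal and lateral sites.
The two compartments have distinct afferents: limbic structures project
preferentially to striosome, sensorimotor structures to matrix. Because the
compartments cannot be seen directly in MRI, they can only be inferred from
connectivity: probabilistic tractography in classification-targets mode
counts, for every striatal seed voxel, the streamlines that reach each of a
set of extra-striatal "bait" regions whose compartment selectivity is
known from tract tracing in animals.

`striatparc` implements that inference chain end to end:

1. **Scoring** (`ctt_bias_score`): a voxel's striosome-like probability is
   the pooled streamline count to the striosome-favoring bait group divided
   by the pooled count to both groups. Voxels with zero counts to both
   groups are *unclassified* (`NA`), never 0.5 — a ratio of zeros carries
   no information, and treating it as neutrality would fabricate data.
2. **Mask construction** (`select_equal_volume_masks`,
   `n1_parcellation`, `proportional_masks`): the most-biased voxels from
   each distribution form two disjoint, equal-volume masks. Equal volume
   matters because the masks later serve as tractography targets, and
   unequal targets would skew streamline counts.
3. **Anatomic validation** (`abundance_fraction`, `location_records`,
   `location_anova`, `leftout_region_bias`): the parcellation is accepted
   only to the degree that it reproduces tissue facts established by
   histology — the ~15/85 volume split among highly biased voxels, the
   spatial gradients of each compartment, and the compartment selectivity
   of primary motor (matrix) and posterior orbitofrontal (striosome)
   projections, quantified without circularity via leave-one-out
   parcellations.
4. **Insulo-striate quantification** (`simulate_insulo_striate` /
   `insular_probability_pair`, `normalize_probability_pair`,
   `subregion_bias`, `cog_analysis`): classification-targets tractography
   from the insula against the two compartment masks yields per-voxel
   striosome-favoring and matrix-favoring probabilities, summarized per
   insular subregion as the *volume percent* —
   `100 * n_matrix / (n_strio + n_matrix)` over suprathreshold voxels.
5. **Inference** (`subregion_ancova`, `paired_t_family`,
   `voxelwise_permutation_test`): Bonferroni-corrected ANCOVAs per
   subregion, paired-t families, and voxelwise sign-flip permutation
   testing with familywise error control.
6. **Controls** (`jitter_masks`, `neighborhood_comparison`,
   `proportional_comparison`): alternative-hypothesis checks that the
   measured biases are compartment-specific rather than driven by the
   striatal neighbourhood or by caudate/putamen differences.

## Key parameters

| parameter | default | role |
|---|---|---|
| `mask_fraction` | 0.13 | fraction of classified voxels per compartment mask |
| `high_bias_threshold` | 0.87 | probability bound defining "highly biased" voxels |
| `suprathreshold` | 0.55 | cut for subregion suprathreshold counting |
| `edge_trim_sum` | 0.5 | minimum striosome+matrix sum for a voxel to be kept |
| `min_suprathreshold_voxels` | 19 | hemisphere QC floor per compartment |
| `jitter_max` | 3 voxels | per-plane range of the neighbourhood control |
| `rostro_caudal_split_y` | 1 mm | coronal split for the two striosome COGs |
| `core_fractions` | 0.25/0.50/0.75 | bundle-core keep fractions |
| `n_permutations` | 5000 | voxelwise FWE permutations |
| Bonferroni families | 19 / 3 / 2 | subregion, streamline-count and voxelwise test families |
| `trending_multiplier` | 10 | results below 10x the family alpha are "trending" |

A documented oddity is carried deliberately: the mask criterion is usually
phrased as "1.5 standard deviations above the mean", glossed as the
uppermost 13% of voxels. The upper tail beyond 1.5 SD of a normal holds
about 6.7%, not 13%. The 13% figure is the operational statement and is
what the parameter encodes; the 1.5 SD phrase is treated as gloss.

Similarly, the marginal-voxel illustration for undersampling — adding one
matrix voxel to a hemisphere with 1 matrix and 9 striosome suprathreshold
voxels raises the matrix volume percent by 8.2 points — is reproduced
exactly by the volume-percent formula. The companion figure sometimes
quoted for the larger subject (2.1 points for 10/90 counts) is *not* what
the formula yields (~0.9 points); the formula's value is the one this
package computes.

## The synthetic phantom

Real inputs would be classification-targets tractography of diffusion MRI.
The phantom (`make_phantom`, `simulate_ctt`, `simulate_insulo_striate`)
stands in for that pipeline so that every stage runs, and is verifiable,
at desk scale.

**Geometry.** One right-hemisphere 1.5 mm grid (28 x 34 x 28) holds two
ellipsoidal nuclei — a medial caudate (~900 voxels) and a lateral putamen
(~1000 voxels) — and a two-voxel-thick elliptical insular sheet (~700
voxels) lateral to both, partitioned into 19 contiguous subregions along
the rostroventral-to-caudodorsal axis. World axes follow the MNI
convention (+x right, +y anterior, +z superior); all volumes share the one
grid, so registration — out of scope — never arises. The edge-trimming
rule (`edge_trim_sum`) is the only surviving trace of the real pipeline's
registration-induced partial-volume behaviour.

**Compartments.** Within each nucleus, a striosome labyrinth of exactly
`round(0.15 * N)` voxels is grown by random-walk branches seeded and
extended under a spatial intensity increasing medially, rostrally and
ventrally (the histological gradients). Growth into voxels already
touching several striosome voxels is penalized (`branch_penalty = 0.35`),
keeping branches thin and dispersed, as tissue striosome is — its branches
(0.5–1.25 mm) are thinner than a diffusion voxel. The per-nucleus quota
reflects histology's finding that both caudate and putamen carry the
~15% fraction.

**Streamline counts.** For striatal CTT, a voxel of compartment c sends a
Beta-distributed fraction of its streamlines (mean `fidelity` = 0.8,
concentration `voxel_kappa` = 25) to the concordant bait group, split
across regions by configurable weights; the rest go to the discordant
group, with an optional lapse to no target and a distance-correction
toggle (off by default — distance correction is tractography-tool
behaviour the analysis consumes, not defines). The Beta heterogeneity is
the phantom's expression of partial-volume mixing: every millimetre-scale
voxel samples both compartments, so per-voxel connection probabilities
spread around the nominal fidelity. Without it no voxel could exceed the
0.87 high-bias bound at realistic streamline depths and the abundance
measure would be degenerate — the parameter is biology, not a tuning knob.

**Insulo-striate CTT.** Each insular voxel of subregion s aims its
streamlines at the striosome-labelled target mask with probability
Beta-distributed around that subregion's true bias (default profile: 7
striosome-leaning, 3 neutral, 9 matrix-leaning subregions, rostroventral
to caudodorsal), and a streamline is scored by the ground-truth tissue of
the mask voxel it lands on. For pure masks aim and tissue coincide and
counts follow b versus 1-b exactly. For impure masks — the jittered
neighbourhood control, whose random relocation lands mostly in the
abundant matrix — the measured bias follows the tissue actually occupying
the masks. That is precisely the effect the round-7 control exists to
expose, and it is why every striosome-leaning subregion shifts toward
matrix when the precisely selected targets are replaced by their
neighbours.

**Path densities.** Bundle maps rasterize straight seed-to-target
segments, accumulating one visit per crossed voxel per segment; at most
`max_targets` distinct targets are rasterized per seed and mask, with
total streamline weight conserved. Curvature, step length and diffusion
physics are not modelled: bundle-level statistics (Dice of thresholded
cores, per-voxel density) need spatial extent, not fibre dynamics. The
bundle-segregation analysis follows the field's convention of assessing
cores within subcortical white matter (`restrict_bundle` removes the
gray-matter seed and target structures where endpoints pile up), and its
demonstration scenario uses the compartment-typical routing — the rostral
striosome-bound bundle targeting the caudate, the matrix-bound bundle the
putamen — because straight rays, unlike real fibres, cannot route around
an interposed nucleus.

**What the phantom does not emulate.** Scanner noise, crossing fibres,
distance-dependent count attenuation, inter-subject anatomic variability,
left/right asymmetries, and spatially correlated score noise (phantom
scores are independent across voxels given tissue class). Passing the
recovery suites therefore shows the *analysis chain* is correct and
calibrated under the stated generative model — not that the acquisition
pipeline would perform equally on real diffusion data.

## Statistical design choices

- **Two-factor location ANOVA** uses Type-II tests of compartment,
  nucleus and their interaction, with subject as a fixed nuisance factor
  when several subjects are pooled. When the interaction is significant,
  simple main effects are computed with the pooled error term and judged
  against a conservative Scheffé-style simultaneous F-critical,
  `(k - 1) * F(1 - alpha; k - 1, df_error)` over the k cell means.
- **Per-subregion ANCOVA** models the volume percent on compartment,
  hemisphere, handedness, sex, self-identified race and age. The combined
  sex-by-hemisphere-by-compartment interaction enters as a single block
  tested by model comparison against the main-effects fit; with two-level
  factors the block has 4 numerator degrees of freedom (it absorbs the
  nested two-way terms). Missing covariates are rejected, not imputed.
  With `covariates = NULL` the model reduces to the repeated-measures form
  `percent ~ subject + compartment`, whose compartment F equals the
  squared paired t — the form appropriate when the two compartments'
  percents are exact complements, as real volume percents are. The
  calibration suite exercises the covariate model under independent
  errors, its assumed regime.
- **Voxelwise inference** replaces threshold-free cluster enhancement
  with max-statistic familywise error control: one-sample t on paired
  differences, sign-flip permutations, and the FWE p of each voxel taken
  from the permutation distribution of the maximum statistic. Two-sided
  testing runs as two one-directional max-statistic tests at alpha/2,
  matching per-direction significant masks. When `2^n` subjects'
  sign patterns number no more than the requested permutations, all are
  enumerated exactly. TFCE would add substantial surface without changing
  the calibration properties under test. Optional variance smoothing
  applies a separable Gaussian (sigma in mm) to the variance map before
  forming t.
- **Verdicts** follow the Bonferroni family: significant below
  `0.05 / family_size`, "trending" below ten times that.

## Numerical conventions and degenerate inputs

- Voxel indices are 0-based; selection ties break by score descending,
  then lexicographic (i, j, k). Selection is therefore deterministic and
  invariant to input row order, which the tests verify against an
  explicit sort-and-take oracle.
- When exact score ties would place a voxel in both equal-volume masks,
  the striosome-like mask takes it and the matrix-like mask draws the next
  voxel in its own ordering — masks stay disjoint and equal-volume.
- Zero-count seed voxels are unclassified; subregions with no
  suprathreshold voxels yield `NA` volume percent (flagged, not 50);
  Dice of two empty masks is 0 with a message; an empty bundle map
  thresholds to an empty mask with a message rather than an error.
- The jitter control redraws a destination while it lies in either
  original mask, outside the striatum, or on an already-placed shifted
  voxel (both latter rules configurable). Placement orders the most
  constrained voxels first and restarts with a reshuffled order on
  failure, within a bounded draw budget, because greedy sequential
  placement can strand a voxel even when a feasible assignment exists.
  Voxels exactly on the COG split plane go caudal.
- In the phantom, the clustered compartments and the striatal boundary
  give the jittered masks a small systematic net drift (well under the
  1 mm neighbourhood criterion, but larger than the < 0.5 voxel drift
  of dispersed masks in open tissue, which is also tested); this is a
  geometric property of rejection sampling near boundaries, reported
  rather than hidden.

## Problem sizes used by the test and acceptance suites

Phantoms use the default grid (~1 900 striatal voxels, ~700 insular
voxels); striatal CTT at 5 000 streamlines per seed voxel, subregion
quantification at 50 000. Recovery runs use 10 phantom seeds; control
comparisons 5; the permutation null calibration 100 replicates of an
8 x 8 x 8 grid with 8 subjects and exhaustive (256-pattern) sign
enumeration; the ANCOVA null calibration 200 replicates of a 12-subject,
19-subregion family. These sizes were chosen to give stable Monte-Carlo
estimates at interactive runtimes.

## Known limitations

The phantom's streamline geometry is straight-ray; its insular sheet is a
plane rather than a folded cortex; hemispheres are modelled singly (the
left-hemisphere x-mirroring path is exercised synthetically). The
volume-percent statistic inherits the instability near zero suprathreshold
counts that motivates the 19-voxel hemisphere QC; the QC is implemented,
but the phantom rarely triggers it at 50 000 streamlines per voxel, since
deeper sampling suppresses undersampled hemispheres. Headline numbers from
real cohorts (exact abundance percentages, F statistics, COG offsets in
mm) depend on real anatomy and are treated as direction and magnitude
checks on the phantom, not as reproduction targets.
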