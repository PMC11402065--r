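#' Analysis parameters
#'
#' Collects the tunable thresholds of the pipeline with their defaults:
#' the equal-volume mask fraction (uppermost 13% of each bias distribution,
#' the operational form of the "1.5 SD above the mean" criterion), the
#' high-bias threshold used for abundance and left-out-region quantification
#' (P >= .87), the suprathreshold cut for subregion counting (0.55), the
#' edge-trim sum (voxels whose striosome+matrix value falls below 0.5 are
#' trimmed), the minimum suprathreshold voxel count per hemisphere (19),
#' the jitter range of the neighbourhood control (0-3 voxels per plane),
#' the rostro-caudal split plane (y = 1 mm), the bundle core fractions
#' (25/50/75%), the permutation count (5000) and the Bonferroni family
#' sizes with the 10x "trending" rule.
#'
#' Note the documented mismatch carried over from the field's usage: the
#' upper tail beyond 1.5 SD of a normal holds about 6.7% of observations,
#' not 13%; the 13% figure is the operational parameter and governs
#' behaviour here.
#'
#' @param mask_fraction fraction of classified voxels per compartment mask.
#' @param high_bias_threshold probability bound defining "highly biased".
#' @param suprathreshold normalized-probability cut for subregion counting.
#' @param edge_trim_sum minimum striosome+matrix sum for a voxel to be kept.
#' @param min_suprathreshold_voxels hemisphere QC minimum per compartment.
#' @param jitter_max maximum per-plane shift (voxels) of the jitter control.
#' @param rostro_caudal_split_y world-mm coronal split for striosome COGs.
#' @param core_fractions bundle-core keep fractions.
#' @param n_permutations permutations for voxelwise FWE testing.
#' @param bonferroni_family_sizes named integer vector of test-family sizes.
#' @param trending_multiplier results below `trending_multiplier` times the
#'   family alpha are labelled "trending".
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(mask_fraction = 0.13,
                            high_bias_threshold = 0.87,
                            suprathreshold = 0.55,
                            edge_trim_sum = 0.5,
                            min_suprathreshold_voxels = 19L,
                            jitter_max = 3L,
                            rostro_caudal_split_y = 1,
                            core_fractions = c(0.25, 0.50, 0.75),
                            n_permutations = 5000L,
                            bonferroni_family_sizes = c(subregion = 19L,
                                                        cortical = 2L,
                                                        streamline = 3L,
                                                        voxelwise = 2L),
                            trending_multiplier = 10) {
  stopifnot(mask_fraction > 0, mask_fraction < 0.5,
            high_bias_threshold > 0.5, high_bias_threshold <= 1,
            suprathreshold >= 0.5, suprathreshold <= 1,
            min_suprathreshold_voxels >= 1)
  structure(list(mask_fraction = mask_fraction,
                 high_bias_threshold = high_bias_threshold,
                 suprathreshold = suprathreshold,
                 edge_trim_sum = edge_trim_sum,
                 min_suprathreshold_voxels = as.integer(min_suprathreshold_voxels),
                 jitter_max = as.integer(jitter_max),
                 rostro_caudal_split_y = rostro_caudal_split_y,
                 core_fractions = core_fractions,
                 n_permutations = as.integer(n_permutations),
                 bonferroni_family_sizes = bonferroni_family_sizes,
                 trending_multiplier = trending_multiplier),
            class = "analysis_params")
}

#' Read analysis parameters from a YAML config
#'
#' Keys mirror the arguments of [analysis_params()]; unknown keys are an
#' error so typos fail loudly.
#'
#' @param path YAML file path.
#' @return An `analysis_params` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(analysis_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$bonferroni_family_sizes))
    cfg$bonferroni_family_sizes <- unlist(cfg$bonferroni_family_sizes)
  do.call(analysis_params, cfg)
}
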