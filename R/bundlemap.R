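#' Streamline bundle map
#'
#' A path-density volume with its provenance: which compartment's targets
#' the bundle reached, the hemisphere, the total streamline count and the
#' seed volume (for per-voxel normalization).
#'
#' @param density a [probability_volume()] of per-voxel visit counts or
#'   normalized amplitudes.
#' @param compartment `"striosome"` or `"matrix"`.
#' @param hemisphere hemisphere tag.
#' @param total_streamlines total streamlines in the bundle.
#' @param seed_volume_voxels voxel count of the seed mask.
#' @return An object of class `bundle_map`.
#' @export
bundle_map <- function(density, compartment, hemisphere = "right",
                       total_streamlines = sum(density$values, na.rm = TRUE),
                       seed_volume_voxels = NA_integer_) {
  stopifnot(inherits(density, "probability_volume"))
  structure(list(density = density, compartment = compartment,
                 hemisphere = hemisphere,
                 total_streamlines = total_streamlines,
                 seed_volume_voxels = seed_volume_voxels),
            class = "bundle_map")
}

#' Average seed-swapped bundle maps (AB-BA averaging)
#'
#' Tractography run in both directions (A-to-B and B-to-A) is averaged
#' voxelwise; the total streamline count is the mean of the two totals.
#'
#' @param map_ab,map_ba `bundle_map`s on the same grid, same compartment
#'   and hemisphere.
#' @return A `bundle_map`.
#' @export
abba_average <- function(map_ab, map_ba) {
  stop_if_grid_mismatch(map_ab$density$grid, map_ba$density$grid)
  if (!identical(map_ab$compartment, map_ba$compartment) ||
      !identical(map_ab$hemisphere, map_ba$hemisphere))
    stop("bundle maps disagree on compartment or hemisphere")
  dens <- probability_volume(map_ab$density$grid,
                             (map_ab$density$values + map_ba$density$values) / 2,
                             probability = FALSE)
  bundle_map(dens, map_ab$compartment, map_ab$hemisphere,
             (map_ab$total_streamlines + map_ba$total_streamlines) / 2,
             map_ab$seed_volume_voxels)
}

#' Restrict a bundle map to an analysis region
#'
#' Zeroes the density outside the given bounding mask (or inside excluded
#' label volumes). Bundle cores are conventionally assessed within a
#' subcortical white-matter bounding mask that excludes the gray-matter
#' seed and target structures, where streamline endpoints pile up.
#'
#' @param map a `bundle_map`.
#' @param exclude list (or single volume) of [label_volume()] /
#'   [binary_volume()]s whose nonzero voxels are removed from the map.
#' @return The restricted `bundle_map`.
#' @export
restrict_bundle <- function(map, exclude) {
  if (!is.list(exclude) || inherits(exclude, c("label_volume",
                                               "binary_volume")))
    exclude <- list(exclude)
  vals <- map$density$values
  for (ex in exclude) {
    stop_if_grid_mismatch(map$density$grid, ex$grid)
    vals[ex$values > 0] <- 0
  }
  map$density <- probability_volume(map$density$grid, vals,
                                    probability = FALSE)
  map
}

#' Normalize a bundle map to its maximum amplitude
#'
#' @param map a `bundle_map`.
#' @return The map with density divided by its maximum (unchanged when the
#'   map is all zero).
#' @export
normalize_bundle <- function(map) {
  mx <- max(map$density$values, na.rm = TRUE)
  if (mx > 0)
    map$density <- probability_volume(map$density$grid,
                                      map$density$values / mx)
  map
}

#' Threshold a bundle map to its core
#'
#' Retains the `round(keep_fraction * n_nonzero)` highest-amplitude nonzero
#' voxels (voxel-count-based selection, not an amplitude cutoff), with the
#' standard deterministic tie-break (amplitude descending, then voxel
#' index). An empty map yields an empty mask with a message, not an error.
#'
#' @param map a `bundle_map` (or [probability_volume()]).
#' @param keep_fraction fraction of nonzero voxels to keep, in (0, 1].
#' @return A [binary_volume()].
#' @export
core_threshold <- function(map, keep_fraction) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  dens <- if (inherits(map, "bundle_map")) map$density else map
  vals <- dens$values
  vals[is.na(vals)] <- 0
  lin <- which(vals > 0)
  out <- array(FALSE, dens$grid$shape)
  if (!length(lin)) {
    message("core_threshold: empty bundle map; returning empty mask")
    return(binary_volume(dens$grid, out))
  }
  k <- round(keep_fraction * length(lin))
  if (k >= 1) {
    ijk <- linear_to_ijk(dens$grid, lin)
    sel <- ordered_voxels_by_score(ijk, vals[lin])[seq_len(k), , drop = FALSE]
    out[ijk_to_linear(dens$grid, sel)] <- TRUE
  }
  binary_volume(dens$grid, out)
}

#' Dice similarity coefficient of two binary volumes
#'
#' `2|A n B| / (|A| + |B|)`; defined as 0 (with a message) when both masks
#' are empty.
#'
#' @param mask_a,mask_b [binary_volume()]s on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a$grid, mask_b$grid)
  na <- sum(mask_a$values); nb <- sum(mask_b$values)
  if (na + nb == 0) {
    message("dice: both masks empty; returning 0")
    return(0)
  }
  2 * sum(mask_a$values & mask_b$values) / (na + nb)
}

#' Seed-volume-normalized streamline counts and compartment ratio
#'
#' Normalizes per-compartment streamline totals by the insular seed volume
#' and reports the matrix percentage `matrix / (striosome + matrix)` and
#' the striosome/matrix fold ratio.
#'
#' @param striosome_count,matrix_count total streamlines reaching each
#'   compartment's targets.
#' @param insular_seed_volume seed mask voxel count (> 0).
#' @return List with `striosome_per_voxel`, `matrix_per_voxel`,
#'   `matrix_percent`, `fold_ratio`.
#' @export
streamline_density_stats <- function(striosome_count, matrix_count,
                                     insular_seed_volume) {
  if (insular_seed_volume <= 0) stop("insular seed volume must be positive")
  if (striosome_count + matrix_count == 0)
    stop("zero total streamlines; ratio undefined")
  list(striosome_per_voxel = striosome_count / insular_seed_volume,
       matrix_per_voxel = matrix_count / insular_seed_volume,
       matrix_percent = 100 * matrix_count / (striosome_count + matrix_count),
       fold_ratio = striosome_count / matrix_count)
}

#' Voxelwise paired contrast of compartment bundle maps
#'
#' Per-subject striosome-minus-matrix density differences are tested
#' voxelwise with the sign-flip permutation engine
#' ([voxelwise_permutation_test()]) under familywise error control, per
#' direction. Reports the fraction of analysed voxels significant in each
#' direction and the mean densities within each significant cluster.
#'
#' @param maps_strio,maps_matrix lists of `bundle_map`s, one per subject,
#'   matched by position; all on one grid.
#' @param n_permutations sign-flip permutations.
#' @param alpha familywise alpha for the two-direction family (each
#'   direction is tested at `alpha / 2`).
#' @param variance_smoothing_mm optional Gaussian smoothing of the
#'   variance map.
#' @param seed RNG seed for the permutation draws.
#' @return List with the `permutation` result, `fraction_striosome`,
#'   `fraction_matrix` (significant-voxel fractions per direction) and
#'   `cluster_densities` (mean strio/matrix density within each direction's
#'   significant mask).
#' @export
voxelwise_bundle_contrast <- function(maps_strio, maps_matrix,
                                      n_permutations = 5000L, alpha = 0.025,
                                      variance_smoothing_mm = 0, seed = 1L) {
  if (length(maps_strio) != length(maps_matrix))
    stop("subject mismatch between striosome and matrix map lists")
  if (length(maps_strio) < 8L)
    stop("voxelwise contrast requires at least 8 subjects")
  grid <- maps_strio[[1]]$density$grid
  diffs <- lapply(seq_along(maps_strio), function(i) {
    stop_if_grid_mismatch(maps_strio[[i]]$density$grid, grid)
    stop_if_grid_mismatch(maps_matrix[[i]]$density$grid, grid)
    maps_strio[[i]]$density$values - maps_matrix[[i]]$density$values
  })
  perm <- voxelwise_permutation_test(diffs, grid = grid,
                                     n_permutations = n_permutations,
                                     alpha = alpha,
                                     variance_smoothing_mm = variance_smoothing_mm,
                                     seed = seed)
  n_an <- sum(perm$analysis_mask$values)
  mean_strio <- Reduce(`+`, lapply(maps_strio, function(m) m$density$values)) /
    length(maps_strio)
  mean_matrix <- Reduce(`+`, lapply(maps_matrix, function(m) m$density$values)) /
    length(maps_matrix)
  cluster_mean <- function(mask) {
    if (!sum(mask$values)) return(c(striosome = NA_real_, matrix = NA_real_))
    c(striosome = mean(mean_strio[mask$values]),
      matrix = mean(mean_matrix[mask$values]))
  }
  list(permutation = perm,
       fraction_striosome = if (n_an) sum(perm$sig_pos$values) / n_an else 0,
       fraction_matrix = if (n_an) sum(perm$sig_neg$values) / n_an else 0,
       cluster_densities = list(striosome_cluster = cluster_mean(perm$sig_pos),
                                matrix_cluster = cluster_mean(perm$sig_neg)))
}
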