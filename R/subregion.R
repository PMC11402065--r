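#' Voxelwise normalization of a compartment probability pair with edge trim
#'
#' Registration-induced partial-volume effects leave some edge voxels with
#' striosome + matrix probability below 1. Voxels whose summed value falls
#' below `edge_trim_sum` (default 0.5) are trimmed; retained voxels are
#' rescaled so the pair sums to exactly 1.
#'
#' @param p_strio,p_matrix [probability_volume()]s on one grid (`NA`
#'   outside the region of interest).
#' @param edge_trim_sum minimum striosome+matrix sum for retention.
#' @return List with normalized `p_strio`, `p_matrix` and `retained`
#'   (a [binary_volume()] of kept voxels).
#' @export
normalize_probability_pair <- function(p_strio, p_matrix,
                                       edge_trim_sum = 0.5) {
  stop_if_grid_mismatch(p_strio$grid, p_matrix$grid)
  s <- p_strio$values
  m <- p_matrix$values
  tot <- s + m
  keep <- !is.na(tot) & tot >= edge_trim_sum
  if (!any(keep)) stop("edge trimming removed every voxel")
  s_out <- array(NA_real_, p_strio$grid$shape)
  m_out <- array(NA_real_, p_strio$grid$shape)
  s_out[keep] <- s[keep] / tot[keep]
  m_out[keep] <- m[keep] / tot[keep]
  list(p_strio = probability_volume(p_strio$grid, s_out),
       p_matrix = probability_volume(p_strio$grid, m_out),
       retained = binary_volume(p_strio$grid, keep))
}

#' Volume-percent bias statistic
#'
#' The percentage of suprathreshold voxels dominated by the matrix
#' compartment: `100 * n_matrix / (n_strio + n_matrix)`. Undefined (NA)
#' when both counts are zero - never coerced to 50.
#'
#' @param n_strio,n_matrix suprathreshold voxel counts.
#' @return Percentage in \[0, 100\], or `NA` when the denominator is zero.
#' @export
volume_percent_matrix <- function(n_strio, n_matrix) {
  ifelse(n_strio + n_matrix > 0, 100 * n_matrix / (n_strio + n_matrix),
         NA_real_)
}

#' Per-subregion suprathreshold counts and volume-percent bias
#'
#' Within each insular subregion, counts voxels whose normalized striosome
#' (resp. matrix) probability meets the suprathreshold cut (default 0.55)
#' and expresses the bias as the matrix volume percent. Subregions with no
#' suprathreshold voxels yield `NA` percent and are flagged, not dropped.
#'
#' @param normalized output of [normalize_probability_pair()].
#' @param insula_labels a [label_volume()] of subregions 1..K.
#' @param suprathreshold probability cut (default 0.55).
#' @param subject,hemisphere identifiers attached to the records.
#' @return Data frame with `subject`, `hemisphere`, `subregion`, `n_strio`,
#'   `n_matrix`, `volume_percent_matrix`, `defined`.
#' @export
subregion_bias <- function(normalized, insula_labels, suprathreshold = 0.55,
                           subject = "s1", hemisphere = "right") {
  stop_if_grid_mismatch(normalized$p_strio$grid, insula_labels$grid)
  labs <- sort(unique(insula_labels$values[insula_labels$values > 0L]))
  s <- normalized$p_strio$values
  m <- normalized$p_matrix$values
  recs <- lapply(labs, function(lb) {
    in_sub <- insula_labels$values == lb & !is.na(s)
    n_s <- sum(s[in_sub] >= suprathreshold)
    n_m <- sum(m[in_sub] >= suprathreshold)
    data.frame(subject = subject, hemisphere = hemisphere,
               subregion = as.integer(lb), n_strio = n_s, n_matrix = n_m,
               volume_percent_matrix = volume_percent_matrix(n_s, n_m),
               defined = n_s + n_m > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Hemisphere-level suprathreshold quality control
#'
#' A hemisphere passes only if it holds at least
#' `min_suprathreshold_voxels` suprathreshold voxels (default 19, the
#' number of subregions considered) for both the striosome-favoring and
#' matrix-favoring distributions; failing hemispheres are excluded from
#' group statistics downstream.
#'
#' @param records data frame from [subregion_bias()] (possibly several
#'   subjects/hemispheres).
#' @param min_suprathreshold_voxels QC minimum per compartment.
#' @return Data frame with one row per (subject, hemisphere):
#'   `total_strio`, `total_matrix`, `qc_pass`.
#' @export
hemisphere_qc <- function(records, min_suprathreshold_voxels = 19L) {
  agg <- stats::aggregate(cbind(total_strio = n_strio,
                                total_matrix = n_matrix) ~
                            subject + hemisphere, data = records, FUN = sum)
  agg$qc_pass <- agg$total_strio >= min_suprathreshold_voxels &
    agg$total_matrix >= min_suprathreshold_voxels
  for (i in which(!agg$qc_pass))
    message(sprintf("hemisphere_qc: excluding %s/%s (strio %d, matrix %d < %d)",
                    agg$subject[i], agg$hemisphere[i], agg$total_strio[i],
                    agg$total_matrix[i], min_suprathreshold_voxels))
  agg
}

weighted_cog <- function(grid, weights_arr, keep) {
  lin <- which(keep & !is.na(weights_arr) & weights_arr > 0)
  if (!length(lin)) return(NULL)
  w <- weights_arr[lin]
  pos <- voxel_to_world(grid, linear_to_ijk(grid, lin))
  colSums(pos * w) / sum(w)
}

#' Centre-of-gravity geometry of compartment-favoring distributions
#'
#' Computes the probability-weighted COG of the matrix-favoring
#' distribution over the whole (retained) insula, and of the
#' striosome-favoring distribution separately rostral (y > split) and
#' caudal (y <= split) of the coronal split plane (default y = 1 mm, the
#' centre of the matrix cluster). Reports per-plane deltas and RMS
#' distances of each striosome COG from the matrix COG. For left
#' hemispheres, x can be mirrored so data pool across hemispheres.
#'
#' @param normalized output of [normalize_probability_pair()].
#' @param split_y world-mm coronal split; voxels exactly on the plane go
#'   caudal.
#' @param mirror_x mirror x about the midline (use for left hemispheres
#'   before pooling).
#' @return Data frame with rows `matrix_whole`, `strio_rostral`,
#'   `strio_caudal`: COG coordinates, per-plane deltas vs the matrix COG,
#'   and RMS distance. Empty clusters yield `NA` rows.
#' @export
cog_analysis <- function(normalized, split_y = 1, mirror_x = FALSE) {
  grid <- normalized$p_strio$grid
  keep <- normalized$retained$values
  ally <- voxel_to_world(grid, linear_to_ijk(grid, seq_len(prod(grid$shape))))[, 2]
  y_arr <- array(ally, grid$shape)
  cogs <- list(
    matrix_whole = weighted_cog(grid, normalized$p_matrix$values, keep),
    strio_rostral = weighted_cog(grid, normalized$p_strio$values,
                                 keep & y_arr > split_y),
    strio_caudal = weighted_cog(grid, normalized$p_strio$values,
                                keep & y_arr <= split_y))
  if (mirror_x)
    cogs <- lapply(cogs, function(v) if (is.null(v)) v else v * c(-1, 1, 1))
  mat <- cogs$matrix_whole
  row_of <- function(nm) {
    v <- cogs[[nm]]
    if (is.null(v))
      return(data.frame(cluster = nm, x = NA_real_, y = NA_real_, z = NA_real_,
                        dx = NA_real_, dy = NA_real_, dz = NA_real_,
                        rms_distance = NA_real_, stringsAsFactors = FALSE))
    d <- if (nm == "matrix_whole" || is.null(mat)) c(NA_real_, NA_real_, NA_real_)
         else v - mat
    data.frame(cluster = nm, x = v[1], y = v[2], z = v[3],
               dx = d[1], dy = d[2], dz = d[3],
               rms_distance = if (all(is.na(d))) NA_real_ else sqrt(sum(d^2)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(cogs), row_of))
  rownames(out) <- out$cluster
  out
}

#' Score an insulo-striate connectivity table into a probability pair
#'
#' Convenience wrapper: per seed voxel,
#' `p_strio = striosome_count / (striosome_count + matrix_count)` with
#' zero-count voxels unclassified, returned as volumes on the grid (the
#' round-5 quantification input).
#'
#' @param conn a [connectivity_table()] with groups `striosome_like`,
#'   `matrix_like`.
#' @return List with `p_strio`, `p_matrix` volumes.
#' @export
insular_probability_pair <- function(conn) {
  sc <- ctt_bias_score(conn, bait_grouping("striosome_like", "matrix_like"))
  sc[c("p_strio", "p_matrix")]
}
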