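#' Score striatal voxels for compartment-like connectivity
#'
#' For each seed voxel, the striosome-like probability is the pooled
#' streamline count to the striosome-favoring bait group divided by the
#' pooled count to both groups; the matrix-like probability is its
#' complement. Voxels whose pooled counts are both zero are unclassified
#' (`NA`), not 0.5 - a ratio of zeros carries no information and such
#' voxels are excluded from distributions and mask selection.
#'
#' @param conn a [connectivity_table()] whose target groups cover the bait
#'   regions (minus any `left_out`).
#' @param baits a [bait_grouping()]; a set `left_out` region's counts are
#'   excluded from the pooled sums.
#' @param pooling `"sum"` pools counts across a group's regions;
#'   `"mean"` averages per region first (both conventions are in use).
#' @return List with `p_strio` and `p_matrix` ([probability_volume()]s,
#'   `NA` off-seed and at unclassified voxels), `n_classified`, and the
#'   seed/classified bookkeeping used downstream.
#' @export
ctt_bias_score <- function(conn, baits, pooling = c("sum", "mean")) {
  pooling <- match.arg(pooling)
  s_regions <- setdiff(baits$striosome_group, baits$left_out)
  m_regions <- setdiff(baits$matrix_group, baits$left_out)
  if (!length(s_regions) || !length(m_regions))
    stop("a bait group is empty after excluding the left-out region")
  missing <- setdiff(c(s_regions, m_regions), conn$target_groups)
  if (length(missing))
    stop("connectivity table lacks target groups: ",
         paste(missing, collapse = ", "))
  agg <- if (pooling == "sum") rowSums else rowMeans
  S <- agg(conn$counts[, s_regions, drop = FALSE])
  M <- agg(conn$counts[, m_regions, drop = FALSE])
  tot <- S + M
  classified <- tot > 0
  if (!any(classified)) stop("all seed voxels are unclassified (zero counts)")
  p <- rep(NA_real_, length(S))
  p[classified] <- S[classified] / tot[classified]

  grid <- conn$grid
  vs <- array(NA_real_, grid$shape)
  lin <- ijk_to_linear(grid, conn$seeds)
  vs[lin] <- p
  list(p_strio = probability_volume(grid, vs),
       p_matrix = probability_volume(grid, 1 - vs),
       n_classified = sum(classified),
       seeds = conn$seeds, classified = classified)
}

## deterministic selection order: score descending, then lexicographic
## (i, j, k) voxel index
ordered_voxels_by_score <- function(voxels, score) {
  ord <- order(-score, voxels[, 1], voxels[, 2], voxels[, 3])
  voxels[ord, , drop = FALSE]
}

new_compartment_masks <- function(striosome_like, matrix_like, source) {
  canon <- function(v) {
    v <- matrix(as.integer(v), ncol = 3,
                dimnames = list(NULL, c("i", "j", "k")))
    v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  }
  structure(list(striosome_like = canon(striosome_like),
                 matrix_like = canon(matrix_like), source = source),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks: %d striosome-like, %d matrix-like voxels (%s)>\n",
              nrow(x$striosome_like), nrow(x$matrix_like),
              x$source$method %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## classified voxel indices + scores from a score pair
classified_scores <- function(p_strio, p_matrix) {
  stop_if_grid_mismatch(p_strio$grid, p_matrix$grid)
  lin <- which(!is.na(p_strio$values))
  ijk <- linear_to_ijk(p_strio$grid, lin)
  list(voxels = ijk, strio = p_strio$values[lin], matrix = p_matrix$values[lin])
}

#' Select equal-volume most-biased compartment masks
#'
#' Takes the uppermost `fraction` of classified voxels from each
#' compartment's bias distribution (default 13%, the operational form of
#' the 1.5 SD criterion), yielding two disjoint masks of exactly
#' `round(fraction * n_classified)` voxels each. Ties are broken by voxel
#' index (lexicographic on i, j, k) so selection is deterministic and
#' invariant to input row order.
#'
#' @param p_strio,p_matrix complementary [probability_volume()]s from
#'   [ctt_bias_score()].
#' @param fraction fraction of classified voxels per mask, in (0, 0.5);
#'   fractions >= 0.5 cannot guarantee disjoint masks for complementary
#'   scores and are rejected. When boundary ties would place a voxel in
#'   both masks, the striosome-like mask takes it and the matrix-like mask
#'   draws the next voxel in its own ordering, keeping the masks disjoint
#'   and the selection deterministic.
#' @return A `compartment_masks` object.
#' @export
select_equal_volume_masks <- function(p_strio, p_matrix, fraction = 0.13) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must lie in (0, 0.5)")
  cs <- classified_scores(p_strio, p_matrix)
  n <- nrow(cs$voxels)
  k <- round(fraction * n)
  if (k < 1) stop("too few classified voxels for the requested fraction")
  sel <- take_disjoint_top(cs$voxels, cs$strio, cs$matrix, k, k)
  new_compartment_masks(sel$striosome, sel$matrix,
                        list(method = "fraction", fraction = fraction,
                             n_classified = n, voxels_per_mask = k))
}

## top-k selection for both compartments with the shared tie policy:
## striosome first, matrix from the remaining voxels
take_disjoint_top <- function(voxels, strio_score, matrix_score, k_s, k_m) {
  strio_sel <- ordered_voxels_by_score(voxels, strio_score)[
    seq_len(k_s), , drop = FALSE]
  taken <- paste(strio_sel[, 1], strio_sel[, 2], strio_sel[, 3])
  free <- !(paste(voxels[, 1], voxels[, 2], voxels[, 3]) %in% taken)
  if (sum(free) < k_m)
    stop("too few voxels remain for the matrix-like mask")
  matrix_sel <- ordered_voxels_by_score(voxels[free, , drop = FALSE],
                                        matrix_score[free])[
    seq_len(k_m), , drop = FALSE]
  list(striosome = strio_sel, matrix = matrix_sel)
}

#' Leave-one-out (N-1) parcellation
#'
#' Re-scores the striatum with one bait region's counts excluded and
#' selects equal-volume masks, so the left-out region's compartment bias
#' can later be quantified without circularity.
#'
#' @param conn a [connectivity_table()].
#' @param baits a [bait_grouping()].
#' @param leave_out name of the bait region to exclude; must belong to one
#'   group (and not be its sole member).
#' @param fraction per-mask fraction as in [select_equal_volume_masks()].
#' @return A `compartment_masks` object; provenance records the left-out
#'   region.
#' @export
n1_parcellation <- function(conn, baits, leave_out, fraction = 0.13) {
  if (!leave_out %in% c(baits$striosome_group, baits$matrix_group))
    stop("leave_out region not found in either bait group: ", leave_out)
  b2 <- bait_grouping(setdiff(baits$striosome_group, leave_out),
                      setdiff(baits$matrix_group, leave_out))
  b2$left_out <- leave_out
  sc <- ctt_bias_score(conn, b2)
  masks <- select_equal_volume_masks(sc$p_strio, sc$p_matrix, fraction)
  masks$source$method <- "n1_fraction"
  masks$source$left_out <- leave_out
  masks
}

#' Nucleus-proportional compartment masks
#'
#' Instead of drawing the most-biased voxels from anywhere in the striatum,
#' each nucleus contributes a fixed quota (e.g. 80 caudate + 100 putamen
#' voxels per compartment), so caudate/putamen differences in connectivity
#' cannot masquerade as compartment effects. Selection within a nucleus is
#' by descending score with the standard tie-break; striosome-like and
#' matrix-like masks are equal-volume by construction.
#'
#' @param p_strio,p_matrix complementary score volumes.
#' @param nucleus_labels a [label_volume()] with legend names `caudate` and
#'   `putamen` (or matching the names of `quotas`).
#' @param quotas named integer vector, voxels per nucleus per compartment.
#' @return A `compartment_masks` object.
#' @export
proportional_masks <- function(p_strio, p_matrix, nucleus_labels,
                               quotas = c(caudate = 80L, putamen = 100L)) {
  cs <- classified_scores(p_strio, p_matrix)
  stop_if_grid_mismatch(p_strio$grid, nucleus_labels$grid)
  lin <- ijk_to_linear(nucleus_labels$grid, cs$voxels)
  nuc_of <- nucleus_labels$legend[as.character(nucleus_labels$values[lin])]
  sel <- list(striosome_like = NULL, matrix_like = NULL)
  for (nuc in names(quotas)) {
    in_nuc <- which(!is.na(nuc_of) & nuc_of == nuc)
    if (length(in_nuc) < 2L * quotas[[nuc]])
      stop(sprintf("nucleus '%s' holds only %d classified voxels; quota is %d",
                   nuc, length(in_nuc), quotas[[nuc]]))
    if (quotas[[nuc]] == 0L) next
    take <- take_disjoint_top(cs$voxels[in_nuc, , drop = FALSE],
                              cs$strio[in_nuc], cs$matrix[in_nuc],
                              quotas[[nuc]], quotas[[nuc]])
    sel$striosome_like <- rbind(sel$striosome_like, take$striosome)
    sel$matrix_like <- rbind(sel$matrix_like, take$matrix)
  }
  new_compartment_masks(sel$striosome_like, sel$matrix_like,
                        list(method = "proportional",
                             quotas = as.list(quotas)))
}

#' Write a compartment mask pair as NIfTI binary masks plus provenance
#'
#' @param masks a `compartment_masks`.
#' @param grid the [volume_grid()] the voxel indices refer to.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_compartment_masks <- function(masks, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cmp in c("striosome_like", "matrix_like")) {
    arr <- array(FALSE, grid$shape)
    arr[ijk_to_linear(grid, masks[[cmp]])] <- TRUE
    write_probability_volume(binary_volume(grid, arr),
                             file.path(dir, paste0(cmp, ".nii.gz")))
  }
  jsonlite::write_json(masks$source, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
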