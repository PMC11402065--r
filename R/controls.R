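#' Randomly jitter compartment masks into their striatal neighbourhood
#'
#' Every mask voxel is shifted independently by uniform integer offsets in
#' `[-jitter_max, jitter_max]` per plane, redrawn while the destination
#' (a) lies in either original mask, (b) falls outside the striatum, or
#' (c) collides with an already-placed shifted voxel. This yields
#' "neighbourhood" masks that keep the topographic organization of the
#' originals while abandoning connectivity-based selection.
#'
#' @param masks a `compartment_masks` pair.
#' @param striatum a [label_volume()] of striatal nuclei (nonzero =
#'   striatum), or a [binary_volume()].
#' @param jitter_max maximum per-plane shift in voxels.
#' @param seed RNG seed.
#' @param max_draws rejection-sampling budget per voxel.
#' @param forbid_outside_striatum,forbid_collisions rejection-rule toggles
#'   (both default on; the collision rule keeps the shifted mask a set of
#'   distinct voxels).
#' @return List with `masks` (the shifted `compartment_masks`) and
#'   `report` (class `jitter_report`): per-voxel shifts, mean absolute and
#'   net per-plane shifts (voxels and mm), RMS distance from the nucleus
#'   centroid before and after, and the number of rejected draws.
#' @export
jitter_masks <- function(masks, striatum, jitter_max = 3L, seed = 1L,
                         max_draws = 10000L,
                         forbid_outside_striatum = TRUE,
                         forbid_collisions = TRUE) {
  grid <- striatum$grid
  in_striatum <- if (inherits(striatum, "label_volume"))
    striatum$values > 0L else striatum$values
  orig <- rbind(masks$striosome_like, masks$matrix_like)
  orig_lin <- ijk_to_linear(grid, orig)
  forbidden <- array(FALSE, grid$shape)
  forbidden[orig_lin] <- TRUE
  occupied <- array(FALSE, grid$shape)

  set.seed(seed)
  vox_all <- orig
  n_vox <- nrow(vox_all)
  cmp_of <- rep(c("striosome_like", "matrix_like"),
                c(nrow(masks$striosome_like), nrow(masks$matrix_like)))
  offs <- (-jitter_max):jitter_max
  ## intrinsically free destinations per voxel, used to place the most
  ## constrained voxels first (greedy sequential placement can otherwise
  ## strand a voxel whose whole neighbourhood was claimed earlier)
  free_count <- vapply(seq_len(n_vox), function(v) {
    box <- as.matrix(expand.grid(i = vox_all[v, 1] + offs,
                                 j = vox_all[v, 2] + offs,
                                 k = vox_all[v, 3] + offs))
    box <- box[in_grid(grid, box), , drop = FALSE]
    lin <- ijk_to_linear(grid, box)
    ok <- !forbidden[lin]
    if (forbid_outside_striatum) ok <- ok & in_striatum[lin]
    sum(ok)
  }, integer(1))
  if (any(free_count == 0L)) {
    v <- which(free_count == 0L)[1]
    stop(sprintf("no admissible jitter destination for voxel (%d,%d,%d)",
                 vox_all[v, 1], vox_all[v, 2], vox_all[v, 3]))
  }

  per_pass <- 200L
  max_passes <- max(1L, max_draws %/% per_pass)
  n_rejected <- 0L
  shift_of <- NULL
  for (pass in seq_len(max_passes)) {
    order_v <- if (pass == 1L) order(free_count) else sample.int(n_vox)
    occupied <- array(FALSE, grid$shape)
    shift_try <- matrix(NA_integer_, n_vox, 3)
    stuck <- FALSE
    for (v in order_v) {
      placed <- FALSE
      for (draw in seq_len(per_pass)) {
        sh <- offs[sample.int(length(offs), 3L, replace = TRUE)]
        dest <- vox_all[v, ] + sh
        ok <- in_grid(grid, matrix(dest, 1))
        if (ok) {
          dl <- ijk_to_linear(grid, matrix(dest, 1))
          ok <- !forbidden[dl] &&
            (!forbid_outside_striatum || in_striatum[dl]) &&
            (!forbid_collisions || !occupied[dl])
        }
        if (ok) {
          shift_try[v, ] <- sh
          occupied[dl] <- TRUE
          placed <- TRUE
          break
        }
        n_rejected <- n_rejected + 1L
      }
      if (!placed) { stuck <- TRUE; break }
    }
    if (!stuck) { shift_of <- shift_try; break }
  }
  if (is.null(shift_of)) {
    v <- order_v[1]
    stop(sprintf("jitter draw budget exhausted for voxel (%d,%d,%d)",
                 vox_all[v, 1], vox_all[v, 2], vox_all[v, 3]))
  }
  shift_all <- shift_of
  dest_all <- vox_all + shift_of
  shifted <- list(striosome_like = dest_all[cmp_of == "striosome_like", ,
                                            drop = FALSE],
                  matrix_like = dest_all[cmp_of == "matrix_like", ,
                                         drop = FALSE])

  new_masks <- new_compartment_masks(shifted$striosome_like,
                                     shifted$matrix_like,
                                     c(masks$source,
                                       list(jitter_max = jitter_max,
                                            jitter_seed = seed)))
  rms_from_centroid <- function(vox_mat) {
    w <- voxel_to_world(grid, vox_mat)
    ctr <- colMeans(voxel_to_world(grid, voxels_where(grid, in_striatum)))
    sqrt(mean(rowSums(sweep(w, 2, ctr)^2)))
  }
  report <- structure(list(
    shifts = shift_all,
    mean_abs_shift_per_plane = colMeans(abs(shift_all)),
    mean_net_shift_per_plane_mm = colMeans(shift_all) * grid$voxel_size,
    rms_from_centroid_before = rms_from_centroid(orig),
    rms_from_centroid_after = rms_from_centroid(rbind(new_masks$striosome_like,
                                                      new_masks$matrix_like)),
    n_rejected_draws = n_rejected), class = "jitter_report")
  list(masks = new_masks, report = report)
}

check_pairing <- function(a, b) {
  key <- function(d) paste(d$subject, d$hemisphere, d$subregion)
  if (!setequal(key(a), key(b)) || nrow(a) != nrow(b))
    stop("record tables disagree on subject/hemisphere/subregion pairing")
  b[match(key(a), key(b)), , drop = FALSE]
}

#' Compare precise and neighbourhood (jittered) subregion bias
#'
#' Per subregion, paired comparison of the matrix volume percent between
#' tractography targeting the precisely selected compartment masks and
#' tractography targeting their jittered neighbours, Bonferroni-corrected
#' across subregions.
#'
#' @param bias_precise,bias_shifted [subregion_bias()] record tables over
#'   the same subjects and hemispheres.
#' @param family_size Bonferroni family size (default 19).
#' @return Data frame: `subregion`, `mean_precise`, `mean_shifted`,
#'   `delta` (shifted - precise), `t`, `p`, `verdict`.
#' @export
neighborhood_comparison <- function(bias_precise, bias_shifted,
                                    family_size = 19L) {
  bias_shifted <- check_pairing(bias_precise, bias_shifted)
  out <- NULL
  for (sr in sort(unique(bias_precise$subregion))) {
    a <- bias_precise[bias_precise$subregion == sr, ]
    b <- bias_shifted[bias_shifted$subregion == sr, ]
    ok <- !is.na(a$volume_percent_matrix) & !is.na(b$volume_percent_matrix)
    delta <- mean(b$volume_percent_matrix[ok] - a$volume_percent_matrix[ok])
    tt <- if (sum(ok) >= 3L)
      paired_t_family(b$volume_percent_matrix[ok],
                      a$volume_percent_matrix[ok], family_size)
    else list(t = NA_real_, p = NA_real_, verdict = "ns")
    out <- rbind(out, data.frame(
      subregion = sr,
      mean_precise = mean(a$volume_percent_matrix[ok]),
      mean_shifted = mean(b$volume_percent_matrix[ok]),
      delta = delta, t = tt$t, p = tt$p, verdict = tt$verdict,
      stringsAsFactors = FALSE))
  }
  out
}

#' Compare standard and nucleus-proportional mask conditions
#'
#' Per-subregion mean change in matrix volume percent between the standard
#' (whole-striatum) and proportional (per-nucleus quota) mask conditions,
#' the rank correlation of subregion bias orderings, and any subregion
#' whose bias direction flips across conditions.
#'
#' @param bias_standard,bias_proportional [subregion_bias()] record tables
#'   over the same subjects and hemispheres.
#' @return List with `per_subregion` (data frame: subregion, means, delta,
#'   `sign_flip`), `rank_correlation` (Spearman over subregion means) and
#'   `flipped_subregions`.
#' @export
proportional_comparison <- function(bias_standard, bias_proportional) {
  bias_proportional <- check_pairing(bias_standard, bias_proportional)
  mean_by <- function(d) {
    agg <- stats::aggregate(volume_percent_matrix ~ subregion, data = d,
                            FUN = mean, na.action = stats::na.omit)
    agg[order(agg$subregion), ]
  }
  ms <- mean_by(bias_standard)
  mp <- mean_by(bias_proportional)
  stopifnot(all(ms$subregion == mp$subregion))
  sign_of <- function(x) sign(x - 50)
  flips <- sign_of(ms$volume_percent_matrix) * sign_of(mp$volume_percent_matrix) < 0
  per <- data.frame(subregion = ms$subregion,
                    mean_standard = ms$volume_percent_matrix,
                    mean_proportional = mp$volume_percent_matrix,
                    delta = mp$volume_percent_matrix - ms$volume_percent_matrix,
                    sign_flip = flips)
  list(per_subregion = per,
       rank_correlation = stats::cor(ms$volume_percent_matrix,
                                     mp$volume_percent_matrix,
                                     method = "spearman"),
       flipped_subregions = per$subregion[flips])
}
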