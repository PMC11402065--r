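#' Bait-region grouping
#'
#' Named extra-striatal regions with compartment-selective afferents,
#' grouped into striosome-favoring and matrix-favoring sets. The default
#' is the insula-free grouping: 4 striosome-favoring regions (mediodorsal
#' thalamus, posterior orbitofrontal cortex, basolateral amygdala, basal
#' operculum) and 5 matrix-favoring regions (supplementary motor area,
#' primary motor cortex, primary sensory cortex, globus pallidus interna,
#' VL/VPL thalamus).
#'
#' @param striosome_group character vector of striosome-favoring region names.
#' @param matrix_group character vector of matrix-favoring region names.
#' @param left_out optional region name excluded from scoring (N-1 analysis);
#'   must not be listed in either group.
#' @return An object of class `bait_grouping`.
#' @export
bait_grouping <- function(striosome_group, matrix_group, left_out = NULL) {
  if (!length(striosome_group) || !length(matrix_group))
    stop("both bait groups must be non-empty")
  if (length(intersect(striosome_group, matrix_group)))
    stop("bait groups must be disjoint")
  if (!is.null(left_out) && left_out %in% c(striosome_group, matrix_group))
    stop("left_out region must be absent from both groups")
  structure(list(striosome_group = striosome_group,
                 matrix_group = matrix_group, left_out = left_out),
            class = "bait_grouping")
}

#' @rdname bait_grouping
#' @export
default_bait_grouping <- function() {
  bait_grouping(
    striosome_group = c("mediodorsal_thalamus", "posterior_orbitofrontal",
                        "basolateral_amygdala", "basal_operculum"),
    matrix_group = c("supplementary_motor", "primary_motor",
                     "primary_sensory", "globus_pallidus_interna",
                     "vl_vpl_thalamus"))
}

#' Default phantom grid
#'
#' A right-hemisphere 1.5 mm isotropic lattice large enough to hold the
#' phantom caudate, putamen and insular sheet, with the midline at x = 0.
#'
#' @return A [volume_grid()].
#' @export
default_phantom_grid <- function() {
  volume_grid(shape = c(28L, 34L, 28L), voxel_size = c(1.5, 1.5, 1.5),
              origin = c(0, -24, -21), space = "phantom", hemisphere = "right")
}

## 0-based ijk of voxels where a 3-D logical/indexable condition holds,
## in canonical (i, then j, then k) order
voxels_where <- function(grid, cond) {
  ijk <- linear_to_ijk(grid, which(cond))
  ijk[order(ijk[, 1], ijk[, 2], ijk[, 3]), , drop = FALSE]
}

ellipsoid_mask <- function(grid, centre, radii) {
  ijk <- linear_to_ijk(grid, seq_len(prod(grid$shape)))
  w <- voxel_to_world(grid, ijk)
  d <- ((w[, 1] - centre[1]) / radii[1])^2 +
       ((w[, 2] - centre[2]) / radii[2])^2 +
       ((w[, 3] - centre[3]) / radii[3])^2
  array(d <= 1, dim = grid$shape)
}

## draw one Beta value per element around mean mu with concentration kappa;
## kappa = Inf degenerates to mu, and mu in {0,1} is returned exactly
rbeta_mean <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep_len(mu, n))
  mu <- rep_len(mu, n)
  out <- mu
  ok <- mu > 0 & mu < 1
  out[ok] <- stats::rbeta(sum(ok), mu[ok] * kappa, (1 - mu[ok]) * kappa)
  out
}

#' Generate the phantom striatum with ground-truth compartments
#'
#' Lays down two ellipsoidal nuclei (caudate medial, putamen lateral) and a
#' dispersed, connected striosome labyrinth grown by random-walk branches
#' whose seeding and growth are weighted by a spatial intensity that
#' increases medially, rostrally and ventrally (the gradients reported for
#' striosome enrichment in tissue); the remaining striatal voxels are
#' matrix. The striosome voxel count is exact: `round(fraction * N)`.
#'
#' @param grid a [volume_grid()]; default [default_phantom_grid()].
#' @param striosome_fraction target striosome fraction of striatal volume.
#' @param gradient_strengths length-3 non-negative weights of the
#'   medio-lateral, rostro-caudal and dorso-ventral gradients (0 = no
#'   spatial bias on that axis).
#' @param branch_penalty multiplicative growth penalty per striosome
#'   6-neighbour of a candidate voxel; values < 1 keep the labyrinth
#'   thin and dispersed (1-voxel-wide branches with matrix between them)
#'   rather than letting it coalesce into solid blobs at the gradient
#'   peak.
#' @param seed RNG seed.
#' @return An object of class `phantom_truth` with elements
#'   `grid`, `nucleus_labels` (1 = caudate, 2 = putamen),
#'   `compartment_labels` (1 = striosome, 2 = matrix), and the generator
#'   parameters.
#' @export
make_striatum <- function(grid = default_phantom_grid(),
                          striosome_fraction = 0.15,
                          gradient_strengths = c(1, 1, 1),
                          branch_penalty = 0.35,
                          seed = 1L) {
  if (striosome_fraction > 0.5)
    stop("striosome_fraction > 0.5 is infeasible")
  set.seed(seed)
  caud <- ellipsoid_mask(grid, c(9, 6, 2), c(6, 14, 8))
  put <- ellipsoid_mask(grid, c(22.5, 0, -2), c(7.5, 12, 9)) & !caud
  if (sum(caud) < 500 || sum(put) < 500)
    stop("grid too small to hold the phantom nuclei")
  nucleus <- array(0L, grid$shape)
  nucleus[caud] <- 1L
  nucleus[put] <- 2L
  striat <- nucleus > 0L

  ## intensity gradients computed within each nucleus: histology reports
  ## the ~15% striosome fraction and the spatial gradients for caudate and
  ## putamen alike, so the labyrinth is grown per nucleus with a
  ## per-nucleus voxel quota
  g <- gradient_strengths
  intensity <- array(0, grid$shape)
  for (nuc in 1:2) {
    lin_nuc <- which(nucleus == nuc)
    z <- scale(voxel_to_world(grid, linear_to_ijk(grid, lin_nuc)))
    ## medial = small x (right hemisphere), rostral = large y,
    ## ventral = small z
    intensity[lin_nuc] <- exp(-g[1] * z[, 1] + g[2] * z[, 2] - g[3] * z[, 3])
  }

  strio <- array(FALSE, grid$shape)
  nb_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (nuc in 1:2) {
    lin_nuc <- which(nucleus == nuc)
    k_target <- round(striosome_fraction * length(lin_nuc))
    n_seeds <- max(1L, round(k_target / 50))
    seed_lin <- if (n_seeds >= length(lin_nuc)) lin_nuc else
      sample(lin_nuc, n_seeds, prob = intensity[lin_nuc])
    strio[seed_lin] <- TRUE
    members <- seed_lin
    count <- length(members)
    guard <- 0L
    while (count < k_target) {
      guard <- guard + 1L
      if (guard > 200L * k_target) stop("striosome growth failed to converge")
      v <- members[sample.int(count, 1L)]
      ijk <- linear_to_ijk(grid, v)
      nb <- sweep(nb_off, 2, as.numeric(ijk), "+")
      nb <- nb[in_grid(grid, nb), , drop = FALSE]
      if (!nrow(nb)) next
      nl <- ijk_to_linear(grid, nb)
      nl <- nl[nucleus[nl] == nuc & !strio[nl]]
      if (!length(nl)) {
        ## local saturation: occasionally restart a branch at a fresh
        ## intensity-weighted site
        if (stats::runif(1) < 0.02) {
          free <- lin_nuc[!strio[lin_nuc]]
          v2 <- if (length(free) == 1L) free else
            sample(free, 1L, prob = intensity[free])
          strio[v2] <- TRUE
          members <- c(members, v2)
          count <- count + 1L
        }
        next
      }
      ## thin-branch rule: growing into a voxel already touching several
      ## striosome voxels is penalized, keeping the labyrinth dispersed
      wgt <- intensity[nl]
      if (branch_penalty < 1) {
        for (q in seq_along(nl)) {
          nijk <- linear_to_ijk(grid, nl[q])
          nnb <- sweep(nb_off, 2, as.numeric(nijk), "+")
          nnb <- nnb[in_grid(grid, nnb), , drop = FALSE]
          k_nb <- sum(strio[ijk_to_linear(grid, nnb)])
          wgt[q] <- wgt[q] * branch_penalty^(k_nb - 1L)
        }
      }
      pick <- if (length(nl) == 1L) nl else sample(nl, 1L, prob = wgt)
      strio[pick] <- TRUE
      members <- c(members, pick)
      count <- count + 1L
    }
  }

  compartment <- array(0L, grid$shape)
  compartment[striat] <- 2L
  compartment[strio] <- 1L
  structure(list(
    grid = grid,
    nucleus_labels = label_volume(grid, nucleus,
                                  c(`1` = "caudate", `2` = "putamen")),
    compartment_labels = label_volume(grid, compartment,
                                      c(`1` = "striosome", `2` = "matrix")),
    striosome_fraction = striosome_fraction,
    gradient_strengths = gradient_strengths,
    rng_seed = seed), class = "phantom_truth")
}

#' Default per-subregion compartment-bias profile
#'
#' The true probability that a streamline seeded in each insular subregion
#' targets striosome tissue, ordered from the most rostroventral subregion
#' (1) to the most caudodorsal (`n`). The 19-subregion default mirrors the
#' reported pattern: 7 striosome-leaning (> 0.55), 3 near-neutral, and 9
#' matrix-leaning (< 0.45) subregions. Other lengths interpolate this
#' profile.
#'
#' @param n number of subregions.
#' @return Numeric vector of length `n`, named by subregion index.
#' @export
default_bias_profile <- function(n = 19L) {
  base <- c(0.90, 0.85, 0.80, 0.75, 0.72, 0.68, 0.62,
            0.53, 0.50, 0.47,
            0.42, 0.38, 0.34, 0.30, 0.26, 0.22, 0.18, 0.14, 0.10)
  prof <- if (n == 19L) base else
    stats::approx(seq(0, 1, length.out = 19L), base,
                  xout = seq(0, 1, length.out = n))$y
  stats::setNames(prof, seq_len(n))
}

#' Add the phantom insular sheet and its subregions
#'
#' Builds a two-voxel-thick elliptical sheet lateral to the striatum and
#' partitions it into `n_subregions` contiguous bands along the
#' rostroventral-to-caudodorsal axis. Subregion 1 is the most rostroventral.
#'
#' @param truth a `phantom_truth` from [make_striatum()].
#' @param n_subregions number of insular subregions (>= 2).
#' @param true_bias_profile per-subregion true striosome-targeting
#'   probabilities in \[0, 1\]; default [default_bias_profile()].
#' @return `truth` with `insula_labels` and `subregion_true_bias` added.
#' @export
make_insula <- function(truth, n_subregions = 19L, true_bias_profile = NULL) {
  grid <- truth$grid
  if (n_subregions < 2L) stop("n_subregions must be >= 2")
  if (is.null(true_bias_profile))
    true_bias_profile <- default_bias_profile(n_subregions)
  if (length(true_bias_profile) != n_subregions)
    stop("true_bias_profile length must equal n_subregions")
  if (any(true_bias_profile < 0 | true_bias_profile > 1))
    stop("biases must lie in [0, 1]")

  ijk <- linear_to_ijk(grid, seq_len(prod(grid$shape)))
  w <- voxel_to_world(grid, ijk)
  sheet <- w[, 1] >= 32.5 & w[, 1] <= 35.5 &
    ((w[, 2] - 1.5) / 20)^2 + (w[, 3] / 13)^2 <= 1
  n_vox <- sum(sheet)
  if (n_subregions > n_vox)
    stop("more subregions than insular sheet voxels")

  ## rostroventral (large y, small z) -> caudodorsal axis
  ys <- w[sheet, 2]; zs <- w[sheet, 3]
  u <- -(ys - mean(ys)) / stats::sd(ys) + (zs - mean(zs)) / stats::sd(zs)
  band <- ceiling(rank(u, ties.method = "first") / n_vox * n_subregions)
  labels <- array(0L, grid$shape)
  labels[sheet] <- as.integer(band)
  truth$insula_labels <- label_volume(
    grid, labels,
    stats::setNames(paste0("insula_", seq_len(n_subregions)),
                    seq_len(n_subregions)))
  truth$subregion_true_bias <- stats::setNames(as.numeric(true_bias_profile),
                                               seq_len(n_subregions))
  truth
}

#' Generate a complete phantom (striatum + insula)
#'
#' @inheritParams make_striatum
#' @inheritParams make_insula
#' @return A `phantom_truth` with striatal and insular components.
#' @export
make_phantom <- function(grid = default_phantom_grid(),
                         striosome_fraction = 0.15,
                         gradient_strengths = c(1, 1, 1),
                         n_subregions = 19L, true_bias_profile = NULL,
                         branch_penalty = 0.35, seed = 1L) {
  make_insula(make_striatum(grid, striosome_fraction, gradient_strengths,
                            branch_penalty = branch_penalty, seed = seed),
              n_subregions, true_bias_profile)
}

#' Simulate classification-targets tractography of the striatum
#'
#' For each striatal voxel, streamline counts to the bait regions are drawn
#' multinomially. A voxel of true compartment c directs a fraction of its
#' streamlines to the concordant bait group and the rest to the discordant
#' group; that fraction is Beta-distributed around `fidelity` with
#' concentration `voxel_kappa`, reflecting partial-volume mixing of tissue
#' within a voxel (millimetre-scale voxels always sample some of both
#' compartments). Within a group, counts split across regions by
#' `region_weights`. An optional `lapse` fraction of streamlines reaches no
#' target, and a distance-correction toggle rescales counts by a nominal
#' seed-to-region path length.
#'
#' @param truth a `phantom_truth`.
#' @param baits a [bait_grouping()].
#' @param streamlines_per_seed streamlines seeded per voxel (default 5000).
#' @param fidelity mean concordant-group probability, in \[0.5, 1\].
#' @param voxel_kappa Beta concentration of per-voxel concordance
#'   (`Inf` = no voxel-to-voxel heterogeneity).
#' @param lapse probability a streamline reaches no target.
#' @param region_weights named non-negative weights over bait regions
#'   (default equal within each group).
#' @param distance_correction if `TRUE`, counts are rescaled by nominal
#'   region path lengths (real-valued counts, as distance-corrected
#'   tractography yields).
#' @param seed RNG seed.
#' @return A [connectivity_table()] with one column per bait region.
#' @export
simulate_ctt <- function(truth, baits = default_bait_grouping(),
                         streamlines_per_seed = 5000L, fidelity = 0.8,
                         voxel_kappa = 25, lapse = 0,
                         region_weights = NULL,
                         distance_correction = FALSE, seed = 1L) {
  if (fidelity < 0.5 || fidelity > 1) stop("fidelity must lie in [0.5, 1]")
  if (streamlines_per_seed <= 0) stop("streamlines_per_seed must be positive")
  set.seed(seed)
  grid <- truth$grid
  regions <- c(baits$striosome_group, baits$matrix_group)
  if (is.null(region_weights))
    region_weights <- stats::setNames(rep(1, length(regions)), regions)
  seeds <- voxels_where(grid, truth$compartment_labels$values > 0L)
  comp <- truth$compartment_labels$values[ijk_to_linear(grid, seeds)]
  n <- nrow(seeds)
  conc <- rbeta_mean(n, fidelity, voxel_kappa)

  ws <- region_weights[baits$striosome_group]
  wm <- region_weights[baits$matrix_group]
  ws <- ws / sum(ws); wm <- wm / sum(wm)
  counts <- matrix(0, n, length(regions),
                   dimnames = list(NULL, regions))
  for (v in seq_len(n)) {
    p_strio_grp <- if (comp[v] == 1L) conc[v] else 1 - conc[v]
    p <- c(p_strio_grp * ws, (1 - p_strio_grp) * wm) * (1 - lapse)
    draw <- stats::rmultinom(1, streamlines_per_seed, c(p, lapse))
    counts[v, ] <- draw[seq_along(regions)]
  }
  if (distance_correction) {
    dist_mm <- stats::setNames(
      seq(40, 80, length.out = length(regions)), regions)
    counts <- sweep(counts, 2, dist_mm / 50, "*")
    ## rescaled counts may exceed the seeded number; the table stores the
    ## effective bound
    streamlines_per_seed <- ceiling(max(rowSums(counts)))
  }
  connectivity_table(grid, seeds, counts, streamlines_per_seed)
}

## ground-truth compartment fractions of an arbitrary voxel set
mask_compartment_fraction <- function(truth, voxels) {
  comp <- truth$compartment_labels$values[ijk_to_linear(truth$grid, voxels)]
  c(striosome = mean(comp == 1L), matrix = mean(comp == 2L))
}

#' Ground-truth purity of a compartment mask pair
#'
#' @param masks a `compartment_masks` pair.
#' @param truth the `phantom_truth` the masks were derived from.
#' @return Named vector: fraction of striosome-like mask voxels that are
#'   true striosome, and of matrix-like mask voxels that are true matrix.
#' @export
mask_purity <- function(masks, truth) {
  c(striosome = unname(mask_compartment_fraction(truth,
                                                 masks$striosome_like)["striosome"]),
    matrix = unname(mask_compartment_fraction(truth,
                                              masks$matrix_like)["matrix"]))
}

## rasterize straight voxel-to-voxel segments, accumulating per-voxel visit
## weights; each segment contributes its weight once per voxel it crosses
rasterize_segments <- function(grid, from, to, weights) {
  dens <- array(0, grid$shape)
  n <- nrow(from)
  if (!n) return(dens)
  cheb <- apply(abs(to - from), 1, max)
  n_steps <- 2L * max(1L, ceiling(max(cheb))) + 1L
  tt <- seq(0, 1, length.out = n_steps)
  nvox <- prod(grid$shape)
  seg_id <- rep(seq_len(n), times = n_steps)
  lin <- integer(n * n_steps)
  for (s in seq_len(n_steps)) {
    p <- round(from + tt[s] * (to - from))
    lin[((s - 1L) * n + 1L):(s * n)] <- ijk_to_linear(grid, p)
  }
  key <- as.numeric(seg_id) * nvox + lin
  keep <- !duplicated(key)
  acc <- rowsum(weights[seg_id[keep]], lin[keep])
  dens[as.integer(rownames(acc))] <- acc[, 1]
  dens
}

#' Simulate insulo-striate tractography against compartment target masks
#'
#' Each insular voxel of subregion s aims its streamlines at the
#' striosome-labelled target mask with a probability Beta-distributed
#' around `subregion_true_bias[s]`, and at the matrix-labelled mask with
#' the complement; a streamline lands on a uniformly drawn voxel of the
#' aimed mask. The streamline is scored as striosome-favoring or
#' matrix-favoring by the ground-truth tissue of its landing voxel. For
#' pure masks aim and tissue coincide, so counts follow b versus 1 - b
#' exactly; for impure masks (the jittered neighbourhood control, where
#' random relocation lands mostly in matrix tissue) the measured bias
#' shifts toward the tissue actually occupying the masks - the effect the
#' control exists to expose.
#'
#' Path-density maps are produced by rasterizing straight segments from each
#' seed to multinomially drawn voxels of the aimed mask. At most
#' `max_targets` distinct targets are rasterized per (seed, mask) with the
#' total streamline weight conserved.
#'
#' @param truth a `phantom_truth` with insula.
#' @param masks a `compartment_masks` pair (the tractography targets).
#' @param streamlines_per_seed streamlines per insular voxel (5000 for
#'   bundle mapping, 50000 for subregion quantification).
#' @param voxel_kappa Beta concentration of per-voxel insular bias.
#' @param lapse probability a streamline reaches neither mask.
#' @param subregions optional integer vector restricting the seeded
#'   subregions (used to build spatially separated bundles).
#' @param rasterize whether to build path-density maps (slower).
#' @param max_targets rasterized distinct targets per seed and mask.
#' @param seed RNG seed.
#' @return List with `counts` (a [connectivity_table()] with groups
#'   `striosome_like` / `matrix_like`), and when `rasterize = TRUE`,
#'   `density_striosome` and `density_matrix` ([probability_volume()]s of
#'   raw visit counts).
#' @export
simulate_insulo_striate <- function(truth, masks, streamlines_per_seed = 5000L,
                                    voxel_kappa = 30, lapse = 0,
                                    subregions = NULL, rasterize = FALSE,
                                    max_targets = 30L, seed = 1L) {
  if (!nrow(masks$striosome_like) || !nrow(masks$matrix_like))
    stop("target masks must be non-empty")
  if (is.null(truth$insula_labels))
    stop("phantom has no insula; call make_insula() first")
  set.seed(seed)
  grid <- truth$grid
  lab <- truth$insula_labels$values
  keep <- if (is.null(subregions)) lab > 0L else lab %in% subregions
  seeds <- voxels_where(grid, keep)
  sub <- lab[ijk_to_linear(grid, seeds)]
  n <- nrow(seeds)
  if (!n) stop("no insular seed voxels selected")
  b_true <- truth$subregion_true_bias[as.character(sub)]
  b <- rbeta_mean(n, b_true, voxel_kappa)

  fA <- mask_compartment_fraction(truth, masks$striosome_like)["striosome"]
  fB <- mask_compartment_fraction(truth, masks$matrix_like)["striosome"]
  counts <- matrix(0, n, 2, dimnames = list(NULL, c("striosome_like",
                                                    "matrix_like")))
  aimed <- matrix(0, n, 2)  # streamlines aimed at each mask (for densities)
  for (v in seq_len(n)) {
    aim <- stats::rmultinom(1, streamlines_per_seed,
                            c(b[v] * (1 - lapse),
                              (1 - b[v]) * (1 - lapse), lapse))
    aimed[v, ] <- aim[1:2]
    hit_strio <- stats::rbinom(1L, aim[1], fA) + stats::rbinom(1L, aim[2], fB)
    counts[v, ] <- c(hit_strio, aim[1] + aim[2] - hit_strio)
  }
  out <- list(counts = connectivity_table(grid, seeds, counts,
                                          streamlines_per_seed))
  if (rasterize) {
    for (cmp in c("striosome_like", "matrix_like")) {
      targ <- if (cmp == "striosome_like") masks$striosome_like else
        masks$matrix_like
      col <- aimed[, if (cmp == "striosome_like") 1L else 2L]
      froms <- NULL; tos <- NULL; wts <- NULL
      for (v in which(col > 0)) {
        m <- min(max_targets, col[v])
        idx <- sample.int(nrow(targ), m, replace = TRUE)
        froms <- rbind(froms, seeds[rep(v, m), , drop = FALSE])
        tos <- rbind(tos, targ[idx, , drop = FALSE])
        wts <- c(wts, rep(col[v] / m, m))
      }
      dens <- if (is.null(froms)) array(0, grid$shape) else
        rasterize_segments(grid, froms, tos, wts)
      out[[paste0("density_", sub("_like", "", cmp))]] <-
        probability_volume(grid, dens, probability = FALSE)
    }
  }
  out
}

#' Simulate classification-targets tractography from a cortical region
#'
#' Stands in for the round-3 quantification: a synthetic cortical seed
#' region (a voxel box placed dorsal to the striatum) whose voxels target
#' striosome tissue with probability Beta-distributed around
#' `true_striosome_bias`, scored against a compartment mask pair exactly as
#' [simulate_insulo_striate()] scores insular seeds.
#'
#' @param truth a `phantom_truth`.
#' @param masks a `compartment_masks` pair (targets).
#' @param true_striosome_bias mean probability a streamline targets
#'   striosome tissue (e.g. 0.05 for a motor-like region, 0.95 for an
#'   orbitofrontal-like region).
#' @param n_voxels number of seed voxels in the synthetic region.
#' @param streamlines_per_seed streamlines per seed voxel.
#' @param voxel_kappa Beta concentration of per-voxel bias.
#' @param seed RNG seed.
#' @return A [connectivity_table()] with groups `striosome_like` /
#'   `matrix_like`.
#' @export
simulate_cortical_ctt <- function(truth, masks, true_striosome_bias,
                                  n_voxels = 150L,
                                  streamlines_per_seed = 50000L,
                                  voxel_kappa = 25, seed = 1L) {
  set.seed(seed)
  grid <- truth$grid
  ## a compact box near the dorsal grid face, clear of the striatum
  k0 <- grid$shape[3] - 3L
  cand <- as.matrix(expand.grid(i = 2:(grid$shape[1] - 3L),
                                j = 2:(grid$shape[2] - 3L),
                                k = k0:(grid$shape[3] - 2L)))
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  if (n_voxels > nrow(cand)) stop("n_voxels exceeds available region voxels")
  seeds <- cand[seq_len(n_voxels), , drop = FALSE]
  b <- rbeta_mean(n_voxels, true_striosome_bias, voxel_kappa)
  fA <- mask_compartment_fraction(truth, masks$striosome_like)["striosome"]
  fB <- mask_compartment_fraction(truth, masks$matrix_like)["striosome"]
  counts <- matrix(0, n_voxels, 2,
                   dimnames = list(NULL, c("striosome_like", "matrix_like")))
  for (v in seq_len(n_voxels)) {
    aim <- stats::rbinom(1L, streamlines_per_seed, b[v])
    hit_strio <- stats::rbinom(1L, aim, fA) +
      stats::rbinom(1L, streamlines_per_seed - aim, fB)
    counts[v, ] <- c(hit_strio, streamlines_per_seed - hit_strio)
  }
  connectivity_table(grid, seeds, counts, streamlines_per_seed)
}

#' Synthetic subject covariates for the phantom cohort
#'
#' @param subjects character vector of subject ids.
#' @param seed RNG seed.
#' @return Data frame with `subject`, `sex`, `handedness` (-100..100),
#'   `race` (3 levels), `age` (years).
#' @export
phantom_covariates <- function(subjects, seed = 1L) {
  set.seed(seed)
  n <- length(subjects)
  data.frame(subject = subjects,
             sex = sample(c("F", "M"), n, replace = TRUE),
             handedness = round(stats::runif(n, -100, 100)),
             race = sample(paste0("group", 1:3), n, replace = TRUE),
             age = sample(22:35, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write phantom volumes and ground truth to a directory
#'
#' Writes NIfTI label volumes for compartments, nuclei and insula, plus a
#' JSON truth record (fractions, gradients, per-subregion biases, seed)
#' sufficient for parameter-recovery tests.
#'
#' @param truth a `phantom_truth`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_phantom <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_volume(truth$compartment_labels,
                     file.path(dir, "compartments.nii.gz"))
  write_label_volume(truth$nucleus_labels, file.path(dir, "nuclei.nii.gz"))
  if (!is.null(truth$insula_labels))
    write_label_volume(truth$insula_labels, file.path(dir, "insula.nii.gz"))
  jsonlite::write_json(
    list(striosome_fraction = truth$striosome_fraction,
         gradient_strengths = truth$gradient_strengths,
         subregion_true_bias = as.list(truth$subregion_true_bias),
         rng_seed = truth$rng_seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
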