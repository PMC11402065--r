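# Shared fixtures: everything is built in code at test time.

tiny_grid <- function(shape = c(6L, 6L, 6L), voxel = 1.5) {
  volume_grid(shape, voxel_size = rep(voxel, 3),
              origin = -voxel * (shape - 1) / 2)
}

# a probability pair on a tiny grid from explicit per-voxel scores;
# `scores` is a data.frame with i, j, k, p (striosome probability)
score_pair <- function(grid, scores) {
  s <- array(NA_real_, grid$shape)
  s[ijk_mat_to_lin(grid, as.matrix(scores[, c("i", "j", "k")]))] <- scores$p
  list(p_strio = probability_volume(grid, s),
       p_matrix = probability_volume(grid, 1 - s))
}

ijk_mat_to_lin <- function(grid, ijk) {
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

# standard small phantom + round-1 scoring, memoised per test file run
phantom_round1 <- local({
  cache <- NULL
  function(seed = 11L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    ph <- make_phantom(seed = seed)
    conn <- simulate_ctt(ph, seed = seed + 1L)
    sc <- ctt_bias_score(conn, default_bait_grouping())
    masks <- select_equal_volume_masks(sc$p_strio, sc$p_matrix)
    cache <<- list(seed = seed, truth = ph, conn = conn, scores = sc,
                   masks = masks)
    cache
  }
})

# pure ground-truth compartment masks (used where mask purity must be 1)
truth_masks <- function(truth, n_per = 50L) {
  comp <- truth$compartment_labels$values
  grid <- truth$grid
  vox_of <- function(lab) {
    v <- which(comp == lab)
    ijk <- cbind(
      (v - 1L) %% grid$shape[1],
      ((v - 1L) %/% grid$shape[1]) %% grid$shape[2],
      (v - 1L) %/% (grid$shape[1] * grid$shape[2]))
    ijk[seq_len(min(n_per, nrow(ijk))), , drop = FALSE]
  }
  striatparc:::new_compartment_masks(vox_of(1L), vox_of(2L),
                                     list(method = "truth"))
}

# long-format bias records with an optional planted compartment effect;
# the two compartments carry independent errors (the calibration regime
# of an ANCOVA with independent rows). Real volume percents are mirrored
# complements; the repeated-measures reduction handles that pairing.
make_bias_records <- function(n_subjects, subregions = 1:19, effect = 0,
                              sd = 10, seed = 1L) {
  set.seed(seed)
  recs <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                      hemisphere = c("left", "right"),
                      subregion = subregions,
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(recs, compartment = "matrix",
               percent = 50 + effect / 2 + stats::rnorm(nrow(recs), sd = sd)),
    data.frame(recs, compartment = "striosome",
               percent = 50 - effect / 2 + stats::rnorm(nrow(recs), sd = sd)))
}
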