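test_that("striosome fraction constraint holds globally and per nucleus", {
  ph <- make_striatum(seed = 3)
  comp <- ph$compartment_labels$values
  nuc <- ph$nucleus_labels$values
  frac <- mean(comp[nuc > 0] == 1L)
  expect_gte(frac, 0.13)
  expect_lte(frac, 0.17)
  for (n in 1:2) {
    f_n <- mean(comp[nuc == n] == 1L)
    expect_gt(f_n, 0.10)  # both nuclei hold both compartments
    expect_lt(f_n, 0.20)
    expect_gt(sum(comp[nuc == n] == 2L), 0)
  }
  expect_error(make_striatum(striosome_fraction = 0.6), "infeasible")
})

test_that("striosome centroid is medial, rostral and ventral to matrix", {
  hits <- 0L
  for (s in 1:20) {
    ph <- make_striatum(seed = s)
    comp <- ph$compartment_labels$values
    grid <- ph$grid
    ctr <- function(lab) {
      lin <- which(comp == lab)
      ijk <- cbind((lin - 1L) %% grid$shape[1],
                   ((lin - 1L) %/% grid$shape[1]) %% grid$shape[2],
                   (lin - 1L) %/% (grid$shape[1] * grid$shape[2]))
      colMeans(voxel_to_world(grid, ijk))
    }
    d <- ctr(1L) - ctr(2L)
    if (d[1] < 0 && d[2] > 0 && d[3] < 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("zero gradients leave the compartments spatially unbiased", {
  deltas <- t(vapply(1:20, function(s) {
    ph <- make_striatum(gradient_strengths = c(0, 0, 0), seed = s)
    comp <- ph$compartment_labels$values
    grid <- ph$grid
    ctr <- function(lab) {
      lin <- which(comp == lab)
      ijk <- cbind((lin - 1L) %% grid$shape[1],
                   ((lin - 1L) %/% grid$shape[1]) %% grid$shape[2],
                   (lin - 1L) %/% (grid$shape[1] * grid$shape[2]))
      colMeans(voxel_to_world(grid, ijk))
    }
    ctr(1L) - ctr(2L)
  }, numeric(3)))
  # mean centroid separation under the null stays below one voxel (1.5 mm)
  expect_true(all(abs(colMeans(deltas)) < 1.5))
})

test_that("insular sheet partitions into ordered subregions with the reported bias mix", {
  ph <- make_phantom(seed = 2)
  bias <- ph$subregion_true_bias
  expect_length(bias, 19L)
  expect_equal(sum(bias > 0.55), 7L)
  expect_equal(sum(bias < 0.45), 9L)
  expect_equal(sum(bias >= 0.45 & bias <= 0.55), 3L)
  labs <- ph$insula_labels$values
  expect_setequal(unique(labs[labs > 0]), 1:19)

  # uniform profile: all neutral
  ph0 <- make_insula(make_striatum(seed = 2), 19, rep(0.5, 19))
  expect_true(all(ph0$subregion_true_bias == 0.5))

  # two subregions partition the sheet
  ph2 <- make_insula(make_striatum(seed = 2), 2)
  l2 <- ph2$insula_labels$values
  expect_setequal(unique(l2[l2 > 0]), 1:2)
  expect_equal(sum(l2 > 0), sum(ph$insula_labels$values > 0))

  expect_error(make_insula(make_striatum(seed = 2), 10000L), "subregions")
  expect_error(make_insula(make_striatum(seed = 2), 19, rep(1.5, 19)),
               "\\[0, 1\\]")
})

test_that("phantom generation and CTT simulation are seed-deterministic", {
  a <- make_phantom(seed = 7)
  b <- make_phantom(seed = 7)
  expect_identical(a$compartment_labels$values, b$compartment_labels$values)
  ca <- simulate_ctt(a, streamlines_per_seed = 500, seed = 9)
  cb <- simulate_ctt(b, streamlines_per_seed = 500, seed = 9)
  expect_identical(ca$counts, cb$counts)
  cc <- simulate_ctt(a, streamlines_per_seed = 500, seed = 10)
  expect_false(identical(ca$counts, cc$counts))
})

test_that("simulated CTT counts follow the concordance model", {
  ph <- make_striatum(seed = 4)
  baits <- default_bait_grouping()
  comp_of <- function(conn) {
    lin <- ijk_mat_to_lin(ph$grid, conn$seeds)
    ph$compartment_labels$values[lin]
  }

  # perfect fidelity, no heterogeneity: discordant counts are all zero
  conn1 <- simulate_ctt(ph, baits, 200L, fidelity = 1, voxel_kappa = Inf,
                        seed = 5)
  comp <- comp_of(conn1)
  m_cols <- baits$matrix_group
  s_cols <- baits$striosome_group
  expect_true(all(rowSums(conn1$counts[comp == 1L, m_cols]) == 0))
  expect_true(all(rowSums(conn1$counts[comp == 2L, s_cols]) == 0))
  # lapse 0: per-seed totals are exactly the seeded count
  expect_true(all(rowSums(conn1$counts) == 200L))

  # fidelity 0.8: mean concordant fraction approaches 0.8
  conn2 <- simulate_ctt(ph, baits, 5000L, fidelity = 0.8, seed = 6)
  comp <- comp_of(conn2)
  conc <- ifelse(comp == 1L,
                 rowSums(conn2$counts[, s_cols]) / rowSums(conn2$counts),
                 rowSums(conn2$counts[, m_cols]) / rowSums(conn2$counts))
  expect_lt(abs(mean(conc) - 0.8), 0.01)

  # fidelity 0.5: bias scores centre on 0.5
  conn3 <- simulate_ctt(ph, baits, 5000L, fidelity = 0.5, seed = 7)
  sc <- ctt_bias_score(conn3, baits)
  expect_lt(abs(mean(sc$p_strio$values, na.rm = TRUE) - 0.5), 0.01)

  # lapse: totals fall short by the lapse fraction in expectation
  conn4 <- simulate_ctt(ph, baits, 5000L, lapse = 0.1, seed = 8)
  expect_lt(abs(mean(rowSums(conn4$counts)) / 5000 - 0.9), 0.01)

  expect_error(simulate_ctt(ph, baits, 0L), "positive")
  expect_error(simulate_ctt(ph, baits, fidelity = 0.3), "fidelity")
})

test_that("insulo-striate simulation recovers subregion biases against pure masks", {
  ph <- make_phantom(seed = 5)
  masks <- truth_masks(ph, 60L)
  sim <- simulate_insulo_striate(ph, masks, streamlines_per_seed = 5000L,
                                 voxel_kappa = Inf, seed = 6)
  lin <- ijk_mat_to_lin(ph$grid, sim$counts$seeds)
  sub <- ph$insula_labels$values[lin]
  frac <- sim$counts$counts[, "striosome_like"] / rowSums(sim$counts$counts)
  per_sub <- tapply(frac, sub, mean)
  expect_true(all(abs(per_sub - ph$subregion_true_bias) < 0.02))

  # all-striosome profile: no matrix-favoring counts (pure masks)
  ph1 <- make_insula(make_striatum(seed = 5), 19, rep(1, 19))
  sim1 <- simulate_insulo_striate(ph1, truth_masks(ph1, 60L), 500L, seed = 7)
  expect_true(all(sim1$counts$counts[, "matrix_like"] == 0))

  expect_error(simulate_insulo_striate(
    ph, striatparc:::new_compartment_masks(matrix(integer(), 0, 3),
                                           matrix(0L, 1, 3), list()),
    500L), "non-empty")
})

test_that("path densities lie exactly on rasterized seed-target segments", {
  ph <- make_phantom(seed = 8)
  # degenerate masks: one striosome voxel, one matrix voxel
  comp <- ph$compartment_labels$values
  grid <- ph$grid
  one_vox <- function(lab) {
    lin <- which(comp == lab)[1]
    cbind((lin - 1L) %% grid$shape[1],
          ((lin - 1L) %/% grid$shape[1]) %% grid$shape[2],
          (lin - 1L) %/% (grid$shape[1] * grid$shape[2]))
  }
  masks <- striatparc:::new_compartment_masks(one_vox(1L), one_vox(2L),
                                              list())
  sim <- simulate_insulo_striate(ph, masks, 50L, subregions = 1L,
                                 rasterize = TRUE, seed = 9)
  dens <- sim$density_striosome$values
  expect_gt(sum(dens > 0), 0)
  # every visited voxel lies within the bounding box spanned by the seeds
  # and the single striosome target (straight segments cannot leave it)
  vis <- which(dens > 0)
  ijk <- cbind((vis - 1L) %% grid$shape[1],
               ((vis - 1L) %/% grid$shape[1]) %% grid$shape[2],
               (vis - 1L) %/% (grid$shape[1] * grid$shape[2]))
  seeds <- sim$counts$seeds
  lo <- pmin(apply(seeds, 2, min), masks$striosome_like[1, ])
  hi <- pmax(apply(seeds, 2, max), masks$striosome_like[1, ])
  expect_true(all(t(ijk) >= lo & t(ijk) <= hi))
})

test_that("phantom exports volumes and a machine-readable truth record", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(seed = 12)
  export_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "compartments.nii.gz")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$striosome_fraction, 0.15)
  expect_equal(truth$rng_seed, 12)
  back <- read_label_volume(file.path(dir, "compartments.nii.gz"))
  expect_identical(back$values, ph$compartment_labels$values)
})
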