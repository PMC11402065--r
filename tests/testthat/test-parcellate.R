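baits2 <- bait_grouping("S", "M")

conn_from_counts <- function(grid, seeds, S, M, depth = 1000L) {
  connectivity_table(grid, seeds, cbind(S = S, M = M), depth)
}

test_that("bias scores follow the pooled-count ratio with NA for zero counts", {
  grid <- tiny_grid()
  seeds <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  conn <- conn_from_counts(grid, seeds, S = c(300, 5, 0), M = c(100, 5, 0))
  sc <- ctt_bias_score(conn, baits2)
  lin <- ijk_mat_to_lin(grid, seeds)
  expect_equal(sc$p_strio$values[lin], c(0.75, 0.5, NA))
  expect_equal(sc$n_classified, 2L)
  # complement identity at classified voxels
  ok <- !is.na(sc$p_strio$values)
  expect_lt(max(abs(sc$p_strio$values[ok] + sc$p_matrix$values[ok] - 1)),
            1e-12)

  conn0 <- conn_from_counts(grid, seeds, S = c(0, 0, 0), M = c(0, 0, 0))
  expect_error(ctt_bias_score(conn0, baits2), "unclassified")
})

test_that("pooling convention is configurable between sum and per-region mean", {
  grid <- tiny_grid()
  baits <- bait_grouping(c("S1", "S2"), "M1")
  conn <- connectivity_table(grid, rbind(c(0, 0, 0)),
                             cbind(S1 = 30, S2 = 10, M1 = 20), 100L)
  lin <- ijk_mat_to_lin(grid, rbind(c(0, 0, 0)))
  expect_equal(ctt_bias_score(conn, baits)$p_strio$values[lin], 40 / 60)
  expect_equal(ctt_bias_score(conn, baits, pooling = "mean")$p_strio$values[lin],
               20 / 40)
})

test_that("equal-volume selection takes the exact top fraction with deterministic ties", {
  grid <- volume_grid(c(10L, 10L, 10L))
  set.seed(42)
  n <- 1000L
  seeds <- as.matrix(expand.grid(i = 0:9, j = 0:9, k = 0:9))
  p <- runif(n)
  pair <- score_pair(grid, data.frame(seeds, p = p))
  masks <- select_equal_volume_masks(pair$p_strio, pair$p_matrix, 0.13)
  expect_equal(nrow(masks$striosome_like), 130L)
  expect_equal(nrow(masks$matrix_like), 130L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_length(intersect(key(masks$striosome_like),
                          key(masks$matrix_like)), 0L)

  # all-tied scores: still equal-size, disjoint, and reproducible
  pair_t <- score_pair(grid, data.frame(seeds, p = 0.5))
  m1 <- select_equal_volume_masks(pair_t$p_strio, pair_t$p_matrix, 0.13)
  m2 <- select_equal_volume_masks(pair_t$p_strio, pair_t$p_matrix, 0.13)
  expect_identical(m1$striosome_like, m2$striosome_like)
  expect_equal(nrow(m1$striosome_like), 130L)
  expect_length(intersect(key(m1$striosome_like), key(m1$matrix_like)), 0L)

  expect_error(select_equal_volume_masks(pair$p_strio, pair$p_matrix, 0.5),
               "fraction")
})

test_that("mask selection equals the exhaustive sort-and-take oracle", {
  grid <- volume_grid(c(8L, 8L, 8L))
  for (rep in 1:5) {
    set.seed(rep)
    n <- sample(50:500, 1)
    all_vox <- as.matrix(expand.grid(i = 0:7, j = 0:7, k = 0:7))
    seeds <- all_vox[sample(nrow(all_vox), n), , drop = FALSE]
    p <- round(runif(n), 2)  # coarse grid forces ties
    pair <- score_pair(grid, data.frame(i = seeds[, 1], j = seeds[, 2],
                                        k = seeds[, 3], p = p))
    frac <- 0.13
    masks <- select_equal_volume_masks(pair$p_strio, pair$p_matrix, frac)
    k <- round(frac * n)
    # oracle: explicit sort on (-score, i, j, k), take k
    ord <- order(-p, seeds[, 1], seeds[, 2], seeds[, 3])
    oracle <- seeds[ord[seq_len(k)], , drop = FALSE]
    oracle <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ,
                     drop = FALSE]
    expect_equal(unname(masks$striosome_like), unname(oracle))
  }
})

test_that("selection is invariant to the order of input rows", {
  grid <- tiny_grid(c(8L, 8L, 8L))
  set.seed(9)
  all_vox <- as.matrix(expand.grid(i = 0:7, j = 0:7, k = 0:7))
  seeds <- all_vox[sample(nrow(all_vox), 200), ]
  counts <- cbind(S = rpois(200, 50), M = rpois(200, 50))
  ct1 <- connectivity_table(grid, seeds, counts, 1000L)
  shuf <- sample(200)
  ct2 <- connectivity_table(grid, seeds[shuf, ], counts[shuf, ], 1000L)
  m1 <- with(ctt_bias_score(ct1, baits2),
             select_equal_volume_masks(p_strio, p_matrix))
  m2 <- with(ctt_bias_score(ct2, baits2),
             select_equal_volume_masks(p_strio, p_matrix))
  expect_identical(m1$striosome_like, m2$striosome_like)
  expect_identical(m1$matrix_like, m2$matrix_like)
})

test_that("N-1 parcellation drops the left-out region's contribution only", {
  fx <- phantom_round1()
  baits <- default_bait_grouping()
  # a region with all-zero counts changes nothing
  conn <- fx$conn
  conn$counts[, "primary_motor"] <- 0
  full <- with(ctt_bias_score(conn, baits),
               select_equal_volume_masks(p_strio, p_matrix))
  n1 <- n1_parcellation(conn, baits, "primary_motor")
  expect_identical(full$striosome_like, n1$striosome_like)
  expect_identical(full$matrix_like, n1$matrix_like)
  expect_equal(n1$source$left_out, "primary_motor")

  expect_error(n1_parcellation(fx$conn, baits, "cerebellum"), "not found")
  soloist <- bait_grouping("only_strio", c("m1", "m2"))
  conn_s <- connectivity_table(fx$truth$grid, rbind(c(0, 0, 0)),
                               cbind(only_strio = 5, m1 = 3, m2 = 2), 100L)
  expect_error(n1_parcellation(conn_s, soloist, "only_strio"), "empty")
})

test_that("N-1 parcellation keeps mask purity close to the full parcellation", {
  fx <- phantom_round1()
  full_purity <- mask_purity(fx$masks, fx$truth)
  n1 <- n1_parcellation(fx$conn, default_bait_grouping(),
                        "posterior_orbitofrontal")
  n1_purity <- mask_purity(n1, fx$truth)
  expect_true(all(full_purity - n1_purity < 0.10))
})

test_that("proportional masks honour per-nucleus quotas", {
  fx <- phantom_round1()
  pm <- proportional_masks(fx$scores$p_strio, fx$scores$p_matrix,
                           fx$truth$nucleus_labels,
                           c(caudate = 80L, putamen = 100L))
  expect_equal(nrow(pm$striosome_like), 180L)
  expect_equal(nrow(pm$matrix_like), 180L)
  nuc <- fx$truth$nucleus_labels$values
  in_caud <- nuc[ijk_mat_to_lin(fx$truth$grid, pm$striosome_like)] == 1L
  expect_equal(sum(in_caud), 80L)

  # zero quota: nucleus contributes nothing
  pm0 <- proportional_masks(fx$scores$p_strio, fx$scores$p_matrix,
                            fx$truth$nucleus_labels,
                            c(caudate = 0L, putamen = 50L))
  expect_equal(nrow(pm0$striosome_like), 50L)
  expect_false(any(nuc[ijk_mat_to_lin(fx$truth$grid,
                                      pm0$striosome_like)] == 1L))

  expect_error(proportional_masks(fx$scores$p_strio, fx$scores$p_matrix,
                                  fx$truth$nucleus_labels,
                                  c(caudate = 10000L, putamen = 1L)),
               "caudate")
})

test_that("fraction-based masks chase scores into one nucleus where proportional masks cannot", {
  # constructed field: caudate scores uniformly exceed putamen's
  fx <- phantom_round1()
  grid <- fx$truth$grid
  nuc <- fx$truth$nucleus_labels$values
  lin <- which(nuc > 0)
  ijk <- cbind((lin - 1L) %% grid$shape[1],
               ((lin - 1L) %/% grid$shape[1]) %% grid$shape[2],
               (lin - 1L) %/% (grid$shape[1] * grid$shape[2]))
  set.seed(4)
  p <- ifelse(nuc[lin] == 1L, runif(length(lin), 0.6, 0.9),
              runif(length(lin), 0.1, 0.4))
  pair <- score_pair(grid, data.frame(i = ijk[, 1], j = ijk[, 2],
                                      k = ijk[, 3], p = p))
  frac_masks <- select_equal_volume_masks(pair$p_strio, pair$p_matrix, 0.13)
  prop_masks <- proportional_masks(pair$p_strio, pair$p_matrix,
                                   fx$truth$nucleus_labels,
                                   c(caudate = 80L, putamen = 100L))
  caud_frac <- mean(nuc[ijk_mat_to_lin(grid, frac_masks$striosome_like)] == 1L)
  expect_equal(caud_frac, 1)  # fraction masks all pile into the caudate
  caud_prop <- sum(nuc[ijk_mat_to_lin(grid, prop_masks$striosome_like)] == 1L)
  expect_equal(caud_prop, 80L)
})

test_that("mask recovery from a fidelity-0.8 phantom is highly pure", {
  purities <- t(vapply(1:3, function(s) {
    ph <- make_phantom(seed = 100 + s)
    conn <- simulate_ctt(ph, streamlines_per_seed = 5000L, fidelity = 0.8,
                         seed = 200 + s)
    sc <- ctt_bias_score(conn, default_bait_grouping())
    mask_purity(select_equal_volume_masks(sc$p_strio, sc$p_matrix), ph)
  }, numeric(2)))
  expect_gte(mean(purities[, "striosome"]), 0.85)
  expect_gte(mean(purities[, "matrix"]), 0.85)
})
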