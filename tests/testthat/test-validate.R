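test_that("abundance fractions are forced by suprathreshold counts and sum to 100", {
  grid <- tiny_grid()
  # 40 voxels at p = 0.9 (striosome-suprathreshold), 60 at p = 0.1
  vox <- as.matrix(expand.grid(i = 0:4, j = 0:4, k = 0:3))
  p <- c(rep(0.9, 40), rep(0.1, 60))
  pair <- score_pair(grid, data.frame(vox, p = p))
  ab <- abundance_fraction(pair$p_strio, pair$p_matrix, 0.87)
  expect_equal(unname(ab), c(40, 60))
  expect_equal(sum(ab), 100)

  # threshold 1 with no perfect voxels: undefined
  expect_error(abundance_fraction(pair$p_strio, pair$p_matrix, 1),
               "suprathreshold")
  expect_error(abundance_fraction(pair$p_strio, pair$p_matrix, 0.4),
               "threshold")
})

test_that("location records measure world-mm offsets from the nucleus centroid", {
  grid <- tiny_grid(c(8L, 8L, 8L))
  labs <- array(0L, grid$shape)
  labs[2, 2, 2] <- 1L                      # single-voxel caudate
  labs[5, 3, 3] <- 2L; labs[7, 3, 3] <- 2L # two-voxel putamen
  nl <- label_volume(grid, labs, c(`1` = "caudate", `2` = "putamen"))
  masks <- striatparc:::new_compartment_masks(
    rbind(c(1L, 1L, 1L)), rbind(c(4L, 2L, 2L), c(6L, 2L, 2L)), list())
  rec <- location_records(masks, nl)
  expect_equal(nrow(rec), 3L)  # one record per mask voxel
  expect_equal(unlist(rec[rec$compartment == "striosome",
                          c("dx", "dy", "dz")]),
               c(dx = 0, dy = 0, dz = 0))  # centroid identity
  put <- rec[rec$compartment == "matrix", ]
  expect_equal(sum(put$dx), 0)             # symmetric pair cancels
  expect_equal(abs(put$dx), c(1.5, 1.5))

  bad <- striatparc:::new_compartment_masks(rbind(c(0L, 0L, 0L)),
                                            rbind(c(4L, 2L, 2L)), list())
  expect_error(location_records(bad, nl), "outside")
})

simulate_offsets <- function(n_per_cell, delta_comp = 0, delta_nuc = 0,
                             interaction = 0, sd = 1, n_subjects = 4,
                             seed = 1) {
  set.seed(seed)
  cells <- expand.grid(compartment = c("striosome", "matrix"),
                       nucleus = c("caudate", "putamen"),
                       stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    mu <- delta_comp * (cells$compartment[i] == "striosome") +
      delta_nuc * (cells$nucleus[i] == "putamen") +
      interaction * (cells$compartment[i] == "striosome") *
        (cells$nucleus[i] == "putamen")
    data.frame(subject = sample(sprintf("s%d", 1:n_subjects), n_per_cell,
                                replace = TRUE),
               hemisphere = "right",
               compartment = cells$compartment[i],
               nucleus = cells$nucleus[i],
               dx = rnorm(n_per_cell, mu, sd),
               dy = rnorm(n_per_cell, 0, sd),
               dz = rnorm(n_per_cell, 0, sd),
               stringsAsFactors = FALSE)
  }))
  recs
}

test_that("two-factor ANOVA detects a planted compartment effect and nothing else", {
  recs <- simulate_offsets(400, delta_comp = 2, sd = 1, seed = 2)
  out <- location_anova(recs)
  tab <- out$anova
  comp_x <- tab[tab$axis == "dx" & tab$factor == "compartment", ]
  nuc_x <- tab[tab$axis == "dx" & tab$factor == "nucleus", ]
  expect_lt(comp_x$p, 1e-6)
  expect_gt(nuc_x$p, 0.001)
  comp_y <- tab[tab$axis == "dy" & tab$factor == "compartment", ]
  expect_gt(comp_y$p, 0.001)
})

test_that("balanced two-cell ANOVA reduces to the squared two-sample t", {
  set.seed(3)
  recs <- data.frame(subject = "s1", hemisphere = "right",
                     compartment = rep(c("striosome", "matrix"), each = 40),
                     nucleus = rep(c("caudate", "putamen"), 40),
                     dx = rnorm(80), dy = rnorm(80), dz = rnorm(80))
  # reduce to one factor by fitting compartment only, balanced design
  fit <- lm(dx ~ compartment, data = recs)
  F_lm <- anova(fit)["compartment", "F value"]
  t2 <- t.test(dx ~ compartment, data = recs, var.equal = TRUE)$statistic^2
  expect_lt(abs(F_lm - t2), 1e-9)
})

test_that("ANOVA tables match hand-computed least squares on balanced designs", {
  for (seed in 1:3) {
    recs <- simulate_offsets(50, delta_comp = 1, delta_nuc = 0.5,
                             interaction = 0.8, n_subjects = 1, seed = seed)
    recs$subject <- "s1"
    out <- location_anova(recs)$anova
    # balanced design: Type II sums of squares equal classical sequential SS
    y <- recs$dx
    A <- factor(recs$compartment); B <- factor(recs$nucleus)
    n <- length(y) / 4
    mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
    mAB <- tapply(y, list(A, B), mean); gm <- mean(y)
    ss_a <- 2 * n * sum((mA - gm)^2)
    ss_b <- 2 * n * sum((mB - gm)^2)
    ss_ab <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
    ss_e <- sum((y - mAB[cbind(A, B)])^2)
    df_e <- length(y) - 4
    expect_lt(abs(out[out$axis == "dx" & out$factor == "compartment", "F"] -
                    ss_a / (ss_e / df_e)), 1e-9)
    expect_lt(abs(out[out$axis == "dx" & out$factor == "nucleus", "F"] -
                    ss_b / (ss_e / df_e)), 1e-9)
    expect_lt(abs(out[out$axis == "dx" &
                        out$factor == "compartment:nucleus", "F"] -
                    ss_ab / (ss_e / df_e)), 1e-9)
  }
})

test_that("ANOVA p-values are calibrated under the null", {
  pvals <- vapply(1:200, function(s) {
    recs <- simulate_offsets(8, seed = 1000 + s, n_subjects = 1)
    recs$subject <- "s1"
    out <- location_anova(recs)$anova
    out[out$axis == "dx" & out$factor == "compartment", "p"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("simple main effects are produced when the interaction is significant", {
  recs <- simulate_offsets(200, delta_comp = 1, interaction = 2, seed = 5)
  out <- location_anova(recs)
  expect_false(is.null(out$simple_main_effects))
  sme <- out$simple_main_effects
  expect_true(all(c("F", "df1", "df2", "p", "F_crit_conservative") %in%
                    names(sme)))
  expect_true(all(sme$F >= 0))

  expect_error(location_anova(recs[recs$compartment == "matrix", ]),
               "fewer than 2 levels")
})

test_that("left-out-region bias reports the percentage of biased voxels per compartment", {
  grid <- tiny_grid()
  seeds <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  conn <- connectivity_table(
    grid, seeds,
    cbind(striosome_like = c(0, 0, 40), matrix_like = c(100, 100, 60)), 200L)
  out <- leftout_region_bias(conn, 0.87)
  expect_equal(unname(out), c(0, 100))  # voxel 3 (p=0.4) is not biased

  conn2 <- connectivity_table(grid, seeds[1, , drop = FALSE],
                              cbind(striosome_like = 60, matrix_like = 40),
                              200L)
  expect_error(leftout_region_bias(conn2, 0.87), "no biased voxels")
  conn3 <- connectivity_table(grid, seeds[1, , drop = FALSE],
                              cbind(a = 1, b = 1), 10L)
  expect_error(leftout_region_bias(conn3), "compartment masks")
})

test_that("a motor-like region is overwhelmingly matrix-favoring in recovery", {
  fx <- phantom_round1()
  n1 <- n1_parcellation(fx$conn, default_bait_grouping(), "primary_motor")
  pct <- vapply(1:3, function(s) {
    conn <- simulate_cortical_ctt(fx$truth, n1, true_striosome_bias = 0.05,
                                  n_voxels = 100L, seed = 300 + s)
    leftout_region_bias(conn, 0.87)["matrix"]
  }, numeric(1))
  expect_gte(mean(pct), 90)
})
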