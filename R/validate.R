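#' Relative abundance of highly biased compartment voxels
#'
#' Counts voxels whose compartment probability meets the high-bias
#' threshold (default P >= .87) and expresses each compartment as a
#' percentage of all suprathreshold volume. The two percentages sum to 100
#' exactly.
#'
#' @param p_strio,p_matrix complementary score volumes.
#' @param threshold high-bias probability bound, in (0.5, 1].
#' @return Named vector `c(striosome = , matrix = )` of percentages.
#' @export
abundance_fraction <- function(p_strio, p_matrix, threshold = 0.87) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  cs <- classified_scores(p_strio, p_matrix)
  n_s <- sum(cs$strio >= threshold)
  n_m <- sum(cs$matrix >= threshold)
  if (n_s + n_m == 0)
    stop("no suprathreshold voxels in either compartment")
  c(striosome = 100 * n_s / (n_s + n_m), matrix = 100 * n_m / (n_s + n_m))
}

#' Centroid-relative locations of parcellated voxels
#'
#' For every mask voxel, the world-mm offset of its centre from the
#' unweighted centroid of the whole nucleus (caudate or putamen) it resides
#' in. One record per mask voxel.
#'
#' @param masks a `compartment_masks`.
#' @param nucleus_labels a [label_volume()] with nuclei `caudate`, `putamen`.
#' @param subject,hemisphere identifiers attached to each record.
#' @return Data frame with columns `subject`, `hemisphere`, `compartment`,
#'   `nucleus`, `dx`, `dy`, `dz`.
#' @export
location_records <- function(masks, nucleus_labels,
                             subject = "s1", hemisphere = "right") {
  grid <- nucleus_labels$grid
  nuc_names <- nucleus_labels$legend
  centroids <- lapply(names(nuc_names), function(lb) {
    vox <- voxels_where(grid, nucleus_labels$values == as.integer(lb))
    colMeans(voxel_to_world(grid, vox))
  })
  names(centroids) <- nuc_names

  recs <- lapply(c("striosome_like", "matrix_like"), function(cmp) {
    vox <- masks[[cmp]]
    if (!nrow(vox)) return(NULL)
    lab <- nucleus_labels$values[ijk_to_linear(grid, vox)]
    if (any(lab == 0L))
      stop("mask voxel lies outside both nuclei")
    w <- voxel_to_world(grid, vox)
    nuc <- unname(nuc_names[as.character(lab)])
    off <- w - do.call(rbind, centroids[nuc])
    data.frame(subject = subject, hemisphere = hemisphere,
               compartment = sub("_like", "", cmp), nucleus = nuc,
               dx = off[, 1], dy = off[, 2], dz = off[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

## simple-main-effects F tests of one factor within levels of the other,
## using the pooled error term of the full model; the conservative
## simultaneous test procedure sets F-critical Scheffe-style over the
## family of cell-mean contrasts
simple_main_effects <- function(data, response, alpha = 0.05) {
  fit_full <- stats::lm(stats::reformulate("compartment * nucleus", response),
                        data = data)
  mse <- sum(stats::residuals(fit_full)^2) / fit_full$df.residual
  k <- length(unique(data$compartment)) * length(unique(data$nucleus))
  f_crit <- (k - 1) * stats::qf(1 - alpha, k - 1, fit_full$df.residual)
  out <- NULL
  specs <- list(c(effect = "nucleus", within = "compartment"),
                c(effect = "compartment", within = "nucleus"))
  for (sp in specs) {
    for (lev in unique(data[[sp[["within"]]]])) {
      d <- data[data[[sp[["within"]]]] == lev, ]
      means <- tapply(d[[response]], d[[sp[["effect"]]]], mean)
      ns <- tapply(d[[response]], d[[sp[["effect"]]]], length)
      gm <- sum(means * ns) / sum(ns)
      ss <- sum(ns * (means - gm)^2)
      df1 <- length(means) - 1L
      f <- (ss / df1) / mse
      out <- rbind(out, data.frame(
        effect = sp[["effect"]], within = sp[["within"]], level = lev,
        F = f, df1 = df1, df2 = fit_full$df.residual,
        p = stats::pf(f, df1, fit_full$df.residual, lower.tail = FALSE),
        F_crit_conservative = f_crit,
        significant = f > f_crit, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Two-factor ANOVA of intra-striate voxel location
#'
#' Per axis (dx, dy, dz): Type-II F tests of compartment, nucleus and
#' their interaction, with subject as a fixed nuisance factor when more
#' than one subject is present. When the interaction reaches `alpha`,
#' simple main effects are computed against a conservative simultaneous
#' F-critical (Scheffe-style over the cell means).
#'
#' @param records data frame from [location_records()] (possibly pooled
#'   over subjects/hemispheres).
#' @param alpha significance level for the interaction gate.
#' @return List with `anova` (data frame: axis, factor, F, df1, df2, p)
#'   and `simple_main_effects` (data frame or `NULL`).
#' @export
location_anova <- function(records, alpha = 0.05) {
  for (f in c("compartment", "nucleus"))
    if (length(unique(records[[f]])) < 2L)
      stop("factor '", f, "' has fewer than 2 levels")
  records$compartment <- factor(records$compartment)
  records$nucleus <- factor(records$nucleus)
  use_subject <- length(unique(records$subject)) > 1L
  if (use_subject) records$subject <- factor(records$subject)
  rhs <- if (use_subject) "subject + compartment * nucleus" else
    "compartment * nucleus"
  tables <- NULL
  sme <- NULL
  for (axis in c("dx", "dy", "dz")) {
    fit <- stats::lm(stats::reformulate(rhs, axis), data = records)
    a2 <- car::Anova(fit, type = 2)
    keep <- c("compartment", "nucleus", "compartment:nucleus")
    rows <- a2[keep, , drop = FALSE]
    tables <- rbind(tables, data.frame(
      axis = axis, factor = keep, F = rows[["F value"]],
      df1 = rows$Df, df2 = fit$df.residual,
      p = rows[["Pr(>F)"]], stringsAsFactors = FALSE))
    if (rows["compartment:nucleus", "Pr(>F)"] < alpha) {
      s <- simple_main_effects(records, axis, alpha)
      s$axis <- axis
      sme <- rbind(sme, s)
    }
  }
  rownames(tables) <- NULL
  list(anova = tables, simple_main_effects = sme)
}

#' Compartment bias of a left-out region's connectivity
#'
#' Scores each seed voxel of a region-to-masks connectivity table as in
#' [ctt_bias_score()] (the target groups are the two N-1 compartment
#' masks), calls voxels whose larger probability meets `threshold`
#' "biased", and reports the percentage of biased voxels favoring each
#' compartment.
#'
#' @param region_conn a [connectivity_table()] with target groups
#'   `striosome_like` and `matrix_like`.
#' @param threshold high-bias probability bound (default 0.87).
#' @return Named vector `c(striosome = , matrix = )`: percentages of biased
#'   voxels favoring each compartment (summing to 100).
#' @export
leftout_region_bias <- function(region_conn, threshold = 0.87) {
  need <- c("striosome_like", "matrix_like")
  if (!all(need %in% region_conn$target_groups))
    stop("region connectivity must target exactly the two compartment masks")
  S <- region_conn$counts[, "striosome_like"]
  M <- region_conn$counts[, "matrix_like"]
  tot <- S + M
  ok <- tot > 0
  p_s <- S[ok] / tot[ok]
  biased_s <- sum(p_s >= threshold)
  biased_m <- sum(1 - p_s >= threshold)
  if (biased_s + biased_m == 0) stop("no biased voxels at threshold ", threshold)
  c(striosome = 100 * biased_s / (biased_s + biased_m),
    matrix = 100 * biased_m / (biased_s + biased_m))
}
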