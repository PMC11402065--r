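verdict_of <- function(p, family_alpha, trending_multiplier = 10) {
  ifelse(is.na(p), "ns",
         ifelse(p < family_alpha, "significant",
                ifelse(p < trending_multiplier * family_alpha, "trending",
                       "ns")))
}

#' Bonferroni-family paired t test
#'
#' Two-tailed paired-samples t with the verdict taken at
#' `alpha = 0.05 / family_size` and the 10x "trending" rule.
#'
#' @param values_a,values_b paired numeric vectors (length >= 3).
#' @param family_size number of tests in the Bonferroni family.
#' @param trending_multiplier trending threshold multiplier.
#' @return List with `t`, `df`, `p`, `family_alpha`, `verdict`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
paired_t_family <- function(values_a, values_b, family_size = 1L,
                            trending_multiplier = 10) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  if (length(values_a) < 3L) stop("paired t requires n >= 3")
  d <- values_a - values_b
  fam_alpha <- 0.05 / family_size
  if (stats::sd(d) == 0) {
    ## all differences identical: t undefined for nonzero shift, 0 otherwise
    t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
    return(list(t = t_stat, df = length(d) - 1L, p = p,
                family_alpha = fam_alpha,
                verdict = verdict_of(p, fam_alpha, trending_multiplier),
                degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, family_alpha = fam_alpha,
       verdict = verdict_of(tt$p.value, fam_alpha, trending_multiplier),
       degenerate = FALSE)
}

#' Per-subregion ANCOVA of volume-percent bias
#'
#' One model per subregion on the long-format volume-percent records (two
#' rows per subject/hemisphere, one per compartment). With a covariate
#' table: `percent ~ compartment + hemisphere + handedness + sex + race +
#' age + sex:hemisphere:compartment` (subject is omitted - it would alias
#' the subject-constant covariates). Without covariates, the
#' repeated-measures reduction `percent ~ subject + compartment`, whose
#' compartment F equals the squared paired t. Verdicts use
#' `alpha = 0.05 / family_size` with the 10x trending rule.
#'
#' @param records data frame with columns `subject`, `hemisphere`,
#'   `subregion`, `compartment`, `percent`.
#' @param covariates optional data frame with `subject`, `sex`,
#'   `handedness`, `race`, `age`; missing covariate values are an error,
#'   not imputed.
#' @param family_size Bonferroni family size (default 19 subregions).
#' @param trending_multiplier trending threshold multiplier.
#' @return Data frame: `subregion`, `factor`, `F`, `df1`, `df2`, `p`,
#'   `verdict`.
#' @export
subregion_ancova <- function(records, covariates = NULL, family_size = 19L,
                             trending_multiplier = 10) {
  fam_alpha <- 0.05 / family_size
  if (!is.null(covariates)) {
    if (anyNA(covariates)) stop("missing covariate values are not imputed")
    records <- merge(records, covariates, by = "subject")
    rhs <- "compartment + hemisphere + handedness + sex + race + age"
  } else {
    rhs <- "subject + compartment"
  }
  for (f in intersect(c("compartment", "hemisphere", "sex", "race", "subject"),
                      all.vars(stats::as.formula(paste("~", rhs)))))
    records[[f]] <- factor(records[[f]])
  out <- NULL
  for (sr in sort(unique(records$subregion))) {
    d <- records[records$subregion == sr & !is.na(records$percent), ]
    ## drop factors/covariates that are constant in this subregion's data
    terms_rhs <- rhs
    if (!is.null(covariates)) {
      single <- vapply(c("hemisphere", "sex", "race"),
                       function(f) length(unique(d[[f]])) < 2L, logical(1))
      if (any(single))
        stop("factor(s) with a single level in subregion ", sr, ": ",
             paste(names(single)[single], collapse = ", "))
    }
    fit <- stats::lm(stats::reformulate(terms_rhs, "percent"), data = d)
    mm <- stats::model.matrix(fit)
    if (qr(mm)$rank < ncol(mm)) {
      aliased <- names(which(is.na(stats::coef(fit))))
      stop("rank-deficient design in subregion ", sr,
           "; aliased terms: ", paste(aliased, collapse = ", "))
    }
    a2 <- car::Anova(fit, type = 2)
    rows <- rownames(a2)
    rows <- rows[rows != "Residuals"]
    tab <- data.frame(
      subregion = sr, factor = rows, F = a2[rows, "F value"],
      df1 = a2[rows, "Df"], df2 = fit$df.residual,
      p = a2[rows, "Pr(>F)"],
      verdict = verdict_of(a2[rows, "Pr(>F)"], fam_alpha,
                           trending_multiplier),
      stringsAsFactors = FALSE)
    if (!is.null(covariates)) {
      ## combined sex-by-hemisphere-by-compartment interaction as a single
      ## block, tested against the main-effects model by model comparison
      ## (the block absorbs the nested two-way terms, hence its multi-df
      ## numerator)
      fit3 <- stats::lm(stats::reformulate(
        paste(terms_rhs, "+ sex:hemisphere:compartment"), "percent"),
        data = d)
      cmp3 <- stats::anova(fit, fit3)
      tab <- rbind(tab, data.frame(
        subregion = sr, factor = "sex:hemisphere:compartment",
        F = cmp3$F[2], df1 = cmp3$Df[2], df2 = fit3$df.residual,
        p = cmp3$`Pr(>F)`[2],
        verdict = verdict_of(cmp3$`Pr(>F)`[2], fam_alpha,
                             trending_multiplier),
        stringsAsFactors = FALSE))
    }
    out <- rbind(out, tab)
  }
  rownames(out) <- NULL
  attr(out, "family_alpha") <- fam_alpha
  out
}

## separable 3-D Gaussian smoothing (kernel truncated at 3 sigma);
## sigma_vox is per-axis in voxel units
gaussian_smooth_3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    ## pad by edge replication
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(d[1], half), , drop = FALSE])
    sm <- matrix(0, d[1], ncol(m))
    for (o in seq_along(kern))
      sm <- sm + kern[o] * padded[o:(o + d[1] - 1L), , drop = FALSE]
    arr <- aperm(array(sm, d), order(perm))
  }
  arr
}

#' Voxelwise sign-flip permutation test with max-statistic FWE control
#'
#' One-sample t statistics on per-subject paired difference volumes, with
#' familywise error control from the permutation distribution of the
#' maximum statistic under sign flipping. Two-sided inference is run as
#' two one-directional max-statistic tests at `alpha / 2` each, matching
#' per-direction significant masks. When `n_permutations` meets or exceeds
#' `2^n` subjects, all sign patterns are enumerated exactly (logged via a
#' message). Variance maps can be Gaussian-smoothed before forming t.
#' This is a max-statistic FWE procedure, not threshold-free cluster
#' enhancement.
#'
#' @param diff_maps list of per-subject difference volumes
#'   ([probability_volume()]s or plain 3-D arrays on one grid).
#' @param grid the shared [volume_grid()] (required when plain arrays are
#'   given).
#' @param n_permutations requested permutations (default 5000).
#' @param alpha familywise alpha for the two-direction family.
#' @param variance_smoothing_mm Gaussian sigma (mm) for variance
#'   smoothing; 0 disables.
#' @param mask optional [binary_volume()] restricting the analysis;
#'   default: voxels where any subject's difference is nonzero.
#' @param seed RNG seed for random sign draws (ignored when exhaustive).
#' @return List of class `permutation_result`: `statistic_map`,
#'   `fwe_p_pos`, `fwe_p_neg` (volumes), `sig_pos`, `sig_neg`
#'   (binary volumes at `alpha / 2` per direction), `analysis_mask`,
#'   `n_permutations` (actual), `alpha`, `exhaustive`.
#' @export
voxelwise_permutation_test <- function(diff_maps, grid = NULL,
                                       n_permutations = 5000L, alpha = 0.025,
                                       variance_smoothing_mm = 0,
                                       mask = NULL, seed = 1L) {
  vols <- lapply(diff_maps, function(m)
    if (inherits(m, "probability_volume")) m$values else m)
  if (is.null(grid)) {
    if (!inherits(diff_maps[[1]], "probability_volume"))
      stop("grid must be supplied when diff_maps are plain arrays")
    grid <- diff_maps[[1]]$grid
  }
  n <- length(vols)
  if (n < 8L) stop("permutation testing requires at least 8 subjects")
  D <- do.call(rbind, lapply(vols, as.vector))
  D[is.na(D)] <- 0
  keep <- if (is.null(mask)) colSums(D != 0) > 0 else as.vector(mask$values)
  empty_vol <- function(fill) probability_volume(grid, array(fill, grid$shape),
                                                 probability = FALSE)
  if (!any(keep)) {
    z <- binary_volume(grid, array(FALSE, grid$shape))
    return(structure(list(statistic_map = empty_vol(0),
                          fwe_p_pos = empty_vol(1), fwe_p_neg = empty_vol(1),
                          sig_pos = z, sig_neg = z, analysis_mask = z,
                          n_permutations = 0L, alpha = alpha,
                          exhaustive = TRUE), class = "permutation_result"))
  }
  Dk <- D[, keep, drop = FALSE]
  ss <- colSums(Dk^2)

  t_of_signs <- function(signs) {
    m <- as.vector(signs %*% Dk) / n
    v <- (ss - n * m^2) / (n - 1)
    if (variance_smoothing_mm > 0) {
      varr <- array(0, grid$shape)
      varr[keep] <- v
      varr <- gaussian_smooth_3d(varr, variance_smoothing_mm / grid$voxel_size)
      v <- varr[keep]
    }
    tt <- m / sqrt(v / n)
    tt[!is.finite(tt)] <- 0
    tt
  }

  exhaustive <- 2^n <= n_permutations
  if (exhaustive) {
    message(sprintf(
      "voxelwise_permutation_test: enumerating all %d sign patterns exactly",
      2^n))
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    actual <- nrow(signs_mat)
  } else {
    set.seed(seed)
    signs_mat <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                        nrow = n_permutations, ncol = n)
    actual <- n_permutations
  }
  t_obs <- t_of_signs(rep(1, n))
  max_pos <- numeric(actual)
  max_neg <- numeric(actual)
  for (b in seq_len(actual)) {
    tb <- t_of_signs(signs_mat[b, ])
    max_pos[b] <- max(tb)
    max_neg[b] <- max(-tb)
  }
  if (exhaustive) {
    fwe_pos <- vapply(t_obs, function(t0) mean(max_pos >= t0 - 1e-12),
                      numeric(1))
    fwe_neg <- vapply(-t_obs, function(t0) mean(max_neg >= t0 - 1e-12),
                      numeric(1))
  } else {
    fwe_pos <- vapply(t_obs, function(t0)
      (1 + sum(max_pos >= t0 - 1e-12)) / (actual + 1), numeric(1))
    fwe_neg <- vapply(-t_obs, function(t0)
      (1 + sum(max_neg >= t0 - 1e-12)) / (actual + 1), numeric(1))
  }

  fill_vol <- function(vals, fill) {
    arr <- array(fill, grid$shape)
    arr[keep] <- vals
    probability_volume(grid, arr, probability = FALSE, signed = TRUE)
  }
  mask_of <- function(sig) {
    arr <- array(FALSE, grid$shape)
    arr[keep] <- sig
    binary_volume(grid, arr)
  }
  structure(list(statistic_map = fill_vol(t_obs, 0),
                 fwe_p_pos = fill_vol(fwe_pos, 1),
                 fwe_p_neg = fill_vol(fwe_neg, 1),
                 sig_pos = mask_of(fwe_pos <= alpha / 2),
                 sig_neg = mask_of(fwe_neg <= alpha / 2),
                 analysis_mask = mask_of(rep(TRUE, sum(keep))),
                 n_permutations = actual, alpha = alpha,
                 exhaustive = exhaustive), class = "permutation_result")
}
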