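#' Define a shared voxel grid
#'
#' All volumes in an analysis live on one grid: a voxel lattice with an
#' affine mapping voxel indices to world coordinates. Voxel indices are
#' 0-based throughout the package; world axes follow the MNI convention
#' (+x right, +y anterior, +z superior).
#'
#' @param shape integer vector of length 3, voxel counts along i, j, k.
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @param origin world coordinate (mm) of the centre of voxel (0,0,0).
#'   Ignored when `affine` is given.
#' @param affine optional 4x4 voxel-to-world matrix; must be invertible.
#' @param space tag, `"phantom"` or `"standard"`.
#' @param hemisphere tag, `"left"`, `"right"` or `"bilateral"`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1.5, 1.5, 1.5),
                        origin = c(0, 0, 0), affine = NULL,
                        space = c("phantom", "standard"),
                        hemisphere = c("right", "left", "bilateral")) {
  space <- match.arg(space)
  hemisphere <- match.arg(hemisphere)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(shape < 1L)) stop("grid shape entries must be >= 1")
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine, space = space, hemisphere = hemisphere),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, voxel %.2gx%.2gx%.2g mm, %s space, %s hemisphere>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$space, x$hemisphere))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_compatible(a, b)) stop("volumes live on different grids")
  invisible(TRUE)
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param grid a [volume_grid()].
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm) of voxel centres.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  out <- cbind(ijk, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

## n x 3 0-based index matrix <-> R linear (1-based) array index
ijk_to_linear <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

linear_to_ijk <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% grid$shape[1]
  j <- (lin0 %/% grid$shape[1]) %% grid$shape[2]
  k <- lin0 %/% (grid$shape[1] * grid$shape[2])
  cbind(i = i, j = j, k = k)
}

in_grid <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  ijk[, 1] >= 0L & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0L & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0L & ijk[, 3] < grid$shape[3]
}

new_volume <- function(grid, values, class) {
  values <- array(values, dim = grid$shape)
  structure(list(grid = grid, values = values), class = class)
}

#' Integer label volume
#'
#' @param grid a [volume_grid()].
#' @param labels integer array matching the grid shape; 0 is background.
#' @param legend named character vector mapping label value to region name
#'   (names are the integer labels as strings). Labels absent from the
#'   legend are auto-named `region_<label>`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, labels, legend = NULL) {
  if (any(abs(labels - round(labels)) > 1e-8))
    stop("label volume requires integer-valued data")
  x <- new_volume(grid, as.integer(round(labels)), "label_volume")
  present <- sort(unique(x$values[x$values != 0L]))
  full <- if (length(present))
    stats::setNames(paste0("region_", present), as.character(present))
  else stats::setNames(character(0), character(0))
  if (!is.null(legend) && length(legend)) {
    legend <- stats::setNames(as.character(legend), names(legend))
    hit <- intersect(names(legend), names(full))
    full[hit] <- legend[hit]
  }
  x$legend <- full
  x
}

#' Per-voxel real-valued volume (probabilities or amplitudes)
#'
#' @param grid a [volume_grid()].
#' @param values numeric array matching the grid shape. `NA` marks voxels
#'   outside the analysis (e.g. unclassified seeds).
#' @param probability if `TRUE`, values must lie in \[0, 1\].
#' @param signed if `TRUE`, negative values are allowed (e.g. statistic
#'   maps); otherwise values must be non-negative.
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(grid, values, probability = TRUE,
                               signed = FALSE) {
  v <- as.numeric(values)
  if (!signed && any(v < 0, na.rm = TRUE))
    stop("volume values must be >= 0")
  if (probability && any(v > 1 + 1e-9, na.rm = TRUE))
    stop("probability values must be <= 1")
  x <- new_volume(grid, v, "probability_volume")
  x$probability <- isTRUE(probability)
  x
}

#' Binary voxel mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param values logical (or 0/1) array matching the grid shape.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(grid, values) {
  new_volume(grid, as.logical(values), "binary_volume")
}

#' Voxel index set of a binary volume
#' @param x a `binary_volume`.
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
mask_voxels <- function(x) {
  linear_to_ijk(x$grid, which(x$values))
}

grid_from_nifti <- function(img, space = "phantom", hemisphere = "right") {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  volume_grid(dim(img)[1:3], voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)),
              affine = aff, space = space, hemisphere = hemisphere)
}

nifti_from_grid <- function(grid, values) {
  img <- RNifti::asNifti(array(values, dim = grid$shape),
                         pixdim = grid$voxel_size)
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

legend_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.tsv", path)
}

#' Read an integer label volume from NIfTI
#'
#' A sidecar `<stem>.labels.tsv` with columns `label` and `name`, if
#' present, populates the legend; otherwise labels are auto-named.
#'
#' @param path path to a NIfTI-1 file with integer-valued data.
#' @inheritParams volume_grid
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, space = "phantom", hemisphere = "right") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, space, hemisphere)
  legend <- NULL
  side <- legend_sidecar_path(path)
  if (file.exists(side)) {
    tab <- utils::read.delim(side, stringsAsFactors = FALSE)
    legend <- stats::setNames(as.character(tab$name), as.character(tab$label))
  }
  label_volume(grid, img[], legend)
}

#' Write a label volume (and legend sidecar) to NIfTI
#' @param x a [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(x, path) {
  RNifti::writeNifti(nifti_from_grid(x$grid, x$values), path)
  if (length(x$legend))
    utils::write.table(data.frame(label = names(x$legend), name = x$legend),
                       legend_sidecar_path(path), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a real-valued volume from NIfTI
#' @inheritParams read_label_volume
#' @param probability whether values are probabilities (checked against \[0,1\]).
#' @return A [probability_volume()].
#' @export
read_probability_volume <- function(path, probability = TRUE,
                                    space = "phantom", hemisphere = "right") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  probability_volume(grid_from_nifti(img, space, hemisphere), img[],
                     probability = probability)
}

#' Write a real-valued volume to NIfTI
#' @param x a [probability_volume()] or [binary_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probability_volume <- function(x, path) {
  vals <- x$values
  if (is.logical(vals)) vals <- as.numeric(vals)
  vals[is.na(vals)] <- 0
  RNifti::writeNifti(nifti_from_grid(x$grid, vals), path)
  invisible(path)
}
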