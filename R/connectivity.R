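#' Seed-voxel by target-group streamline-count table
#'
#' The tabular abstraction of classification-targets tractography output:
#' for every seed voxel, the (possibly distance-corrected, hence real-valued)
#' number of streamlines that reached each named target group.
#'
#' @param grid the [volume_grid()] the seed voxels live on.
#' @param seeds n x 3 integer matrix of 0-based voxel indices, one row per seed.
#' @param counts n x G numeric matrix, one column per target group
#'   (column names are the group names); all entries >= 0.
#' @param streamlines_per_seed integer, streamlines seeded per voxel. Per-seed
#'   totals may fall short (streamlines can reach no target) but never exceed it.
#' @return An object of class `connectivity_table`.
#' @export
connectivity_table <- function(grid, seeds, counts, streamlines_per_seed) {
  seeds <- matrix(as.integer(seeds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "k")))
  counts <- as.matrix(counts)
  if (nrow(seeds) != nrow(counts))
    stop("seeds and counts disagree on the number of seed voxels")
  if (is.null(colnames(counts)) || anyNA(colnames(counts)))
    stop("counts must have target-group column names")
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (nrow(seeds) && any(!in_grid(grid, seeds)))
    stop("seed voxel index outside the grid")
  if (any(rowSums(counts) > streamlines_per_seed + 1e-6))
    stop("per-seed totals exceed streamlines_per_seed")
  structure(list(grid = grid, seeds = seeds, counts = counts,
                 target_groups = colnames(counts),
                 streamlines_per_seed = as.integer(streamlines_per_seed)),
            class = "connectivity_table")
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat(sprintf("<connectivity_table: %d seeds x %d target groups, %d streamlines/seed>\n",
              nrow(x$seeds), length(x$target_groups), x$streamlines_per_seed))
  invisible(x)
}

#' Read a connectivity table from TSV
#'
#' Expects columns `i`, `j`, `k` (0-based voxel indices) followed by one
#' column per target group. Seed order follows the file.
#'
#' @param path TSV file path.
#' @param grid the [volume_grid()] to validate indices against.
#' @param streamlines_per_seed streamlines seeded per voxel; if `NULL`, read
#'   from a `# streamlines_per_seed:` header comment, else inferred as the
#'   ceiling of the largest per-seed total.
#' @return A [connectivity_table()].
#' @export
read_connectivity_table <- function(path, grid, streamlines_per_seed = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 5L)
  if (is.null(streamlines_per_seed)) {
    m <- grep("^#\\s*streamlines_per_seed:", header, value = TRUE)
    if (length(m))
      streamlines_per_seed <- as.integer(sub(".*:\\s*", "", m[1]))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("i", "j", "k") %in% names(tab)))
    stop("connectivity TSV must have i, j, k index columns")
  groups <- setdiff(names(tab), c("i", "j", "k"))
  counts <- as.matrix(tab[, groups, drop = FALSE])
  if (is.null(streamlines_per_seed))
    streamlines_per_seed <- if (nrow(counts)) ceiling(max(rowSums(counts))) else 0L
  connectivity_table(grid, as.matrix(tab[, c("i", "j", "k")]), counts,
                     streamlines_per_seed)
}

#' Write a connectivity table to TSV
#' @param x a [connectivity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# streamlines_per_seed: %d", x$streamlines_per_seed), con)
  utils::write.table(cbind(as.data.frame(x$seeds), as.data.frame(x$counts)),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
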