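#' Axis-aligned analysis grid
#'
#' Defines the common 3-mm sampling grid on which all volumes, masks and
#' templates live. Coordinates are in mm with x running left-right,
#' y posterior-anterior and z ventral-dorsal; the grid stores the mm
#' position of the centre of the first voxel (`origin_mm`).
#'
#' @param xlim,ylim,zlim numeric length-2 extents in mm (voxel centres are
#'   placed at `xlim[1], xlim[1] + voxel_mm, ...` up to the largest value
#'   not exceeding `xlim[2]`).
#' @param voxel_mm isotropic voxel size in mm.
#' @return an object of class `vox_grid` with elements `dim`, `voxel_mm`
#'   and `origin_mm`.
#' @export
make_grid <- function(xlim = c(-60, 60), ylim = c(-90, 70), zlim = c(-40, 75),
                      voxel_mm = 3) {
  stopifnot(voxel_mm > 0, xlim[2] > xlim[1], ylim[2] > ylim[1], zlim[2] > zlim[1])
  dim <- c(
    floor((xlim[2] - xlim[1]) / voxel_mm) + 1L,
    floor((ylim[2] - ylim[1]) / voxel_mm) + 1L,
    floor((zlim[2] - zlim[1]) / voxel_mm) + 1L
  )
  structure(
    list(dim = as.integer(dim), voxel_mm = voxel_mm,
         origin_mm = c(xlim[1], ylim[1], zlim[1])),
    class = "vox_grid"
  )
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, %.3g mm isotropic\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm))
  hi <- x$origin_mm + (x$dim - 1) * x$voxel_mm
  cat(sprintf("  extent: x %g..%g  y %g..%g  z %g..%g mm\n",
              x$origin_mm[1], hi[1], x$origin_mm[2], hi[2], x$origin_mm[3], hi[3]))
  invisible(x)
}

#' Voxel centre coordinates along each axis
#' @param grid a `vox_grid`.
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  lapply(stats::setNames(1:3, c("x", "y", "z")), function(a)
    grid$origin_mm[a] + (seq_len(grid$dim[a]) - 1) * grid$voxel_mm)
}

#' Convert mm coordinates to the nearest voxel index
#' @param grid a `vox_grid`.
#' @param mm numeric length-3 vector or 3-column matrix of mm coordinates.
#' @return integer matrix of 1-based voxel indices (one row per point).
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- rbind(mm)
  idx <- round(sweep(mm, 2, grid$origin_mm) / grid$voxel_mm) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Convert voxel indices to mm coordinates of the voxel centre
#' @param grid a `vox_grid`.
#' @param idx integer length-3 vector or 3-column matrix of 1-based indices.
#' @export
voxel_to_mm <- function(grid, idx) {
  idx <- rbind(idx)
  sweep((idx - 1) * grid$voxel_mm, 2, grid$origin_mm, "+")
}

in_grid <- function(grid, mm) {
  hi <- grid$origin_mm + (grid$dim - 1) * grid$voxel_mm
  all(mm >= grid$origin_mm - grid$voxel_mm / 2) && all(mm <= hi + grid$voxel_mm / 2)
}

#' Ellipsoidal mask on a grid
#'
#' @param grid a `vox_grid`.
#' @param center ellipsoid centre, mm.
#' @param semi_axes length-3 semi-axes, mm.
#' @return logical 3-D array of the grid's dimensions.
#' @export
ellipsoid_mask <- function(grid, center, semi_axes) {
  stopifnot(all(semi_axes > 0))
  ax <- grid_axes(grid)
  u <- (ax$x - center[1]) / semi_axes[1]
  v <- (ax$y - center[2]) / semi_axes[2]
  w <- (ax$z - center[3]) / semi_axes[3]
  m <- outer(outer(u^2, v^2, "+"), w^2, "+") <= 1
  dim(m) <- grid$dim
  m
}

#' Default synthetic brain mask
#'
#' Ellipsoidal "brain" covering most of the default analysis grid; used as
#' the ICA analysis mask and for within-cohort cluster statistics.
#' @param grid a `vox_grid`, default [make_grid()].
#' @return logical 3-D array.
#' @export
default_brain_mask <- function(grid = make_grid()) {
  ellipsoid_mask(grid, center = c(0, -10, 17), semi_axes = c(60, 80, 57))
}

#' Reference whole-brain mask for the cluster-extent null simulation
#'
#' A ~59k-voxel 3-mm ellipsoidal mask approximating the in-mask volume of a
#' whole-brain analysis in standard space. Used when recomputing the
#' familywise minimum cluster extent, whose value depends on the mask size.
#' @return list with elements `grid` (a `vox_grid`) and `mask` (logical array).
#' @export
whole_brain_reference <- function() {
  dim <- c(49L, 62L, 46L)
  half <- (dim - 1) / 2 * 3
  grid <- make_grid(c(-half[1], half[1]), c(-half[2], half[2]),
                    c(-half[3], half[3]), voxel_mm = 3)
  mask <- ellipsoid_mask(grid, center = c(0, 0, 0), semi_axes = c(68, 88, 64))
  list(grid = grid, mask = mask)
}
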