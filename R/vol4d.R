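#' 4-D volume time series
#'
#' Container for a voxel time series on a `vox_grid`. Data are held as a
#' time x voxel matrix (voxels in array order), which is the natural
#' orientation for detrending, nuisance regression and spatial ICA;
#' [vol4d_array()] reshapes to x-y-z-t when needed.
#'
#' @param mat numeric time x voxel matrix.
#' @param grid a `vox_grid`.
#' @param tr_s repetition time in seconds.
#' @return object of class `vol4d`.
#' @export
vol4d <- function(mat, grid, tr_s) {
  stopifnot(is.matrix(mat), ncol(mat) == prod(grid$dim), tr_s > 0, nrow(mat) >= 1)
  if (!all(is.finite(mat))) stop("non-finite intensities")
  structure(list(mat = mat, grid = grid, tr_s = tr_s), class = "vol4d")
}

#' @export
print.vol4d <- function(x, ...) {
  cat(sprintf("<vol4d> %d volumes of %s voxels (%g mm), TR = %g s\n",
              nrow(x$mat), paste(x$grid$dim, collapse = "x"),
              x$grid$voxel_mm, x$tr_s))
  invisible(x)
}

#' Number of volumes in a `vol4d`
#' @param vol a `vol4d`.
#' @export
n_volumes <- function(vol) nrow(vol$mat)

#' Reshape a `vol4d` to an x-y-z-t array
#' @param vol a `vol4d`.
#' @export
vol4d_array <- function(vol) {
  a <- t(vol$mat)
  dim(a) <- c(vol$grid$dim, nrow(vol$mat))
  a
}

#' Write a `vol4d` or 3-D map to NIfTI-1
#'
#' @param x a `vol4d`, or a 3-D array paired with `grid`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param grid required when `x` is a bare array.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "vol4d")) {
    arr <- vol4d_array(x)
    grid <- x$grid
    pixdim <- c(rep(grid$voxel_mm, 3), x$tr_s)
  } else {
    arr <- x
    stopifnot(!is.null(grid))
    pixdim <- rep(grid$voxel_mm, 3)
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, pixdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a `vol4d` (or 3-D array)
#'
#' @param path NIfTI file.
#' @param grid a `vox_grid` describing the file's sampling; checked against
#'   the stored dimensions.
#' @param tr_s repetition time; taken from the file's pixdim when `NULL`.
#' @export
read_volume <- function(path, grid, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(all(d[1:3] == grid$dim))
  if (length(d) == 3) return(array(as.numeric(img), d))
  if (is.null(tr_s)) {
    pd <- attr(img, "pixdim")
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  m <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  vol4d(t(m), grid, tr_s)
}

mask_matrix <- function(vol, mask) {
  stopifnot(all(dim(mask) == vol$grid$dim))
  vol$mat[, as.vector(mask), drop = FALSE]
}

unmask_vector <- function(v, mask) {
  out <- array(0, dim(mask))
  out[mask] <- v
  out
}
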