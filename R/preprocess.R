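#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes of a run (T1 saturation), keeping
#' all metadata.
#' @param vol a `vol4d`.
#' @param n_discard number of leading volumes to drop (default 2).
#' @return a `vol4d` with `n_volumes(vol) - n_discard` volumes.
#' @export
discard_initial <- function(vol, n_discard = 2) {
  stopifnot(inherits(vol, "vol4d"), n_discard >= 0)
  if (n_volumes(vol) <= n_discard)
    stop("run has no volumes left after discarding ", n_discard)
  if (n_discard == 0) return(vol)
  vol4d(vol$mat[-seq_len(n_discard), , drop = FALSE], vol$grid, vol$tr_s)
}

#' Motion quality check
#'
#' Passes when no translation exceeds half a voxel and no rotation, taken
#' as worst-case surface displacement at `radius_mm` from the rotation
#' centre, exceeds half a voxel.
#'
#' @param params matrix/data frame with one row per volume: 3 translations
#'   (mm) then 3 rotations (degrees).
#' @param voxel_mm voxel size of the analysis grid.
#' @param radius_mm lever arm used to convert rotations to displacements.
#' @return list with `pass`, `max_excursion_mm` and the threshold used.
#' @export
motion_check <- function(params, voxel_mm = 3, radius_mm = 65) {
  params <- as.matrix(params)
  if (nrow(params) == 0 || ncol(params) != 6)
    stop("motion parameters must have 6 columns and at least one row")
  thr <- voxel_mm / 2
  trans <- abs(params[, 1:3, drop = FALSE])
  rot_disp <- abs(params[, 4:6, drop = FALSE]) * pi / 180 * radius_mm
  mx <- max(trans, rot_disp)
  list(pass = mx <= thr, max_excursion_mm = mx, threshold_mm = thr)
}

#' Voxel-wise linear detrending
#'
#' Removes each voxel's least-squares line over time and re-adds its
#' temporal mean, so stage output keeps the original means.
#' @param vol a `vol4d` with at least 3 volumes.
#' @return a detrended `vol4d`.
#' @export
detrend_voxelwise <- function(vol) {
  stopifnot(inherits(vol, "vol4d"))
  nt <- n_volumes(vol)
  if (nt < 3) stop("need at least 3 volumes to detrend")
  tt <- seq_len(nt) - (nt + 1) / 2            # centred time: slope removal
  slope <- crossprod(tt, vol$mat) / sum(tt^2) # leaves temporal means intact
  vol4d(vol$mat - outer(tt, drop(slope)), vol$grid, vol$tr_s)
}

#' Spatial Gaussian smoothing
#'
#' Convolves every volume with an isotropic Gaussian kernel of the given
#' FWHM (SD = FWHM / (2 sqrt(2 ln 2)) per axis), reflective borders.
#' @param vol a `vol4d`.
#' @param fwhm_mm kernel FWHM in mm; 0 returns the input unchanged.
#' @return a smoothed `vol4d`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 6) {
  stopifnot(inherits(vol, "vol4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vol$grid$voxel_mm
  sm <- .smooth4d_cpp(vol$mat, vol$grid$dim, sigma_vox, border = 0L)
  vol4d(sm, vol$grid, vol$tr_s)
}

#' FWHM to Gaussian SD
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a single 3-D map
#' @param map 3-D array.
#' @param sigma_vox kernel SD in voxels (scalar or length 3).
#' @param border `"reflect"` or `"zero"`.
#' @return smoothed array of the same dimensions.
#' @export
smooth_map <- function(map, sigma_vox, border = c("reflect", "zero")) {
  border <- match.arg(border)
  .smooth3d_cpp(as.numeric(map), as.integer(dim(map)), sigma_vox,
                border = if (border == "zero") 1L else 0L)
}

#' White-matter / CSF nuisance regression
#'
#' Builds two covariates as the mean time series within the WM and CSF
#' masks and replaces every voxel's series with the residual of its
#' regression on `[intercept, WM, CSF]` (residuals are exactly orthogonal
#' to the regressors). Near-collinear covariates (|r| > 0.999) raise a
#' warning and the CSF covariate is dropped.
#'
#' @param vol a `vol4d`.
#' @param wm_mask,csf_mask logical 3-D masks on the volume's grid.
#' @return list with `vol` (residual `vol4d`), `wm` and `csf` (the
#'   covariate series; `csf` is `NULL` when dropped).
#' @export
nuisance_regression <- function(vol, wm_mask, csf_mask) {
  stopifnot(inherits(vol, "vol4d"))
  if (!any(wm_mask)) stop("empty WM mask")
  if (!any(csf_mask)) stop("empty CSF mask")
  wm <- rowMeans(vol$mat[, as.vector(wm_mask), drop = FALSE])
  csf <- rowMeans(vol$mat[, as.vector(csf_mask), drop = FALSE])
  drop_csf <- stats::sd(wm) == 0 || stats::sd(csf) == 0 ||
    abs(stats::cor(wm, csf)) > 0.999
  X <- if (drop_csf) cbind(1, wm) else cbind(1, wm, csf)
  if (drop_csf) warning("WM and CSF covariates are collinear; CSF dropped")
  Q <- qr.Q(qr(X))
  resid <- vol$mat - Q %*% crossprod(Q, vol$mat)
  list(vol = vol4d(resid, vol$grid, vol$tr_s), wm = wm,
       csf = if (drop_csf) NULL else csf)
}

#' Standard per-subject preprocessing chain
#'
#' discard -> motion QC -> detrend -> smooth -> nuisance regression.
#'
#' @param vol a `vol4d`.
#' @param wm_mask,csf_mask nuisance masks.
#' @param motion optional 6-column motion table for the QC step.
#' @param n_discard leading volumes to drop.
#' @param fwhm_mm smoothing kernel FWHM, mm.
#' @param regress_nuisance logical; the WM/CSF regression can be switched
#'   off to defer nuisance handling to a later stage.
#' @return list with `vol`, `motion_qc`, `wm`, `csf`.
#' @export
preprocess_subject <- function(vol, wm_mask, csf_mask, motion = NULL,
                               n_discard = 2, fwhm_mm = 6,
                               regress_nuisance = TRUE) {
  v <- discard_initial(vol, n_discard)
  qc <- NULL
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    if (n_discard > 0 && nrow(m) > n_volumes(v)) m <- m[-seq_len(n_discard), , drop = FALSE]
    qc <- motion_check(m, vol$grid$voxel_mm)
    if (!qc$pass)
      warning(sprintf("motion exceeds half a voxel (%.2f mm > %.2f mm)",
                      qc$max_excursion_mm, qc$threshold_mm))
  }
  v <- detrend_voxelwise(v)
  v <- smooth_gaussian(v, fwhm_mm)
  wm <- csf <- NULL
  if (regress_nuisance) {
    nr <- nuisance_regression(v, wm_mask, csf_mask)
    v <- nr$vol; wm <- nr$wm; csf <- nr$csf
  }
  list(vol = v, motion_qc = qc, wm = wm, csf = csf)
}
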