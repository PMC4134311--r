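#' PCA whitening of a time x voxel matrix
#'
#' Spatial-ICA orientation: time points are the variables and in-mask
#' voxels the samples. Each voxel's temporal mean and each time point's
#' spatial mean are removed, the time-point covariance is
#' eigen-decomposed, and the leading `n_components` dimensions are
#' projected and scaled so the retained subspace has identity covariance
#' across voxels. If the data rank is below the request the retained
#' dimension is reduced with a warning.
#'
#' @param X numeric time x voxel matrix (voxels restricted to the
#'   analysis mask).
#' @param n_components requested dimension (default 30).
#' @return list of class `whitening`: `Z` (k x voxel whitened matrix),
#'   `K` (k x t projection), `dewhiten` (t x k back-projection),
#'   `eigenvalues`, `var_explained`, `n_components`.
#' @export
whiten <- function(X, n_components = 30) {
  stopifnot(is.matrix(X), n_components >= 1)
  nt <- nrow(X); V <- ncol(X)
  Xc <- X - matrix(colMeans(X), nt, V, byrow = TRUE)
  Xc <- Xc - rowMeans(Xc)
  C <- tcrossprod(Xc) / (V - 1)
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-9
  rank <- sum(e$values > tol)
  if (rank == 0) stop("degenerate (constant) data")
  k <- as.integer(min(n_components, rank, nt - 1))
  if (k < n_components)
    warning(sprintf("data rank %d < requested %d components; retaining %d",
                    rank, n_components, k))
  vals <- e$values[seq_len(k)]
  E <- e$vectors[, seq_len(k), drop = FALSE]
  K <- sweep(t(E), 1, sqrt(vals), "/")
  structure(list(Z = K %*% Xc, K = K,
                 dewhiten = sweep(E, 2, sqrt(vals), "*"),
                 eigenvalues = e$values,
                 var_explained = e$values[seq_len(k)] / sum(e$values),
                 n_components = k),
            class = "whitening")
}

fastica_one <- function(Z, W_prev, w0, tol, max_iter) {
  .fastica_one_cpp(Z, W_prev, w0, tol, as.integer(max_iter))
}

#' FastICA by deflation with tanh contrast
#'
#' Extracts components one at a time with the fixed-point update
#' `w <- E[z g(w'z)] - E[g'(w'z)] w` (g = tanh), Gram-Schmidt deflation
#' against previously extracted components and renormalisation at every
#' step; a component is declared converged when `|<w_new, w_old>| > 1 - tol`.
#' Non-converged components are restarted from fresh seeded directions up
#' to `restarts` times and flagged if still unconverged. Deterministic
#' given `seed`.
#'
#' @param wh a `whitening` object from [whiten()], or a whitened k x voxel
#'   matrix.
#' @param n_components number of components to extract (default: all
#'   whitened dimensions).
#' @param tol convergence tolerance on the direction cosine.
#' @param max_iter maximum fixed-point iterations per attempt.
#' @param restarts maximum re-initialisations of a non-converged component.
#' @param seed integer seed for the initial directions.
#' @return object of class `ic_decomposition`: `maps` (component x voxel,
#'   Z-scaled to zero mean / unit variance), `time_courses` (t x component
#'   mixing columns, present when `wh` carries a dewhitening matrix), `W`
#'   (unmixing in whitened space), `converged`, `iters`, `whitening`.
#' @export
fastica_deflation <- function(wh, n_components = NULL, tol = 1e-5,
                              max_iter = 1000, restarts = 5, seed = 1) {
  Z <- if (inherits(wh, "whitening")) wh$Z else wh
  k_max <- nrow(Z)
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  set.seed(seed)
  W <- matrix(0, k_max, 0)
  iters <- integer(k)
  conv <- logical(k)
  for (p in seq_len(k)) {
    res <- fastica_one(Z, W, stats::rnorm(k_max), tol, max_iter)
    tries <- 0
    while (!res$converged && tries < restarts) {
      tries <- tries + 1
      res2 <- fastica_one(Z, W, stats::rnorm(k_max), tol, max_iter)
      if (res2$converged) res <- res2
    }
    if (!res$converged)
      warning(sprintf("component %d did not converge in %d iterations", p, max_iter))
    W <- cbind(W, drop(res$w))
    iters[p] <- res$iters
    conv[p] <- res$converged
  }
  maps <- crossprod(W, Z)                       # sources over voxels
  maps <- zscale_maps(maps)
  tc <- if (inherits(wh, "whitening")) wh$dewhiten %*% W else NULL
  structure(list(maps = maps, time_courses = tc, W = W,
                 converged = conv, iters = iters,
                 whitening = if (inherits(wh, "whitening"))
                   wh[c("eigenvalues", "var_explained", "n_components")]
                 else NULL,
                 seed = seed),
            class = "ic_decomposition")
}

zscale_maps <- function(maps) {
  mu <- rowMeans(maps)
  s <- sqrt(rowMeans(maps^2) - mu^2)
  s[s == 0] <- 1
  (maps - mu) / s
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("<ic_decomposition> %d components over %d voxels\n",
              nrow(x$maps), ncol(x$maps)))
  cat(sprintf("  converged: %d/%d (median %g iterations)\n",
              sum(x$converged), length(x$converged), stats::median(x$iters)))
  invisible(x)
}

#' @export
summary.ic_decomposition <- function(object, ...) {
  data.frame(component = seq_len(nrow(object$maps)),
             converged = object$converged, iterations = object$iters,
             map_skewness = apply(object$maps, 1, function(m) mean(m^3)))
}

#' Resolve the ICA sign ambiguity
#'
#' Flips every component whose spatial map has negative skewness (and its
#' time course with it), so suprathreshold network structure is positive.
#' Maps with exactly zero skewness are left untouched. Idempotent.
#'
#' @param decomp an `ic_decomposition`.
#' @return the decomposition with aligned signs.
#' @export
orient_components <- function(decomp) {
  stopifnot(inherits(decomp, "ic_decomposition"))
  sk <- apply(decomp$maps, 1, function(m) mean(m^3))
  flip <- ifelse(sk < 0, -1, 1)
  decomp$maps <- decomp$maps * flip
  if (!is.null(decomp$time_courses))
    decomp$time_courses <- sweep(decomp$time_courses, 2, flip, "*")
  decomp$W <- sweep(decomp$W, 2, flip, "*")
  decomp
}

#' Per-subject spatial ICA of a preprocessed run
#'
#' Convenience wrapper: restrict to the analysis mask, whiten to
#' `n_components` dimensions, run deflation FastICA, orient components.
#'
#' @param vol a preprocessed `vol4d`.
#' @param mask logical analysis mask on the volume's grid.
#' @param n_components model order (default 30).
#' @param seed integer seed.
#' @param ... further arguments to [fastica_deflation()].
#' @return an `ic_decomposition` (with `mask` and `grid` attached).
#' @export
run_subject_ica <- function(vol, mask, n_components = 30, seed = 1, ...) {
  X <- mask_matrix(vol, mask)
  wh <- whiten(X, n_components)
  dec <- fastica_deflation(wh, seed = seed, ...)
  dec <- orient_components(dec)
  dec$mask <- mask
  dec$grid <- vol$grid
  dec
}

#' Persist a decomposition as NIfTI maps + TSV time courses + JSON sidecar
#'
#' Writes the Z-scaled spatial maps as one 4-D NIfTI stack (component as
#' the fourth dimension), the time courses as TSV, and a JSON sidecar
#' with seed, convergence record and retained-variance fractions.
#'
#' @param decomp an `ic_decomposition` carrying `mask` and `grid` (as
#'   returned by [run_subject_ica()]).
#' @param prefix output path prefix (files `<prefix>_maps.nii.gz`,
#'   `<prefix>_timecourses.tsv`, `<prefix>_ica.json`).
#' @export
write_decomposition <- function(decomp, prefix) {
  stopifnot(inherits(decomp, "ic_decomposition"),
            !is.null(decomp$mask), !is.null(decomp$grid))
  k <- nrow(decomp$maps)
  stack <- vapply(seq_len(k), function(i)
    unmask_vector(decomp$maps[i, ], decomp$mask), array(0, dim(decomp$mask)))
  write_volume(vol4d(t(matrix(stack, ncol = k)), decomp$grid, 1),
               paste0(prefix, "_maps.nii.gz"))
  if (!is.null(decomp$time_courses))
    utils::write.table(decomp$time_courses,
                       paste0(prefix, "_timecourses.tsv"), sep = "\t",
                       row.names = FALSE,
                       col.names = sprintf("IC%02d", seq_len(k)))
  jsonlite::write_json(
    list(seed = decomp$seed, converged = decomp$converged,
         iterations = decomp$iters,
         var_explained = decomp$whitening$var_explained),
    paste0(prefix, "_ica.json"), auto_unbox = TRUE, digits = 10)
  invisible(prefix)
}
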