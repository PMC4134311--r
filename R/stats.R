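#' Configuration of the voxel-wise group inference
#'
#' @param voxel_p voxel-level threshold probability (two-sided), default
#'   0.005.
#' @param alpha familywise error level for the cluster-extent correction.
#' @param sim_fwhm_vox FWHM (voxels) of the Gaussian kernel modelling the
#'   spatial correlation among voxels in the null simulation (default
#'   1.842).
#' @param n_iterations Monte Carlo iterations (default 5000).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param sim_seed integer seed of the null simulation.
#' @return object of class `stats_config`.
#' @export
stats_config <- function(voxel_p = 0.005, alpha = 0.05, sim_fwhm_vox = 1.842,
                         n_iterations = 5000, connectivity = 26,
                         sim_seed = 1234L) {
  stopifnot(voxel_p > 0, voxel_p < alpha, alpha < 1, n_iterations >= 100,
            connectivity %in% c(6, 18, 26))
  structure(list(voxel_p = voxel_p, alpha = alpha,
                 sim_fwhm_vox = sim_fwhm_vox,
                 n_iterations = as.integer(n_iterations),
                 connectivity = as.integer(connectivity),
                 sim_seed = as.integer(sim_seed)),
            class = "stats_config")
}

#' Voxel-wise one-way ANOVA between two groups of Z maps
#'
#' Per voxel, the one-way two-group ANOVA F with (1, n1 + n2 - 2) df,
#' together with the signed companion two-sample pooled t (group 1 minus
#' group 2), for which t^2 = F. Voxels with zero within-group variance
#' and equal means get statistic 0 and are flagged.
#'
#' @param z1,z2 subject x voxel matrices of Z values (group 1 = EDp,
#'   group 2 = HC in the cohort convention).
#' @return list of class `stat_map`: `t`, `F`, `df` (c(1, n-2)),
#'   `mean_diff`, `flagged` (voxels with degenerate variance).
#' @export
voxelwise_group_anova <- function(z1, z2) {
  n1 <- nrow(z1); n2 <- nrow(z2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  if (ncol(z1) != ncol(z2)) stop("voxel count mismatch")
  m1 <- colMeans(z1); m2 <- colMeans(z2)
  v1 <- colSums(z1^2) - n1 * m1^2
  v2 <- colSums(z2^2) - n2 * m2^2
  df2 <- n1 + n2 - 2
  sp2 <- (v1 + v2) / df2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  flagged <- se == 0
  tval <- ifelse(flagged, 0, (m1 - m2) / ifelse(se == 0, 1, se))
  structure(list(t = tval, F = tval^2, df = c(1, df2),
                 mean_diff = m1 - m2, flagged = flagged,
                 n = c(n1, n2)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, df = (%d, %d), |t| max = %.2f\n",
              length(x$t), x$df[1], x$df[2], max(abs(x$t))))
  invisible(x)
}

#' Monte Carlo minimum cluster extent
#'
#' Null simulation for the cluster-size familywise correction: at every
#' iteration the mask is filled with unit Gaussian noise, smoothed with a
#' Gaussian kernel of FWHM `sim_fwhm_vox` voxels, re-standardised within
#' the mask, thresholded two-sided at `voxel_p`, and the largest
#' suprathreshold cluster is recorded under the configured connectivity.
#' The returned minimum extent is the smallest k with
#' `P(max cluster >= k) <= alpha`. Deterministic given `cfg$sim_seed`.
#'
#' @param mask logical 3-D array (the functional volume).
#' @param cfg a [stats_config()].
#' @return object of class `mc_threshold`: `min_cluster`, `attained`
#'   (the tail probability at that extent), `n_mask`, `max_sizes`
#'   (per-iteration maxima), `cfg`.
#' @export
montecarlo_min_cluster <- function(mask, cfg = stats_config()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), any(mask))
  dim3 <- dim(mask)
  mvec <- as.vector(mask != 0)
  nm <- sum(mvec)
  sigma <- fwhm_to_sigma(cfg$sim_fwhm_vox)
  zthr <- stats::qnorm(1 - cfg$voxel_p / 2)
  set.seed(cfg$sim_seed)
  maxes <- integer(cfg$n_iterations)
  sup <- logical(length(mvec))
  for (i in seq_len(cfg$n_iterations)) {
    f <- numeric(length(mvec))
    f[mvec] <- stats::rnorm(nm)
    f <- .smooth3d_cpp(f, as.integer(dim3), sigma, border = 1L)
    v <- f[mvec]
    v <- (v - mean(v)) / stats::sd(v)
    sup[] <- FALSE
    sup[mvec] <- abs(v) > zthr
    maxes[i] <- .max_cluster_cpp(sup, as.integer(dim3), cfg$connectivity)
  }
  k <- 1L
  while (mean(maxes >= k) > cfg$alpha) k <- k + 1L
  structure(list(min_cluster = k, attained = mean(maxes >= k),
                 n_mask = nm, max_sizes = maxes, cfg = cfg),
            class = "mc_threshold")
}

#' @export
print.mc_threshold <- function(x, ...) {
  cat(sprintf(paste0("<mc_threshold> min cluster = %d voxels ",
                     "(attained tail %.4f, alpha %.3g)\n"),
              x$min_cluster, x$attained, x$cfg$alpha))
  cat(sprintf("  mask: %d voxels; %d iterations, FWHM %.3f vox, voxel p %.3g\n",
              x$n_mask, x$cfg$n_iterations, x$cfg$sim_fwhm_vox, x$cfg$voxel_p))
  invisible(x)
}

#' Threshold a statistic map and label suprathreshold clusters
#'
#' Two-sided voxel threshold from the t distribution, connected-component
#' labelling at the configured connectivity, removal of clusters smaller
#' than the minimum extent, and peak reporting in mm.
#'
#' @param statmap a `stat_map` from [voxelwise_group_anova()] (or a
#'   numeric vector of in-mask t values with `df` supplied).
#' @param grid the analysis `vox_grid`.
#' @param mask logical analysis mask.
#' @param voxel_p two-sided voxel threshold probability.
#' @param min_cluster minimum cluster extent in voxels (e.g. from
#'   [montecarlo_min_cluster()]).
#' @param connectivity 6, 18 or 26.
#' @param df error degrees of freedom (taken from `statmap` when absent).
#' @return data frame of class `cluster_table`: one row per surviving
#'   cluster with `label`, `size`, `peak_x/y/z` (mm), `peak_t`, `sign`.
#' @export
threshold_and_label <- function(statmap, grid, mask, voxel_p = 0.005,
                                min_cluster = 1, connectivity = 26,
                                df = NULL) {
  tvec <- if (inherits(statmap, "stat_map")) statmap$t else as.numeric(statmap)
  if (is.null(df)) {
    if (!inherits(statmap, "stat_map")) stop("df required")
    df <- statmap$df[2]
  }
  stopifnot(length(tvec) == sum(mask))
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  sup <- array(FALSE, dim(mask))
  tmap <- array(0, dim(mask))
  tmap[mask] <- tvec
  sup[mask] <- abs(tvec) > tcrit
  lab <- .label3d_cpp(sup, as.integer(dim(mask)), as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  rows <- list()
  if (ncomp > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    keep <- which(sizes >= min_cluster)
    for (ci in keep) {
      idx <- which(lab == ci)
      pk <- idx[which.max(abs(tmap[idx]))]
      pk3 <- arrayInd(pk, dim(mask))
      mm <- voxel_to_mm(grid, pk3)
      rows[[length(rows) + 1]] <- data.frame(
        label = ci, size = sizes[ci],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_t = tmap[pk], sign = sign(tmap[pk]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), size = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0), peak_t = numeric(0),
               sign = numeric(0))
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  attr(out, "tcrit") <- tcrit
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' ROI group comparison of network Z values
#'
#' Averages each subject's Z values within a cluster/ROI and compares the
#' groups with the classical pooled-variance two-tailed t test.
#'
#' @param z1,z2 subject x voxel matrices (in-mask values) for the two
#'   groups.
#' @param roi logical vector over the in-mask voxels (or indices).
#' @return list: per-group `mean` and `sem`, `t`, `df`, `p`.
#' @export
roi_group_ttest <- function(z1, z2, roi) {
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) == 0) stop("empty ROI")
  a <- rowMeans(z1[, roi, drop = FALSE])
  b <- rowMeans(z2[, roi, drop = FALSE])
  res <- physio_group_test(a, b)
  list(mean = c(group1 = mean(a), group2 = mean(b)),
       sem = c(group1 = stats::sd(a) / sqrt(length(a)),
               group2 = stats::sd(b) / sqrt(length(b))),
       t = res$t, df = res$df, p = res$p)
}

#' Between-group t tests for every behavioural/physiological column
#'
#' Pooled-variance two-tailed t per numeric score column of the subjects
#' table; non-numeric or absent columns are skipped with a warning.
#'
#' @param subjects data frame with a `group` column (`EDp` / `HC`).
#' @param columns score columns to test (default: every numeric column
#'   except seeds and identifiers).
#' @return data frame with `score`, `mean_EDp`, `sd_EDp`, `mean_HC`,
#'   `sd_HC`, `t`, `df`, `p`.
#' @export
behavioral_group_tests <- function(subjects, columns = NULL) {
  stopifnot("group" %in% names(subjects))
  g1 <- subjects$group == "EDp"
  g2 <- subjects$group == "HC"
  if (!any(g1) || !any(g2)) stop("both groups must be present")
  if (is.null(columns)) {
    skip <- c("seed", "physio_seed", "lipl_loading")
    columns <- setdiff(names(subjects)[vapply(subjects, is.numeric, TRUE)], skip)
  }
  rows <- list()
  for (col in columns) {
    if (!col %in% names(subjects) || !is.numeric(subjects[[col]])) {
      warning("column skipped: ", col)
      next
    }
    a <- subjects[[col]][g1]; b <- subjects[[col]][g2]
    res <- physio_group_test(a, b)
    rows[[col]] <- data.frame(score = col, mean_EDp = mean(a),
                              sd_EDp = stats::sd(a), mean_HC = mean(b),
                              sd_HC = stats::sd(b), t = res$t, df = res$df,
                              p = res$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between ROI Z values and a behavioural score
#'
#' Two-tailed p from the t transform of r; no multiplicity correction.
#'
#' @param roi_z per-subject ROI Z values.
#' @param scores per-subject behavioural scores (same order).
#' @return list with `r`, `n`, `p`.
#' @export
roi_behavior_correlation <- function(roi_z, scores) {
  keep <- is.finite(roi_z) & is.finite(scores)
  x <- roi_z[keep]; y <- scores[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Between-group tests recomputed from printed group summaries
#'
#' Pooled two-sample t statistics recomputed from a mean/SD/n summary
#' table (as printed in a paper), e.g. [behaviour_reference()].
#'
#' @param ref data frame with `score`, `mean_EDp`, `sd_EDp`, `mean_HC`,
#'   `sd_HC`.
#' @param n_EDp,n_HC group sizes.
#' @return the table with recomputed `t` and `p` columns appended.
#' @export
summary_group_tests <- function(ref, n_EDp = 16, n_HC = 19) {
  res <- t(vapply(seq_len(nrow(ref)), function(i) {
    r <- pooled_t_summary(ref$mean_EDp[i], ref$sd_EDp[i], n_EDp,
                          ref$mean_HC[i], ref$sd_HC[i], n_HC)
    c(r$t, r$p)
  }, numeric(2)))
  ref$t <- res[, 1]
  ref$p <- res[, 2]
  ref
}
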