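#' Spatial correlation of two maps
#'
#' Pearson correlation over in-mask voxels.
#' @param map_a,map_b 3-D arrays on the same grid, or equal-length vectors.
#' @param mask logical mask (ignored when the maps are already vectors of
#'   in-mask values).
#' @return correlation coefficient.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  a <- if (!is.null(mask) && !is.null(dim(map_a))) map_a[mask] else as.numeric(map_a)
  b <- if (!is.null(mask) && !is.null(dim(map_b))) map_b[mask] else as.numeric(map_b)
  if (length(a) != length(b)) stop("maps differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance map")
  stats::cor(a, b)
}

template_matrix <- function(templates, mask) {
  tm <- vapply(templates, function(tp) {
    v <- tp$map[mask]
    v <- v - mean(v)
    s <- sqrt(mean(v^2))
    if (s == 0) stop("zero-variance template")
    v / s
  }, numeric(sum(mask)))
  t(tm)  # template x voxel, standardised (population scaling)
}

#' Match independent components to network templates
#'
#' For every template, finds the component map maximising the absolute
#' spatial correlation over the analysis mask. Matching is greedy by
#' descending |r| with ties broken by the lower component index, and a
#' component may serve at most one template. Templates whose best |r|
#' falls below `r_min` are reported absent. Matched signs are aligned so
#' the reported correlation is positive.
#'
#' @param maps an `ic_decomposition` or a component x voxel matrix of
#'   in-mask map values.
#' @param templates an `icn_templates` list.
#' @param mask logical analysis mask (taken from the decomposition when
#'   available).
#' @param r_min acceptance threshold on |r| (default 0.25).
#' @return data frame with one row per template: `template`, `component`
#'   (NA when absent), `r`, `sign`, `matched`.
#' @export
match_templates <- function(maps, templates, mask = NULL, r_min = 0.25) {
  if (inherits(maps, "ic_decomposition")) {
    if (is.null(mask)) mask <- maps$mask
    M <- maps$maps
  } else M <- maps
  stopifnot(!is.null(mask))
  TM <- template_matrix(templates, mask)
  if (ncol(TM) != ncol(M)) stop("templates and maps are on different grids")
  Ms <- M - rowMeans(M)
  Ms <- Ms / sqrt(rowMeans(Ms^2))
  R <- tcrossprod(TM, Ms) / ncol(M)        # template x component r
  out <- data.frame(template = names(templates),
                    component = NA_integer_, r = NA_real_,
                    sign = NA_real_, matched = FALSE,
                    stringsAsFactors = FALSE)
  absR <- abs(R)
  repeat {
    best <- which(absR == max(absR), arr.ind = TRUE)
    if (max(absR) < r_min || nrow(best) == 0) break
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    ti <- best[1]; ci <- best[2]
    out$component[ti] <- ci
    out$r[ti] <- absR[ti, ci]
    out$sign[ti] <- sign(R[ti, ci])
    out$matched[ti] <- TRUE
    absR[ti, ] <- -Inf
    absR[, ci] <- -Inf
    if (all(!is.finite(absR))) break
  }
  out
}

#' Cluster components across subjects (sogICA-style)
#'
#' Pools every subject's component maps, computes pairwise spatial
#' similarities, and agglomerates with average linkage on the distance
#' `1 - |r|` under the constraint that no cluster may contain two
#' components of the same subject (inadmissible merges are skipped).
#' Members are sign-aligned to their cluster centroid and the cluster map
#' is the voxel-wise mean of the aligned member Z maps. Fully
#' deterministic: no random initialisation, ties resolved by the lowest
#' (subject, component) order.
#'
#' @param ic_list named list (one element per subject) of
#'   `ic_decomposition`s or component x voxel matrices of in-mask values.
#' @param n_clusters number of clusters to retain (default: the
#'   per-subject component count).
#' @return object of class `sogica_clusters`: list with `clusters` (each:
#'   `members` data frame of subject/component/sign, `map` mean Z map
#'   vector, `similarity` mean pairwise |r|), and `membership` table.
#' @export
sogica_cluster <- function(ic_list, n_clusters = NULL) {
  if (length(ic_list) < 2) {
    # degenerate single-subject case: each component is its own cluster
    M <- if (inherits(ic_list[[1]], "ic_decomposition")) ic_list[[1]]$maps else ic_list[[1]]
    cl <- lapply(seq_len(nrow(M)), function(i)
      list(members = data.frame(subject = names(ic_list)[1], component = i,
                                sign = 1, stringsAsFactors = FALSE),
           map = M[i, ], similarity = 1))
    return(structure(list(clusters = cl,
                          membership = data.frame(
                            subject = names(ic_list)[1],
                            component = seq_len(nrow(M)),
                            cluster = seq_len(nrow(M)))),
                     class = "sogica_clusters"))
  }
  mats <- lapply(ic_list, function(x)
    if (inherits(x, "ic_decomposition")) x$maps else x)
  k_per <- vapply(mats, nrow, 0L)
  if (is.null(n_clusters)) n_clusters <- max(k_per)
  if (n_clusters > max(k_per) * length(mats))
    stop("n_clusters exceeds the total component count")
  subj_id <- rep(seq_along(mats), k_per)
  comp_id <- unlist(lapply(k_per, seq_len), use.names = FALSE)
  M <- do.call(rbind, mats)
  Ms <- M - rowMeans(M)
  Ms <- Ms / sqrt(rowMeans(Ms^2))
  R <- tcrossprod(Ms) / ncol(M)
  D <- 1 - abs(R)
  memb <- .constrained_linkage_cpp(D, subj_id, as.integer(n_clusters))
  ncl <- attr(memb, "n_clusters")
  subj_names <- names(ic_list)
  clusters <- lapply(seq_len(ncl), function(ci) {
    idx <- which(memb == ci)
    # centroid from the unsigned leading member, then sign-align members
    signs <- rep(1, length(idx))
    if (length(idx) > 1) {
      # seed signs from the first member, then refine against the centroid
      signs <- ifelse(R[idx[1], idx] < 0, -1, 1)
      cen <- colMeans(Ms[idx, , drop = FALSE] * signs)
      signs <- vapply(seq_along(idx), function(j)
        if (sum(Ms[idx[j], ] * cen) < 0) -1 else 1, 0)
    }
    map <- colMeans(M[idx, , drop = FALSE] * signs)
    sim <- if (length(idx) > 1)
      mean(abs(R[idx, idx][upper.tri(diag(length(idx)))])) else 1
    list(members = data.frame(subject = subj_names[subj_id[idx]],
                              component = comp_id[idx], sign = signs,
                              stringsAsFactors = FALSE),
         map = map, similarity = sim)
  })
  # order clusters by size then mean similarity for stable reporting
  ord <- order(-vapply(clusters, function(c) nrow(c$members), 0L),
               -vapply(clusters, function(c) c$similarity, 0))
  clusters <- clusters[ord]
  membership <- do.call(rbind, lapply(seq_along(clusters), function(ci)
    cbind(clusters[[ci]]$members[, c("subject", "component")], cluster = ci)))
  structure(list(clusters = clusters, membership = membership),
            class = "sogica_clusters")
}

#' @export
print.sogica_clusters <- function(x, ...) {
  cat(sprintf("<sogica_clusters> %d clusters\n", length(x$clusters)))
  sz <- vapply(x$clusters, function(c) nrow(c$members), 0L)
  sim <- vapply(x$clusters, function(c) c$similarity, 0)
  for (i in seq_len(min(10, length(sz))))
    cat(sprintf("  cluster %d: %d members, mean |r| %.2f\n", i, sz[i], sim[i]))
  if (length(sz) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-subject network Z maps from matched clusters
#'
#' Matches cluster mean maps to the network templates (greedy unique
#' matching as in [match_templates()]) and, for every matched cluster,
#' emits each member subject's sign-aligned Z map — the input to the
#' voxel-wise group statistics. Subjects missing from a matched cluster
#' are recorded and excluded from that network with a warning.
#'
#' @param clusters a `sogica_clusters` object.
#' @param templates an `icn_templates` list.
#' @param mask logical analysis mask.
#' @param ic_list the list of subject decompositions/matrices the clusters
#'   were built from (maps are re-read from here).
#' @param r_min template acceptance threshold.
#' @return list of class `network_zmaps`: per matched network, a list with
#'   `zmaps` (subject x voxel matrix), `subjects`, `r`, `missing`.
#' @export
subject_network_zmaps <- function(clusters, templates, mask, ic_list,
                                  r_min = 0.25) {
  cl_maps <- do.call(rbind, lapply(clusters$clusters, function(c) c$map))
  match <- match_templates(cl_maps, templates, mask, r_min)
  all_subjects <- names(ic_list)
  out <- list()
  for (i in seq_len(nrow(match))) {
    if (!match$matched[i]) next
    cl <- clusters$clusters[[match$component[i]]]
    sgn_cluster <- match$sign[i]
    mem <- cl$members
    zm <- matrix(NA_real_, nrow(mem), length(cl$map))
    for (j in seq_len(nrow(mem))) {
      x <- ic_list[[mem$subject[j]]]
      M <- if (inherits(x, "ic_decomposition")) x$maps else x
      zm[j, ] <- M[mem$component[j], ] * mem$sign[j] * sgn_cluster
    }
    missing <- setdiff(all_subjects, mem$subject)
    if (length(missing) > 0)
      warning(sprintf("network %s: no component for subject(s) %s",
                      match$template[i], paste(missing, collapse = ", ")))
    out[[match$template[i]]] <- list(zmaps = zm, subjects = mem$subject,
                                     r = match$r[i], missing = missing)
  }
  structure(out, class = "network_zmaps")
}

#' Template-first per-subject network maps
#'
#' Alternative ordering of the group stage: match every subject's
#' components to the templates directly, then stack the matched,
#' sign-aligned maps per network. Subjects without a match for a network
#' are recorded as missing.
#'
#' @inheritParams subject_network_zmaps
#' @return a `network_zmaps` list.
#' @export
subject_network_zmaps_direct <- function(ic_list, templates, mask,
                                         r_min = 0.25) {
  subj <- names(ic_list)
  per <- lapply(ic_list, match_templates, templates = templates, mask = mask,
                r_min = r_min)
  out <- list()
  for (tp in names(templates)) {
    rows <- lapply(seq_along(subj), function(i) {
      m <- per[[i]]
      m[m$template == tp & m$matched, , drop = FALSE]
    })
    hit <- which(vapply(rows, nrow, 0L) > 0)
    if (length(hit) < 2) next
    zm <- t(vapply(hit, function(i) {
      x <- ic_list[[i]]
      M <- if (inherits(x, "ic_decomposition")) x$maps else x
      M[rows[[i]]$component, ] * rows[[i]]$sign
    }, numeric(sum(mask))))
    missing <- setdiff(subj, subj[hit])
    if (length(missing) > 0)
      warning(sprintf("network %s: no matching component for %s",
                      tp, paste(missing, collapse = ", ")))
    out[[tp]] <- list(zmaps = zm, subjects = subj[hit],
                      r = mean(vapply(hit, function(i)
                        per[[i]]$r[per[[i]]$template == tp], 0)),
                      missing = missing)
  }
  structure(out, class = "network_zmaps")
}
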