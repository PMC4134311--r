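#' Full-run configuration
#'
#' Bundles the cohort, preprocessing, ICA and inference settings of an
#' end-to-end run. Every stage seed derives from `cohort$master_seed`
#' through a counter scheme, so stages can be re-run independently.
#'
#' @param cohort a [cohort_config()].
#' @param stats a [stats_config()].
#' @param n_components ICA model order per subject.
#' @param n_discard leading volumes to drop.
#' @param fwhm_mm spatial smoothing FWHM (mm).
#' @param ica_max_iter,ica_restarts FastICA iteration budget per component
#'   and restart budget for non-converged components.
#' @param match_order `"cluster_then_match"` (sogICA clustering first,
#'   templates matched to cluster maps) or `"match_then_cluster"`
#'   (templates matched per subject directly).
#' @param r_min template acceptance threshold.
#' @param n_clusters group cluster count (default: `n_components`).
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), stats = stats_config(),
                       n_components = 30, n_discard = 2, fwhm_mm = 6,
                       ica_max_iter = 100, ica_restarts = 1,
                       match_order = c("cluster_then_match",
                                       "match_then_cluster"),
                       r_min = 0.25, n_clusters = NULL) {
  match_order <- match.arg(match_order)
  structure(list(cohort = cohort, stats = stats,
                 n_components = as.integer(n_components),
                 n_discard = as.integer(n_discard), fwhm_mm = fwhm_mm,
                 ica_max_iter = as.integer(ica_max_iter),
                 ica_restarts = as.integer(ica_restarts),
                 match_order = match_order, r_min = r_min,
                 n_clusters = if (is.null(n_clusters)) as.integer(n_components)
                              else as.integer(n_clusters)),
            class = "run_config")
}

#' Serialise / restore a run configuration as YAML
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(cohort = unclass(config$cohort),
                        stats = unclass(config$stats),
                        pipeline = unclass(config)[setdiff(names(config),
                                                           c("cohort", "stats"))]),
                   path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(cohort = do.call(cohort_config, y$cohort),
             stats = do.call(stats_config, y$stats),
             n_components = y$pipeline$n_components,
             n_discard = y$pipeline$n_discard, fwhm_mm = y$pipeline$fwhm_mm,
             ica_max_iter = y$pipeline$ica_max_iter,
             ica_restarts = y$pipeline$ica_restarts,
             match_order = y$pipeline$match_order, r_min = y$pipeline$r_min,
             n_clusters = y$pipeline$n_clusters)
}

#' Run the group spatial-ICA comparison end to end
#'
#' simulate -> physio reduction -> preprocess -> per-subject FastICA ->
#' group clustering / template matching -> voxel-wise ANOVA with Monte
#' Carlo cluster-extent correction -> ROI t tests, behavioural t tests and
#' brain-behaviour correlation. Subjects are processed in a stream so
#' only their component maps are retained. When `dir` is given, maps,
#' tables, the JSON report and a log are written there.
#'
#' @param config a [run_config()].
#' @param dir optional output directory.
#' @param grid analysis grid (default [make_grid()]).
#' @param mask analysis mask (default [default_brain_mask()]).
#' @param networks planted networks.
#' @param effects planted group effects.
#' @param templates network templates used for component selection
#'   (default: all seven canonical networks on `grid`).
#' @param min_cluster optional precomputed minimum cluster extent; when
#'   `NULL` it is recomputed on `mask` with `config$stats`.
#' @param verbose print stage progress.
#' @return object of class `sogica_run` with elements `matched` (network
#'   match table), `network_stats` (per network: stat map and cluster
#'   table), `roi_tests`, `behavioural`, `physio`, `correlations`,
#'   `min_cluster`, `config`.
#' @export
run_pipeline <- function(config = run_config(), dir = NULL,
                         grid = make_grid(voxel_mm = config$cohort$voxel_mm),
                         mask = default_brain_mask(grid),
                         networks = planted_networks(),
                         effects = default_group_effects(),
                         templates = make_templates(grid),
                         min_cluster = NULL, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    say("%s", line)
    log_lines <<- c(log_lines, line)
  }
  t0 <- proc.time()[3]
  cfg <- config$cohort
  note("cohort: %d EDp + %d HC, %d volumes, master seed %d",
       cfg$n_EDp, cfg$n_HC, cfg$n_volumes, cfg$master_seed)
  cohort <- simulate_cohort(cfg, networks, effects, grid = grid)
  subjects <- cohort$subjects
  n <- nrow(subjects)

  # --- physiology -----------------------------------------------------
  physio <- do.call(rbind, lapply(seq_len(n), function(i) {
    ph <- cohort_physio(cohort, i)
    cbind(subjects[i, c("id", "group")],
          summarize_physio(ph, cfg$tr_s, cfg$n_volumes))
  }))
  subjects$tumescence_pct <- physio$tumescence_pct
  subjects$heart_rate <- physio$heart_rate
  subjects$resp_rate <- physio$resp_rate

  # --- per-subject preprocessing + ICA --------------------------------
  ic_list <- vector("list", n)
  names(ic_list) <- subjects$id
  for (i in seq_len(n)) {
    sub <- cohort_subject(cohort, i)
    pre <- preprocess_subject(sub$vol, sub$wm_mask, sub$csf_mask,
                              motion = sub$motion,
                              n_discard = config$n_discard,
                              fwhm_mm = config$fwhm_mm)
    dec <- run_subject_ica(pre$vol, mask, config$n_components,
                           seed = derive_seed(cfg$master_seed, 3L, i),
                           max_iter = config$ica_max_iter,
                           restarts = config$ica_restarts)
    dec$mask <- NULL; dec$grid <- NULL   # shared; drop per-subject copies
    ic_list[[i]] <- dec
    if (i == 1 || i %% 8 == 0)
      say("  subject %d/%d done (%.1f s elapsed)", i, n, proc.time()[3] - t0)
  }

  # --- group stage -----------------------------------------------------
  if (config$match_order == "cluster_then_match") {
    clusters <- sogica_cluster(ic_list, config$n_clusters)
    cl_maps <- do.call(rbind, lapply(clusters$clusters, function(c) c$map))
    matched <- match_templates(cl_maps, templates, mask, config$r_min)
    netz <- suppressWarnings(
      subject_network_zmaps(clusters, templates, mask, ic_list, config$r_min))
  } else {
    clusters <- NULL
    netz <- suppressWarnings(
      subject_network_zmaps_direct(ic_list, templates, mask, config$r_min))
    matched <- data.frame(template = names(templates),
                          component = NA_integer_,
                          r = NA_real_, sign = 1,
                          matched = names(templates) %in% names(netz))
    matched$r[matched$matched] <- vapply(netz, function(x) x$r, 0)
  }
  note("matched networks: %s; absent: %s",
       paste(matched$template[matched$matched], collapse = ", "),
       paste(matched$template[!matched$matched], collapse = ", "))

  # --- group inference -------------------------------------------------
  if (cfg$n_EDp < 2 || cfg$n_HC < 2)
    stop("stats stage requires at least 2 subjects per group")
  if (is.null(min_cluster)) {
    mc <- montecarlo_min_cluster(mask, config$stats)
    note("minimum cluster extent: %d voxels (mask %d voxels)",
         mc$min_cluster, mc$n_mask)
  } else {
    mc <- min_cluster
  }
  kmin <- if (inherits(mc, "mc_threshold")) mc$min_cluster else mc
  network_stats <- list()
  roi_tests <- list()
  for (nm in names(netz)) {
    nz <- netz[[nm]]
    grp <- subjects$group[match(nz$subjects, subjects$id)]
    if (sum(grp == "EDp") < 2 || sum(grp == "HC") < 2) next
    sm <- voxelwise_group_anova(nz$zmaps[grp == "EDp", , drop = FALSE],
                                nz$zmaps[grp == "HC", , drop = FALSE])
    ct <- threshold_and_label(sm, grid, mask, config$stats$voxel_p,
                              kmin, config$stats$connectivity)
    network_stats[[nm]] <- list(stat = sm, clusters = ct)
    if (nrow(ct) > 0) {
      lab <- attr(ct, "labels")
      roi_tests[[nm]] <- lapply(seq_len(nrow(ct)), function(ri) {
        roi <- (lab[mask] == ct$label[ri])
        roi_group_ttest(nz$zmaps[grp == "EDp", , drop = FALSE],
                        nz$zmaps[grp == "HC", , drop = FALSE], roi)
      })
    }
  }

  behavioural <- behavioral_group_tests(subjects)

  # brain-behaviour: left-IPL DMN cluster Z vs SAI-E excitation in EDp
  correlations <- NULL
  if ("DMN" %in% names(network_stats) &&
      nrow(network_stats$DMN$clusters) > 0 &&
      "SAI_excitation" %in% names(subjects)) {
    ct <- network_stats$DMN$clusters
    lipl <- c(-49, -62, 27)
    dd <- sqrt((ct$peak_x - lipl[1])^2 + (ct$peak_y - lipl[2])^2 +
               (ct$peak_z - lipl[3])^2)
    ri <- which.min(dd)
    if (dd[ri] < 30) {
      lab <- attr(ct, "labels")
      roi <- (lab[mask] == ct$label[ri])
      nz <- netz$DMN
      grp <- subjects$group[match(nz$subjects, subjects$id)]
      zv <- rowMeans(nz$zmaps[, roi, drop = FALSE])
      sc <- subjects$SAI_excitation[match(nz$subjects, subjects$id)]
      ed <- grp == "EDp"
      if (sum(ed) >= 3)
        correlations <- c(list(roi = "DMN left IPL cluster",
                               score = "SAI_excitation", group = "EDp"),
                          roi_behavior_correlation(zv[ed], sc[ed]))
    }
  }

  run <- structure(list(matched = matched, clusters = clusters,
                        network_zmaps = netz,
                        network_stats = network_stats, roi_tests = roi_tests,
                        behavioural = behavioural, physio = physio,
                        correlations = correlations, min_cluster = mc,
                        subjects = subjects, config = config,
                        elapsed_s = unname(proc.time()[3] - t0),
                        log = log_lines),
                   class = "sogica_run")
  if (!is.null(dir)) write_run(run, dir, grid, mask)
  run
}

#' @export
print.sogica_run <- function(x, ...) {
  cat("<sogica_run>\n")
  cat("  matched networks:",
      paste(x$matched$template[x$matched$matched], collapse = ", "), "\n")
  cat("  absent networks: ",
      paste(x$matched$template[!x$matched$matched], collapse = ", "), "\n")
  kmin <- if (inherits(x$min_cluster, "mc_threshold"))
    x$min_cluster$min_cluster else x$min_cluster
  cat(sprintf("  cluster correction: voxel p < %g, min extent %d voxels\n",
              x$config$stats$voxel_p, kmin))
  for (nm in names(x$network_stats)) {
    ct <- x$network_stats[[nm]]$clusters
    cat(sprintf("  %s: %d corrected cluster(s)\n", nm, nrow(ct)))
  }
  invisible(x)
}

run_report <- function(run) {
  kmin <- if (inherits(run$min_cluster, "mc_threshold"))
    run$min_cluster$min_cluster else run$min_cluster
  list(
    matched_networks = run$matched$template[run$matched$matched],
    absent_networks = run$matched$template[!run$matched$matched],
    min_cluster = kmin,
    cluster_tables = lapply(run$network_stats, function(ns)
      as.data.frame(ns$clusters)),
    roi_tests = lapply(run$roi_tests, function(rts)
      lapply(rts, function(r) r[c("mean", "sem", "t", "df", "p")])),
    behavioural = run$behavioural,
    physio_group_means = stats::aggregate(
      run$physio[, c("tumescence_pct", "heart_rate", "resp_rate")],
      by = list(group = run$physio$group), FUN = mean),
    correlation = run$correlations,
    config = list(cohort = unclass(run$config$cohort),
                  stats = unclass(run$config$stats))
  )
}

write_run <- function(run, dir, grid, mask) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(run$config, file.path(dir, "config.yaml"))
  utils::write.table(run$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$behavioural, file.path(dir, "behavioural_tests.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$physio, file.path(dir, "physio_summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(run$network_stats)) {
    ns <- run$network_stats[[nm]]
    write_volume(unmask_vector(ns$stat$t, mask),
                 file.path(dir, sprintf("%s_tmap.nii.gz", nm)), grid)
    utils::write.table(as.data.frame(ns$clusters),
                       file.path(dir, sprintf("%s_clusters.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(run$network_zmaps))
    write_volume(unmask_vector(colMeans(run$network_zmaps[[nm]]$zmaps), mask),
                 file.path(dir, sprintf("%s_mean_zmap.nii.gz", nm)), grid)
  jsonlite::write_json(run_report(run), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       dataframe = "columns")
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Packaged test datasets
#'
#' `tiny` builds a reduced cohort (4 + 4 subjects, compact grid, 60
#' volumes) that runs end to end in about a minute; `demo` is the full
#' 16 + 19 cohort at the default grid. Both carry their planted ground
#' truth in the manifest/seeds.
#'
#' @param size `"tiny"` or `"demo"`.
#' @param dir optional output directory (written with [simulate_cohort()]).
#' @param master_seed master seed.
#' @return the `sogica_cohort` (invisibly when written to disk).
#' @export
make_fixtures <- function(size = c("tiny", "demo"), dir = NULL,
                          master_seed = 42L) {
  size <- match.arg(size)
  if (size == "tiny") {
    cfg <- cohort_config(n_EDp = 4, n_HC = 4, n_volumes = 60, voxel_mm = 6,
                         master_seed = master_seed)
    simulate_cohort(cfg, dir = dir)
  } else {
    cfg <- cohort_config(master_seed = master_seed)
    simulate_cohort(cfg, dir = dir)
  }
}

#' Tiny-run settings matched to the tiny fixture
#'
#' Convenience `run_config` for the reduced cohort: lower model order and
#' a lighter Monte Carlo, for smoke tests.
#' @param master_seed master seed.
#' @export
tiny_run_config <- function(master_seed = 42L) {
  run_config(cohort = cohort_config(n_EDp = 4, n_HC = 4, n_volumes = 60,
                                    voxel_mm = 6, master_seed = master_seed),
             stats = stats_config(n_iterations = 200),
             n_components = 8, ica_max_iter = 60)
}
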