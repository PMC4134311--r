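#' Cohort configuration
#'
#' Study-level parameters of the synthetic two-group cohort. The defaults
#' reproduce the acquisition of the emulated study: 16 patients (EDp) and
#' 19 controls (HC), 210 volumes at TR = 2 s on a 3-mm grid.
#'
#' @param n_EDp,n_HC group sizes.
#' @param n_volumes volumes per run.
#' @param tr_s repetition time, seconds.
#' @param voxel_mm isotropic voxel size, mm.
#' @param noise_sd SD of i.i.d. Gaussian voxel noise (signal time courses
#'   have unit variance and node peaks unit spatial weight).
#' @param drift_amplitude SD of the rank-1 linear drift's spatial weights.
#' @param signal_amplitude network signal amplitude at a unit-weight voxel.
#' @param loading_jitter_sd between-subject SD of the relative node-loading
#'   jitter (lognormal-free multiplicative Gaussian, truncated at 0.05).
#' @param nuisance_amplitude amplitude of the WM and CSF nuisance signals.
#' @param behaviour_coupling correlation between the planted left-IPL DMN
#'   loading and the SAI-E excitation score within the EDp group.
#' @param master_seed integer master seed; all per-subject seeds derive
#'   from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_EDp = 16, n_HC = 19, n_volumes = 210, tr_s = 2,
                          voxel_mm = 3, noise_sd = 0.35, drift_amplitude = 0.3,
                          signal_amplitude = 1, loading_jitter_sd = 0.4,
                          nuisance_amplitude = 0.5, behaviour_coupling = 0.6,
                          master_seed = 42L) {
  stopifnot(n_EDp >= 0, n_HC >= 0, n_volumes >= 10, tr_s > 0, voxel_mm > 0,
            noise_sd >= 0, loading_jitter_sd >= 0,
            is.finite(master_seed))
  structure(list(n_EDp = as.integer(n_EDp), n_HC = as.integer(n_HC),
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 voxel_mm = voxel_mm, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 signal_amplitude = signal_amplitude,
                 loading_jitter_sd = loading_jitter_sd,
                 nuisance_amplitude = nuisance_amplitude,
                 behaviour_coupling = behaviour_coupling,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Deterministic seed fan-out
#'
#' Derives a stage/index-specific RNG seed from a master seed with a simple
#' counter-based congruential scheme; every derived seed stays below 2^31.
#' @param master integer master seed.
#' @param stage integer stage offset.
#' @param index integer counter within the stage.
#' @export
derive_seed <- function(master, stage = 0L, index = 0L) {
  s <- (abs(as.numeric(master)) %% 98561) * 20011 +
    as.numeric(stage) * 104729 + as.numeric(index) * 1009
  as.integer(s %% 2147483629) + 1L
}

#' Planted group effects at network nodes
#'
#' Node-loading multipliers for the two groups, mirroring the reported
#' between-group differences: reduced DMN loading at mPFC, PCC and left
#' IPL, reduced SN loading at the right insula, increased SN loading at
#' the dorsal ACC. With the default multiplier gap (0.55 vs 1.0) and the
#' default loading jitter SD (0.4), the planted standardised node effect
#' is about 1.1 between-subject SD.
#' @return data frame with columns `network`, `node`, `mult_EDp`, `mult_HC`.
#' @export
default_group_effects <- function() {
  data.frame(
    network = c("DMN", "DMN", "DMN", "SN", "SN"),
    node = c("mPFC", "PCC", "IPL_L", "AI/IFG_R", "ACC_R"),
    mult_EDp = c(0.55, 0.55, 0.55, 0.55, 1.45),
    mult_HC = c(1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

group_effect_spec <- function(network, node, mult_EDp, mult_HC = 1) {
  stopifnot(is.finite(mult_EDp), is.finite(mult_HC), mult_EDp >= 0, mult_HC >= 0)
  data.frame(network = network, node = node, mult_EDp = mult_EDp,
             mult_HC = mult_HC, stringsAsFactors = FALSE)
}

#' Smooth band-limited network time course
#'
#' Gaussian noise low-pass filtered below `f_hi` Hz (Fourier truncation),
#' standardised to zero mean and unit variance.
#' @param n number of time points.
#' @param tr_s sampling interval, seconds.
#' @param seed integer seed.
#' @param f_hi upper frequency bound, Hz.
#' @export
simulate_timecourse <- function(n, tr_s, seed = NULL, f_hi = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * tr_s)
  f[abs(freq) >= f_hi] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Default white-matter and CSF masks
#'
#' Small ellipsoidal regions inside the synthetic brain: two deep
#' white-matter blobs and a midline third-ventricle-like CSF region.
#' @param grid a `vox_grid`.
#' @return list with logical arrays `wm` and `csf`.
#' @export
default_nuisance_masks <- function(grid = make_grid()) {
  wm <- ellipsoid_mask(grid, c(26, -20, 28), c(8, 10, 8)) |
    ellipsoid_mask(grid, c(-26, -20, 28), c(8, 10, 8))
  csf <- ellipsoid_mask(grid, c(0, -24, 14), c(4, 12, 8))
  list(wm = wm, csf = csf)
}

subject_loadings <- function(atlas, effects, group, jitter_sd) {
  lapply(atlas$networks, function(nw) {
    nd <- nw$nodes
    mult <- rep(1, nrow(nd))
    if (nrow(effects) > 0) {
      for (i in seq_len(nrow(effects))) {
        if (effects$network[i] == nw$spec$name) {
          j <- match(effects$node[i], nd$name)
          if (!is.na(j))
            mult[j] <- if (group == "EDp") effects$mult_EDp[i] else effects$mult_HC[i]
        }
      }
    }
    pmax(mult * (1 + stats::rnorm(nrow(nd), 0, jitter_sd)), 0.05)
  })
}

network_map_from_loadings <- function(atlas, network, loadings) {
  nw <- atlas$networks[[network]]
  map <- array(0, atlas$grid$dim)
  nd <- nw$nodes
  for (i in seq_len(nrow(nd)))
    map <- map + loadings[i] *
      gaussian_bump(atlas$grid, c(nd$x[i], nd$y[i], nd$z[i]), nd$radius_mm[i])
  map
}

#' Simulate one subject's 4-D run
#'
#' Voxel time series = sum over networks of (node-weighted spatial map) x
#' (band-limited unit-variance time course) x group multiplier, plus WM
#' and CSF nuisance signals confined to their masks, a rank-1 linear
#' drift, and i.i.d. Gaussian noise. Deterministic given `seed`.
#'
#' @param atlas an `icn_atlas` of the planted networks.
#' @param effects data frame of group effects ([default_group_effects()]).
#' @param group `"EDp"` or `"HC"`.
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param masks nuisance masks as from [default_nuisance_masks()].
#' @return list with `vol` (`vol4d`), `wm_mask`, `csf_mask`, `motion`
#'   (all-zero 6-parameter table) and `truth` (planted loadings, time
#'   courses and nuisance series).
#' @export
simulate_subject <- function(atlas, effects, group, cfg, seed,
                             masks = default_nuisance_masks(atlas$grid)) {
  stopifnot(inherits(atlas, "icn_atlas"), group %in% c("EDp", "HC"))
  grid <- atlas$grid
  nt <- cfg$n_volumes
  V <- prod(grid$dim)
  set.seed(seed)
  loadings <- subject_loadings(atlas, effects, group, cfg$loading_jitter_sd)
  tcs <- sapply(names(atlas$networks), function(nm)
    simulate_timecourse(nt, cfg$tr_s), simplify = TRUE)
  maps <- lapply(stats::setNames(nm = names(atlas$networks)), function(nm)
    network_map_from_loadings(atlas, nm, loadings[[nm]]))
  wm_tc <- simulate_timecourse(nt, cfg$tr_s)
  csf_tc <- simulate_timecourse(nt, cfg$tr_s)
  # assemble all rank-1 terms (networks, nuisance, drift) in one product
  S <- cbind(tcs * cfg$signal_amplitude,
             wm = wm_tc * cfg$nuisance_amplitude,
             csf = csf_tc * cfg$nuisance_amplitude,
             drift = seq(-0.5, 0.5, length.out = nt))
  A <- matrix(0, ncol(S), V)
  for (j in seq_along(maps)) A[j, ] <- as.vector(maps[[j]])
  A[length(maps) + 1, as.vector(masks$wm)] <- 1
  A[length(maps) + 2, as.vector(masks$csf)] <- 1
  A[length(maps) + 3, ] <- stats::rnorm(V, 0, cfg$drift_amplitude)
  X <- S %*% A
  if (cfg$noise_sd > 0)
    X <- X + stats::rnorm(nt * V, 0, cfg$noise_sd)
  motion <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  list(vol = vol4d(X, grid, cfg$tr_s), wm_mask = masks$wm,
       csf_mask = masks$csf, motion = motion,
       truth = list(group = group, seed = seed, loadings = loadings,
                    timecourses = tcs, nuisance = cbind(wm = wm_tc, csf = csf_tc),
                    maps = maps))
}

#' Printed group summary table of the emulated study
#'
#' Mean and SD per group for the demographic, psychological and
#' physiological scores, as printed in the source study's summary table;
#' used both to parameterise the behavioural generator and to recompute
#' the between-group t statistics from summaries.
#' @return data frame.
#' @export
behaviour_reference <- function() {
  data.frame(
    score = c("age", "education", "IIEF5", "BIS", "BAS_reward", "BAS_drive",
              "BAS_fun", "STAI_Y1", "STAI_Y2", "SAI_excitation", "SAI_anxiety",
              "SAI_total", "tumescence_pct", "heart_rate", "resp_rate"),
    mean_EDp = c(33.87, 14.5, 14.5, 20.8, 19, 12, 11.2, 38.1, 43.2, 74, 76,
                 2.06, 0.81, 74, 0.68),
    sd_EDp = c(11.2, 2.3, 5.5, 3.4, 2.4, 3.7, 2.8, 8.9, 9.2, 26.7, 17.4,
               15.5, 7.1, 12.5, 0.10),
    mean_HC = c(33.57, 14.5, 24, 21.26, 19.6, 12.8, 13, 35.4, 39, 106, 98,
                -7.84, 10.32, 75.4, 0.69),
    sd_HC = c(11.4, 2.7, 0.93, 3.7, 2.5, 2.7, 2.3, 7.3, 8.5, 28.1, 14.8,
              15.3, 16.4, 11.2, 0.17),
    t_printed = c(0.076, 0.041, -7.37, -0.34, -0.77, -0.75, -2.03, 0.98,
                  1.41, -4.03, 1.90, -3.42, -2.13, 0.35, 0.16),
    stringsAsFactors = FALSE
  )
}

#' Simulate one subject's physiological traces
#'
#' 100-Hz tumescence cuff pressure around a baseline with a sigmoid rise
#' to a plateau (amplitude in percent of baseline), a cardiac R-peak event
#' train at a given mean rate, and a respiratory belt sinusoid.
#'
#' @param group `"EDp"` or `"HC"` (sets default amplitudes/rates).
#' @param cfg a [cohort_config()] (duration = `n_volumes * tr_s`).
#' @param seed integer seed.
#' @param tumescence_amp_pct plateau amplitude, percent of baseline
#'   (default: HC 10.32, EDp 0.81 — the emulated group means).
#' @param cardiac_rate_bpm mean cardiac rate (default HC 75.4, EDp 74).
#' @param resp_rate_cpm respiratory rate in cycles/min (default HC 15.0,
#'   EDp 14.7; the printed unit of the source table is implausible, so the
#'   generator states its unit explicitly).
#' @param baseline_mmHg cuff pre-inflation pressure.
#' @param rise_onset_s,rise_tau_s onset and time constant of the sigmoid.
#' @param noise_sd additive measurement noise on continuous traces.
#' @param ibi_jitter relative SD of the inter-beat intervals.
#' @param fs sampling rate, Hz.
#' @return list of class `physio_traces`: `tumescence` and `respiratory`
#'   (data frames `time_s`, `value`), `cardiac_events` (seconds), and
#'   `truth` (the planted parameters).
#' @export
simulate_physio <- function(group, cfg, seed,
                            tumescence_amp_pct = if (group == "HC") 10.32 else 0.81,
                            cardiac_rate_bpm = if (group == "HC") 75.4 else 74,
                            resp_rate_cpm = if (group == "HC") 15.0 else 14.7,
                            baseline_mmHg = 80, rise_onset_s = 20,
                            rise_tau_s = 4, noise_sd = 0.2,
                            ibi_jitter = 0.02, fs = 100) {
  stopifnot(group %in% c("EDp", "HC"), fs > 0, cardiac_rate_bpm > 0,
            resp_rate_cpm > 0, baseline_mmHg > 0)
  set.seed(seed)
  dur <- cfg$n_volumes * cfg$tr_s
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- 1 / (1 + exp(-(tt - rise_onset_s) / rise_tau_s))
  tum <- baseline_mmHg * (1 + tumescence_amp_pct / 100 * sig) +
    stats::rnorm(length(tt), 0, noise_sd)
  ibi0 <- 60 / cardiac_rate_bpm
  n_beats <- ceiling(dur / ibi0) + 10
  ibis <- ibi0 * (1 + stats::rnorm(n_beats, 0, ibi_jitter))
  ev <- cumsum(pmax(ibis, 0.2))
  ev <- ev[ev < dur]
  resp <- sin(2 * pi * (resp_rate_cpm / 60) * tt) +
    stats::rnorm(length(tt), 0, noise_sd / 4)
  structure(list(
    tumescence = data.frame(time_s = tt, value = tum),
    cardiac_events = ev,
    respiratory = data.frame(time_s = tt, value = resp),
    truth = list(amp_pct = tumescence_amp_pct, cardiac_rate_bpm = cardiac_rate_bpm,
                 resp_rate_cpm = resp_rate_cpm, baseline_mmHg = baseline_mmHg,
                 rise_onset_s = rise_onset_s, rise_tau_s = rise_tau_s)),
    class = "physio_traces")
}

simulate_behaviour <- function(plan_subjects, cfg) {
  ref <- behaviour_reference()
  scores <- c("age", "education", "IIEF5", "BIS", "BAS_reward", "BAS_drive",
              "BAS_fun", "STAI_Y1", "STAI_Y2", "SAI_excitation", "SAI_anxiety",
              "SAI_total")
  set.seed(derive_seed(cfg$master_seed, stage = 7L))
  out <- plan_subjects
  for (sc in scores) {
    r <- ref[ref$score == sc, ]
    m <- ifelse(out$group == "EDp", r$mean_EDp, r$mean_HC)
    s <- ifelse(out$group == "EDp", r$sd_EDp, r$sd_HC)
    out[[sc]] <- round(m + s * stats::rnorm(nrow(out)), 2)
  }
  out
}

#' Build the cohort plan and (optionally) write the dataset to disk
#'
#' Assembles the subjects table (ids, group labels, derived seeds,
#' behavioural scores drawn from the printed group summaries, planted
#' physiological parameters) and, when `dir` is given, simulates and
#' writes every subject's 4-D NIfTI, masks, motion table and physiological
#' traces plus a JSON manifest. Per-subject image data can always be
#' (re)generated deterministically with [simulate_subject()] via the
#' recorded seeds, so pipelines may stream subjects without a disk copy.
#'
#' The SAI-E excitation score of the EDp group is linearly coupled to the
#' planted left-IPL DMN loading with correlation `cfg$behaviour_coupling`.
#'
#' @param cfg a [cohort_config()].
#' @param networks planted networks (default [planted_networks()]).
#' @param effects planted group effects ([default_group_effects()]).
#' @param grid analysis grid.
#' @param dir output directory, or `NULL` for a plan-only (no image files).
#' @return object of class `sogica_cohort`: list with `cfg`, `atlas`,
#'   `effects`, `subjects` (data frame), `masks`, and `dir`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), networks = planted_networks(),
                            effects = default_group_effects(),
                            grid = make_grid(voxel_mm = cfg$voxel_mm),
                            dir = NULL) {
  atlas <- make_network_atlas(networks, grid)
  n <- cfg$n_EDp + cfg$n_HC
  if (n == 0) stop("empty cohort")
  subjects <- data.frame(
    id = c(sprintf("EDp%02d", seq_len(cfg$n_EDp)),
           sprintf("HC%02d", seq_len(cfg$n_HC))),
    group = c(rep("EDp", cfg$n_EDp), rep("HC", cfg$n_HC)),
    seed = derive_seed(cfg$master_seed, 1L, seq_len(n)),
    physio_seed = derive_seed(cfg$master_seed, 2L, seq_len(n)),
    stringsAsFactors = FALSE
  )
  subjects <- simulate_behaviour(subjects, cfg)

  # planted physiological parameters (between-subject spread around the
  # group means; amplitudes may be mildly negative = detumescence)
  set.seed(derive_seed(cfg$master_seed, 8L))
  subjects$tumescence_amp_pct <- round(ifelse(subjects$group == "EDp",
    0.81 + 2 * stats::rnorm(n), 10.32 + 5 * stats::rnorm(n)), 3)
  subjects$cardiac_rate_bpm <- round(pmax(ifelse(subjects$group == "EDp",
    74 + 12.5 * stats::rnorm(n), 75.4 + 11.2 * stats::rnorm(n)), 40), 2)
  subjects$resp_rate_cpm <- round(pmax(ifelse(subjects$group == "EDp",
    14.7 + 2 * stats::rnorm(n), 15.0 + 2 * stats::rnorm(n)), 6), 2)

  # left-IPL loading / SAI-E excitation coupling within EDp
  if (cfg$n_EDp > 1 && "DMN" %in% names(atlas$networks) &&
      cfg$behaviour_coupling != 0) {
    lipl <- vapply(seq_len(n), function(i) {
      set.seed(subjects$seed[i])
      ld <- subject_loadings(atlas, effects, subjects$group[i],
                             cfg$loading_jitter_sd)
      ld$DMN[match("IPL_L", atlas$networks$DMN$nodes$name)]
    }, 0)
    subjects$lipl_loading <- lipl
    ed <- subjects$group == "EDp"
    z <- scale(lipl[ed])[, 1]
    r <- behaviour_reference()
    rr <- r[r$score == "SAI_excitation", ]
    rho <- cfg$behaviour_coupling
    set.seed(derive_seed(cfg$master_seed, 9L))
    subjects$SAI_excitation[ed] <- round(rr$mean_EDp + rr$sd_EDp *
      (rho * z + sqrt(1 - rho^2) * stats::rnorm(sum(ed))), 2)
  }

  cohort <- structure(list(cfg = cfg, atlas = atlas, effects = effects,
                           subjects = subjects,
                           masks = default_nuisance_masks(grid), dir = dir),
                      class = "sogica_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.sogica_cohort <- function(x, ...) {
  cat(sprintf("<sogica_cohort> %d EDp + %d HC subjects, %d volumes, TR %g s\n",
              x$cfg$n_EDp, x$cfg$n_HC, x$cfg$n_volumes, x$cfg$tr_s))
  cat(sprintf("  networks: %s\n", paste(names(x$atlas$networks), collapse = ", ")))
  if (!is.null(x$dir)) cat("  on disk at", x$dir, "\n")
  invisible(x)
}

#' Simulate (or re-simulate) one cohort subject's image data
#' @param cohort a `sogica_cohort`.
#' @param i subject row index or id.
#' @export
cohort_subject <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subjects$id)
  simulate_subject(cohort$atlas, cohort$effects, cohort$subjects$group[i],
                   cohort$cfg, cohort$subjects$seed[i], cohort$masks)
}

#' Simulate one cohort subject's physiological traces
#' @param cohort a `sogica_cohort`.
#' @param i subject row index or id.
#' @export
cohort_physio <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subjects$id)
  s <- cohort$subjects[i, ]
  simulate_physio(s$group, cohort$cfg, s$physio_seed,
                  tumescence_amp_pct = s$tumescence_amp_pct,
                  cardiac_rate_bpm = s$cardiac_rate_bpm,
                  resp_rate_cpm = s$resp_rate_cpm)
}

write_cohort <- function(cohort, dir) {
  if (dir.exists(dir) && length(list.files(dir)) > 0)
    stop("output directory exists and is not empty: ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$atlas$grid
  write_volume(cohort$masks$wm * 1, file.path(dir, "wm_mask.nii.gz"), grid)
  write_volume(cohort$masks$csf * 1, file.path(dir, "csf_mask.nii.gz"), grid)
  files <- character(0)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    sub <- cohort_subject(cohort, i)
    f <- file.path(dir, sprintf("%s_bold.nii.gz", id))
    write_volume(sub$vol, f)
    utils::write.table(sub$motion, file.path(dir, sprintf("%s_motion.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ph <- cohort_physio(cohort, i)
    utils::write.table(ph$tumescence, file.path(dir, sprintf("%s_tumescence.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(time_s = ph$cardiac_events),
                       file.path(dir, sprintf("%s_cardiac.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ph$respiratory, file.path(dir, sprintf("%s_respiratory.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(config = unclass(cohort$cfg),
                   networks = names(cohort$atlas$networks),
                   effects = cohort$effects,
                   subjects = cohort$subjects[, c("id", "group", "seed",
                                                  "physio_seed")],
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
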