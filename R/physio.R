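#' Tumescence percent change, TR-locked
#'
#' Down-samples the 100-Hz cuff-pressure trace to one value per TR
#' (within-TR block mean), removes the least-squares linear trend (the
#' series mean is retained), and expresses the series as percent change
#' relative to a baseline taken as the mean of the first 10 s of the
#' down-sampled raw trace — the cuff is inflated to a known pressure
#' before acquisition, so the opening seconds are a meaningful reference.
#'
#' @param trace data frame with `time_s` and `value` (mmHg), sampled
#'   regularly and covering the whole run.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of TR blocks to produce.
#' @param baseline_s length of the baseline window, seconds.
#' @return list with `series` (percent change per TR), `mean` (its mean
#'   over the run) and `baseline` (mmHg).
#' @export
tumescence_percent_change <- function(trace, tr_s, n_volumes, baseline_s = 10) {
  stopifnot(is.data.frame(trace), all(c("time_s", "value") %in% names(trace)))
  dur <- n_volumes * tr_s
  if (max(trace$time_s) < dur - tr_s)
    stop("trace shorter than the imaging run")
  block <- pmin(floor(trace$time_s / tr_s) + 1, n_volumes)
  keep <- trace$time_s < dur
  ds <- as.numeric(tapply(trace$value[keep], block[keep], mean))
  if (length(ds) < n_volumes) stop("trace does not cover every TR")
  nb <- max(1, floor(baseline_s / tr_s))
  baseline <- mean(ds[seq_len(nb)])
  if (baseline <= 0) stop("non-positive baseline")
  t_idx <- seq_along(ds)
  trend <- unname(stats::fitted(stats::lm(ds ~ t_idx)))
  detr <- ds - trend + mean(ds)
  pct <- unname(100 * (detr - baseline) / baseline)
  list(series = pct, mean = mean(pct), baseline = baseline)
}

#' Cardiac rate series from R-peak event times
#'
#' Instantaneous rate = 60 / inter-beat interval, assigned to the interval
#' midpoint and linearly interpolated to the TR grid (constant
#' extrapolation at the ends).
#'
#' @param events strictly increasing R-peak times, seconds.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of TR samples.
#' @return list with `series` (beats/min per TR) and `mean`.
#' @export
cardiac_rate <- function(events, tr_s, n_volumes) {
  if (length(events) < 2) stop("need at least 2 cardiac events")
  if (any(diff(events) <= 0)) stop("event times must be strictly increasing")
  ibi <- diff(events)
  mid <- events[-length(events)] + ibi / 2
  rate <- 60 / ibi
  tr_t <- (seq_len(n_volumes) - 0.5) * tr_s
  series <- stats::approx(mid, rate, xout = tr_t, rule = 2)$y
  list(series = series, mean = mean(series))
}

#' Respiratory rate series from a belt trace
#'
#' Cycle rate from rising zero-crossing intervals of the mean-centred
#' trace (crossing times located by linear interpolation), assigned to
#' interval midpoints and interpolated to the TR grid.
#'
#' @param trace data frame with `time_s` and `value`.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of TR samples.
#' @return list with `series` (cycles/min per TR) and `mean`.
#' @export
respiratory_rate <- function(trace, tr_s, n_volumes) {
  x <- trace$value - mean(trace$value)
  tt <- trace$time_s
  # light moving-average smoothing (~0.5 s) so measurement noise does not
  # produce spurious crossings near zero
  if (length(tt) > 3) {
    dt <- stats::median(diff(tt))
    w <- max(1L, round(0.5 / dt))
    if (w > 1) {
      x <- stats::filter(x, rep(1 / w, w), sides = 2)
      keep <- !is.na(x)
      x <- as.numeric(x[keep]); tt <- tt[keep]
    }
  }
  s <- sign(x)
  i <- which(s[-length(s)] <= 0 & s[-1] > 0)
  if (length(i) < 2) stop("no complete respiratory cycle in trace")
  cross <- tt[i] - x[i] * (tt[i + 1] - tt[i]) / (x[i + 1] - x[i])
  iv <- diff(cross)
  mid <- cross[-length(cross)] + iv / 2
  rate <- 60 / iv
  tr_t <- (seq_len(n_volumes) - 0.5) * tr_s
  series <- stats::approx(mid, rate, xout = tr_t, rule = 2)$y
  list(series = series, mean = mean(series))
}

#' Pooled-variance two-sample t test
#'
#' Classical two-tailed two-sample t with pooled variance and
#' df = n1 + n2 - 2, computed from the raw values.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
physio_group_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  pooled_t_summary(mean(a), stats::sd(a), n1, mean(b), stats::sd(b), n2)
}

#' Pooled two-sample t from group summaries
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
pooled_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, mean1 = m1, mean2 = m2))
    stop("zero pooled variance with unequal means")
  }
  tval <- (m1 - m2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean1 = m1, mean2 = m2)
}

#' Per-subject physiological summaries
#'
#' Reduces a subject's traces to the three summary numbers compared
#' between groups: mean tumescence percent change, mean cardiac rate and
#' mean respiratory rate over the run.
#'
#' @param physio a `physio_traces` object ([simulate_physio()]) or a list
#'   with elements `tumescence`, `cardiac_events`, `respiratory`.
#' @param tr_s,n_volumes the imaging run timing the traces are locked to.
#' @return one-row data frame.
#' @export
summarize_physio <- function(physio, tr_s, n_volumes) {
  data.frame(
    tumescence_pct = tumescence_percent_change(physio$tumescence, tr_s,
                                               n_volumes)$mean,
    heart_rate = cardiac_rate(physio$cardiac_events, tr_s, n_volumes)$mean,
    resp_rate = respiratory_rate(physio$respiratory, tr_s, n_volumes)$mean
  )
}

#' Read a subject's physiological traces from TSV files
#'
#' Counterpart of the files written by [simulate_cohort()]: continuous
#' traces as two-column TSVs (`time_s`, `value`), cardiac R-peaks as a
#' one-column TSV of event times.
#'
#' @param dir directory holding `<id>_tumescence.tsv`,
#'   `<id>_cardiac.tsv`, `<id>_respiratory.tsv`.
#' @param id subject identifier.
#' @return list with `tumescence`, `cardiac_events`, `respiratory`.
#' @export
read_physio <- function(dir, id) {
  rd <- function(suffix) {
    f <- file.path(dir, sprintf("%s_%s.tsv", id, suffix))
    if (!file.exists(f)) stop("missing trace file: ", f)
    utils::read.table(f, header = TRUE, sep = "\t")
  }
  list(tumescence = rd("tumescence"),
       cardiac_events = rd("cardiac")$time_s,
       respiratory = rd("respiratory"))
}
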