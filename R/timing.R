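#' Activation-call configuration
#'
#' Tuning parameters of the rate-change calling pipeline: light
#' Savitzky--Golay smoothing, pre-peak cropping, a single slope change
#' fitted by exact dynamic programming, and an acceptance rule.  A call is
#' accepted when the post-change slope exceeds the pre-change slope, is
#' positive, and the change explains at least `min_improvement` of the
#' single-line residual in the analysis window; the last condition rejects
#' the spurious breaks that any noisy but changeless trace would otherwise
#' yield (the default 0.6 sits far above the residual fraction a single
#' break explains on white noise at these window lengths, and far below the
#' near-1 fraction of a genuine mitotic switch).
#'
#' @param smooth_window,polyorder smoothing parameters ([smooth_trace()]).
#' @param n_before pre-peak window length in points ([crop_prepeak()]).
#' @param min_improvement minimum fractional RSS improvement of the
#'   one-change fit over the single-line fit.
#' @param min_snr minimum signal-to-noise ratio of the accepted change: the
#'   fitted slope difference, accumulated over the post-change segment, must
#'   exceed `min_snr` times the measurement noise scale, estimated robustly
#'   from the raw trace's first differences.  A single break on a pure-noise
#'   window can explain a substantial residual fraction (the window is
#'   anchored at the trace maximum), but its accumulated slope change stays
#'   within a few noise standard deviations, whereas a mitotic switch
#'   accumulates tens of them; this criterion is what separates the two.
#' @param min_seg minimum segment length for the change-point fit.
#' @return a list of class `"activation_config"`.
#' @export
activation_config <- function(smooth_window = 5, polyorder = 2,
                              n_before = 12, min_improvement = 0.6,
                              min_snr = 8, min_seg = 3) {
  structure(list(smooth_window = smooth_window, polyorder = polyorder,
                 n_before = n_before, min_improvement = min_improvement,
                 min_snr = min_snr, min_seg = min_seg),
            class = "activation_config")
}

new_activation_call <- function(cell_id, channel, time = NA_real_,
                                index = NA_integer_, slope_pre = NA_real_,
                                slope_post = NA_real_,
                                improvement = NA_real_,
                                window = c(NA_integer_, NA_integer_),
                                reason = NULL) {
  structure(list(cell_id = cell_id, channel = channel, time = time,
                 index = index, slope_pre = slope_pre,
                 slope_post = slope_post, improvement = improvement,
                 window = window, reason = reason),
            class = "activation_call")
}

#' @export
print.activation_call <- function(x, ...) {
  if (is.na(x$time))
    cat(sprintf("activation_call '%s' (%s): no call (%s)\n", x$cell_id,
                x$channel, x$reason %||% "unspecified"))
  else
    cat(sprintf("activation_call '%s' (%s): t = %g min (slope %.3g -> %.3g, improvement %.2f)\n",
                x$cell_id, x$channel, x$time, x$slope_pre, x$slope_post,
                x$improvement))
  invisible(x)
}

## shared smooth -> window -> one-change machinery.  The noise scale is
## estimated from the raw (unsmoothed) trace via robust first differences:
## smoothing correlates the noise, so residuals of the fit on the smoothed
## window would understate it badly.
fit_window_change <- function(values, idx_window, config, raw = values) {
  v <- values[idx_window]
  fit <- detect_slope_changes(v, max_changes = 1, min_seg = config$min_seg)
  cost0 <- fit$cost_by_k[1L]
  improvement <- if (is.finite(cost0) && cost0 > 0)
    1 - fit$cost_by_k[2L] / cost0 else 0
  seg <- fit$segments
  sigma <- stats::mad(diff(raw[!is.na(raw)])) / sqrt(2)
  ## accumulated slope change over the post segment, in noise units
  dslope <- abs(seg$slope[2L] - seg$slope[1L]) *
    (seg$end[2L] - seg$start[2L])
  snr <- if (sigma <= 0) Inf else dslope / sigma
  list(fit = fit, improvement = improvement, snr = snr)
}

#' Call mitotic activation from a sensor readout trace
#'
#' Runs the rate-change pipeline (smooth, crop to the pre-peak window,
#' one-change piecewise-linear fit) and reports the initial point of the
#' rapid rise: the first timepoint of the post-change segment, on the
#' acquisition grid.  If the fitted change is a slope decrease, the window
#' overran the true peak into a post-mitotic plateau (the trace maximum was
#' a late noise excursion); the window is then re-anchored at the detected
#' break and the fit repeated once.  Traces without an accepted slope
#' increase (no rapid switch, or missing values in the analysis window)
#' yield a null call with the reason recorded.
#'
#' @param trace a `"sensor_readout_trace"`, or a numeric vector (then
#'   `time` must be given).
#' @param config an [activation_config()].
#' @param time acquisition times, required when `trace` is a bare vector.
#' @param cell_id,channel identifiers for bare-vector input.
#' @return an `"activation_call"` object; `$time` is `NA` for null calls.
#' @examples
#' t <- seq(0, 150, by = 5)
#' y <- c(rep(1, 21), 1 + 0.2 * seq_len(10))
#' call_activation(y, time = t)$time  # first rising frame after t = 100
#' @export
call_activation <- function(trace, config = activation_config(),
                            time = NULL, cell_id = "cell",
                            channel = "readout") {
  if (inherits(trace, "sensor_readout_trace")) {
    time <- trace$time
    cell_id <- trace$cell_id
    channel <- trace$kind
    values <- trace$readout
  } else values <- trace
  if (is.null(time) || length(time) != length(values))
    stop("'time' must accompany the trace values", call. = FALSE)
  if (length(values) <= config$n_before + 1L)
    return(new_activation_call(cell_id, channel,
                               reason = "trace shorter than analysis window"))
  sm <- smooth_trace(values, config$smooth_window, config$polyorder)
  if (all(is.na(sm)))
    return(new_activation_call(cell_id, channel, reason = "all values missing"))
  crop <- suppressWarnings(crop_prepeak(sm, config$n_before))
  idx <- crop$offset:crop$peak_index
  if (anyNA(sm[idx]))
    return(new_activation_call(cell_id, channel,
                               reason = "missing values in analysis window"))
  if (length(idx) < 2 * config$min_seg)
    return(new_activation_call(cell_id, channel,
                               reason = "analysis window too short"))
  wc <- fit_window_change(sm, idx, config, raw = values)
  fit <- wc$fit
  s_pre <- fit$segments$slope[1L]
  s_post <- fit$segments$slope[2L]
  cp_abs <- crop$offset + fit$changepoints[1L] - 1L
  ## a fitted slope *decrease* means the window ran past the true peak
  ## into a plateau (the trace maximum was a late noise excursion);
  ## re-anchor the window at the detected break and re-fit once
  if (s_post < s_pre && cp_abs > 2 * config$min_seg) {
    peak2 <- cp_abs
    lo2 <- max(1L, peak2 - config$n_before)
    idx2 <- lo2:peak2
    if (length(idx2) >= 2 * config$min_seg && !anyNA(sm[idx2])) {
      wc2 <- fit_window_change(sm, idx2, config, raw = values)
      s_pre2 <- wc2$fit$segments$slope[1L]
      s_post2 <- wc2$fit$segments$slope[2L]
      if (s_post2 > s_pre2 && s_post2 > 0 &&
          wc2$improvement >= config$min_improvement &&
          wc2$snr >= config$min_snr) {
        cp2 <- lo2 + wc2$fit$changepoints[1L] - 1L
        return(new_activation_call(cell_id, channel, time = time[cp2],
                                   index = cp2, slope_pre = s_pre2,
                                   slope_post = s_post2,
                                   improvement = wc2$improvement,
                                   window = c(lo2, peak2)))
      }
    }
  }
  if (!(s_post > s_pre) || s_post <= 0)
    return(new_activation_call(cell_id, channel,
                               reason = "no slope increase (post <= pre)"))
  if (wc$improvement < config$min_improvement)
    return(new_activation_call(cell_id, channel,
                               reason = sprintf("rate change not significant (improvement %.2f < %.2f)",
                                                wc$improvement,
                                                config$min_improvement)))
  if (wc$snr < config$min_snr)
    return(new_activation_call(cell_id, channel,
                               reason = sprintf("rate change below noise (SNR %.1f < %.1f)",
                                                wc$snr, config$min_snr)))
  new_activation_call(cell_id, channel, time = time[cp_abs], index = cp_abs,
                      slope_pre = s_pre, slope_post = s_post,
                      improvement = wc$improvement,
                      window = c(crop$offset, crop$peak_index))
}

#' Call the onset of nuclear cyclin export
#'
#' Applies the slope-change pipeline to a nuclear concentration trace around
#' its maximum: the accepted change is from rise to decline, and the
#' reported time (first point of the declining segment) marks export onset.
#'
#' @param values nuclear mean-intensity trace (e.g. the cyclin channel).
#' @param time acquisition times.
#' @param config an [activation_config()]; `n_before` points before and
#'   `n_after` points after the peak form the analysis window.
#' @param n_after points retained after the peak.
#' @param cell_id identifier.
#' @return an `"activation_call"` (channel `"export"`).
#' @export
call_export_onset <- function(values, time, config = activation_config(),
                              n_after = 6, cell_id = "cell") {
  sm <- smooth_trace(values, config$smooth_window, config$polyorder)
  peak <- which.max(sm)
  lo <- max(1L, peak - config$n_before)
  hi <- min(length(sm), peak + n_after)
  idx <- lo:hi
  if (anyNA(sm[idx]))
    return(new_activation_call(cell_id, "export",
                               reason = "missing values in analysis window"))
  if (length(idx) < 2 * config$min_seg)
    return(new_activation_call(cell_id, "export",
                               reason = "analysis window too short"))
  wc <- fit_window_change(sm, idx, config, raw = values)
  fit <- wc$fit
  s_pre <- fit$segments$slope[1L]
  s_post <- fit$segments$slope[2L]
  cp_abs <- lo + fit$changepoints[1L] - 1L
  if (!(s_post < s_pre) || s_post >= 0)
    return(new_activation_call(cell_id, "export",
                               reason = "no decline after the peak"))
  if (wc$improvement < config$min_improvement || wc$snr < config$min_snr)
    return(new_activation_call(cell_id, "export",
                               reason = "rate change not significant"))
  new_activation_call(cell_id, "export", time = time[cp_abs], index = cp_abs,
                      slope_pre = s_pre, slope_post = s_post,
                      improvement = wc$improvement, window = c(lo, hi))
}

#' Call the stop of cell elongation
#'
#' Same smooth/window/one-change pipeline as [call_activation()], anchored
#' at the end of the length trace rather than at a readout peak: growth is
#' linear, then flat.  Accepted when the pre-change slope is positive and
#' the post-change slope is close to zero (below a quarter of the
#' pre-change slope in magnitude).
#'
#' @param values cell length trace (um).
#' @param time acquisition times (min).
#' @param config an [activation_config()].
#' @param cell_id identifier.
#' @return an `"activation_call"` (channel `"length"`).
#' @export
call_elongation_stop <- function(values, time, config = activation_config(),
                                 cell_id = "cell") {
  sm <- smooth_trace(values, config$smooth_window, config$polyorder)
  n <- length(sm)
  lo <- max(1L, n - config$n_before)
  idx <- lo:n
  if (anyNA(sm[idx]) || length(idx) < 2 * config$min_seg)
    return(new_activation_call(cell_id, "length",
                               reason = "analysis window unusable"))
  wc <- fit_window_change(sm, idx, config, raw = values)
  fit <- wc$fit
  s_pre <- fit$segments$slope[1L]
  s_post <- fit$segments$slope[2L]
  cp_abs <- lo + fit$changepoints[1L] - 1L
  if (!(s_pre > 0) || abs(s_post) > 0.25 * abs(s_pre))
    return(new_activation_call(cell_id, "length",
                               reason = "no growth plateau detected"))
  if (wc$improvement < config$min_improvement || wc$snr < config$min_snr)
    return(new_activation_call(cell_id, "length",
                               reason = "rate change not significant"))
  new_activation_call(cell_id, "length", time = time[cp_abs], index = cp_abs,
                      slope_pre = s_pre, slope_post = s_post,
                      improvement = wc$improvement, window = c(lo, n))
}

#' Paired nuclear-to-cytoplasmic activation delays
#'
#' Matches nuclear and cytoplasmic activation calls by cell, computes the
#' per-cell delay `t_cytoplasmic - t_nuclear`, and summarises the cohort
#' with a histogram whose bin width equals the acquisition interval
#' (left-closed bins, right-open except for the last).  Unmatched or null
#' calls are excluded and counted.
#'
#' @param nuclear_calls,cytoplasmic_calls lists of `"activation_call"`s.
#' @param bin_width histogram bin width (min); use the acquisition interval.
#' @return object of class `"delay_summary"`: `delays` (per-cell
#'   data.frame), `mean`, `sd`, `n`, `n_excluded`, `breaks`, `counts`.
#' @export
paired_delays <- function(nuclear_calls, cytoplasmic_calls, bin_width = 5) {
  as_df <- function(calls) {
    do.call(rbind, lapply(calls, function(cl)
      data.frame(cell_id = cl$cell_id, time = cl$time,
                 stringsAsFactors = FALSE)))
  }
  dn <- as_df(nuclear_calls)
  dc <- as_df(cytoplasmic_calls)
  m <- merge(dn, dc, by = "cell_id", suffixes = c("_nuclear", "_cytoplasmic"))
  total <- max(nrow(dn), nrow(dc))
  ok <- !is.na(m$time_nuclear) & !is.na(m$time_cytoplasmic)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no matched cell with both nuclear and cytoplasmic calls",
         call. = FALSE)
  delay <- m$time_cytoplasmic - m$time_nuclear
  lo <- floor(min(delay) / bin_width) * bin_width
  hi <- ceiling(max(delay) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  ## left-closed, right-open except the last bin
  counts <- vapply(seq_len(length(breaks) - 1L), function(b) {
    if (b < length(breaks) - 1L)
      sum(delay >= breaks[b] & delay < breaks[b + 1L])
    else
      sum(delay >= breaks[b] & delay <= breaks[b + 1L])
  }, integer(1))
  structure(list(
    delays = data.frame(cell_id = m$cell_id, t_nuclear = m$time_nuclear,
                        t_cytoplasmic = m$time_cytoplasmic, delay = delay,
                        stringsAsFactors = FALSE),
    mean = mean(delay), sd = stats::sd(delay), n = length(delay),
    n_excluded = total - length(delay),
    breaks = breaks, counts = counts, bin_width = bin_width),
    class = "delay_summary")
}

#' @export
print.delay_summary <- function(x, ...) {
  cat(sprintf("delay_summary: n = %d cells (excluded %d), mean %.2f min, sd %.2f min\n",
              x$n, x$n_excluded, x$mean, x$sd))
  cat("  histogram (bin width", x$bin_width, "min):\n")
  lab <- sprintf("[%g,%g%s", utils::head(x$breaks, -1), x$breaks[-1],
                 c(rep(")", length(x$counts) - 1L), "]"))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' @export
plot.delay_summary <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = sprintf("%g", utils::head(x$breaks, -1)),
                    xlab = "nuclear-to-cytoplasmic delay (min)",
                    ylab = "cells", ...)
  invisible(x)
}

#' Delay between two normalised curves at a threshold level
#'
#' Min--max normalises both traces and measures the time difference between
#' their first upward crossings of `level` (linear interpolation between
#' samples): cytoplasmic crossing minus nuclear crossing.
#'
#' @param nuclear,cytoplasmic `"sensor_readout_trace"`s or numeric vectors
#'   sharing `time`.
#' @param level fraction of the normalised peak, in (0, 1].
#' @param time acquisition times for bare-vector input.
#' @return the delay in minutes, with attributes `t_nuclear` and
#'   `t_cytoplasmic`; `NA` (with attribute `reason`) when either trace never
#'   reaches the level.
#' @examples
#' t <- seq(0, 100, by = 5)
#' threshold_delay(pmin(t / 50, 1), pmin(pmax(t - 7, 0) / 50, 1),
#'                 level = 0.75, time = t)
#' @export
threshold_delay <- function(nuclear, cytoplasmic, level = 0.75, time = NULL) {
  stop_if_not_scalar(level, "level", lower = 1e-9, upper = 1)
  get <- function(tr) {
    if (inherits(tr, "sensor_readout_trace")) list(t = tr$time, x = tr$readout)
    else list(t = time, x = tr)
  }
  a <- get(nuclear); b <- get(cytoplasmic)
  if (is.null(a$t) || is.null(b$t))
    stop("'time' must accompany bare numeric traces", call. = FALSE)
  xa <- normalize_minmax(a$x)
  xb <- normalize_minmax(b$x)
  ta <- first_crossing(a$t, xa, level)
  tb <- first_crossing(b$t, xb, level)
  if (is.na(ta) || is.na(tb)) {
    out <- NA_real_
    attr(out, "reason") <- "level never reached on at least one trace"
    return(out)
  }
  out <- tb - ta
  attr(out, "t_nuclear") <- ta
  attr(out, "t_cytoplasmic") <- tb
  out
}

#' Rate-change time of a phosphosite timecourse
#'
#' One-change piecewise-linear fit over the full (uncropped) normalised
#' timecourse.  The change is reported at the midpoint between the last
#' pre-change and the first post-change timepoint: the break occurred
#' somewhere inside that sampling interval, and the midpoint is never more
#' than half a grid step from it.
#'
#' @param values phosphorylation values (>= 8 timepoints).
#' @param time normalised cell-cycle times; defaults to an even grid on
#'   `[0, 1]`.
#' @param min_seg minimum segment length.
#' @return change time (normalised units).
#' @export
site_change_time <- function(values, time = NULL, min_seg = 3) {
  if (length(values) < 8)
    stop("site timecourse needs >= 8 timepoints", call. = FALSE)
  time <- time %||% seq(0, 1, length.out = length(values))
  cp <- detect_slope_changes(values, max_changes = 1,
                             min_seg = min_seg)$changepoints[1L]
  (time[cp - 1L] + time[cp]) / 2
}
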