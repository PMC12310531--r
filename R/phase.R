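#' Build a single-cell phase orbit
#'
#' Pairs a cyclin--CDK concentration trace with an activity readout trace
#' point by point (acquisition order), after light Savitzky--Golay smoothing
#' of each axis and optional per-axis min--max normalisation.  The orbit is
#' the path the cell traces in (concentration, activity) space over the
#' cycle.
#'
#' @param concentration,activity numeric traces on a shared time grid, or a
#'   `"compartment_series"` / `"sensor_readout_trace"` pair.
#' @param time shared acquisition times (bare-vector input).
#' @param normalize logical of length 2 (concentration axis, activity axis).
#' @param smooth_window,polyorder smoothing settings; `smooth_window = 0`
#'   disables smoothing.
#' @param cell_id,compartment identifiers.
#' @return object of class `"phase_orbit"` with fields `x` (concentration),
#'   `y` (activity), `time`, `dt`, `normalized`, `cell_id`, `compartment`.
#' @export
build_orbit <- function(concentration, activity, time = NULL,
                        normalize = c(TRUE, TRUE),
                        smooth_window = 7, polyorder = 2,
                        cell_id = "cell", compartment = "nucleus") {
  if (inherits(concentration, "compartment_series")) {
    time <- concentration$time
    cell_id <- concentration$cell_id
    concentration <- if (compartment == "nucleus")
      concentration$nuclear_mean else concentration$cytoplasmic_mean
  }
  if (inherits(activity, "sensor_readout_trace")) {
    if (!is.null(time) && !isTRUE(all.equal(time, activity$time)))
      stop("concentration and activity traces are on different time grids; offending times: ",
           paste(utils::head(setdiff(activity$time, time)), collapse = ", "),
           call. = FALSE)
    time <- activity$time
    activity <- activity$readout
  }
  if (is.null(time)) stop("'time' is required", call. = FALSE)
  if (length(concentration) != length(activity))
    stop("traces differ in length", call. = FALSE)
  if (length(concentration) < 10)
    stop("an orbit needs >= 10 points", call. = FALSE)
  x <- concentration; y <- activity
  if (smooth_window > 0) {
    x <- smooth_trace(x, smooth_window, polyorder)
    y <- smooth_trace(y, smooth_window, polyorder)
  }
  if (normalize[1]) x <- normalize_minmax(x)
  if (normalize[2]) y <- normalize_minmax(y)
  structure(list(x = x, y = y, time = time,
                 dt = if (length(time) > 1) diff(time)[1] else NA_real_,
                 normalized = normalize, cell_id = cell_id,
                 compartment = compartment),
            class = "phase_orbit")
}

#' Enclosed orbit area (shoelace)
#'
#' Absolute value of the signed shoelace sum over the polygon obtained by
#' closing the orbit (last point joined to the first).  Self-intersecting
#' orbits are allowed; their lobes cancel in sign before the absolute value
#' is taken.
#'
#' @param orbit a `"phase_orbit"` (or list with `x`, `y`).
#' @return area in the product units of the two axes.
#' @examples
#' sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' orbit_area(sq)  # 1
#' @export
orbit_area <- function(orbit) {
  x <- orbit$x; y <- orbit$y
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("an area needs >= 3 points", call. = FALSE)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  n <- length(x)
  abs(sum(xs[1:n] * ys[2:(n + 1)] - xs[2:(n + 1)] * ys[1:n])) / 2
}

#' Orbit size, thresholds, hysteresis and collapse metrics
#'
#' Quantifies a normalised phase orbit.  The ascending branch is the path up
#' to the activity maximum, the descending branch the rest.  The activation
#' threshold is the concentration at the largest single-step activity
#' increase on the ascending branch (taken at the step's first point); the
#' deactivation concentration is measured symmetrically at the largest
#' single-step drop on the descending branch.  The hysteresis gap is the
#' maximum, over concentration bins of width `bin_width` populated by both
#' branches, of the difference between descending and ascending mean
#' activity.  Linearity is the total-least-squares index
#' `1 - lambda_2 / lambda_1` from the principal components of the point
#' cloud (1 for a perfect line, 0 for an isotropic cloud).  An orbit is
#' classified `"collapsed"` when its area falls below `area_collapse` and
#' its linearity exceeds `r2_collapse`.
#'
#' @param orbit a `"phase_orbit"` normalised on both axes.
#' @param bin_width concentration bin width for the gap (normalised units).
#' @param area_collapse,r2_collapse collapse classification thresholds.
#' @return object of class `"orbit_metrics"`: `area`,
#'   `activation_threshold`, `deactivation_concentration`,
#'   `hysteresis_gap`, `linearity_r2`, `regime` (`"orbit"`/`"collapsed"`),
#'   `partial` (TRUE when a branch was empty).
#' @export
orbit_metrics <- function(orbit, bin_width = 0.05,
                          area_collapse = 0.05, r2_collapse = 0.95) {
  stopifnot(inherits(orbit, "phase_orbit"))
  ok <- !is.na(orbit$x) & !is.na(orbit$y)
  x <- orbit$x[ok]; y <- orbit$y[ok]
  area <- orbit_area(list(x = x, y = y))

  ## total-least-squares linearity from the PCA eigenvalues
  M <- cbind(x, y)
  ev <- eigen(stats::cov(M), symmetric = TRUE, only.values = TRUE)$values
  r2 <- if (ev[1] <= 0) 1 else max(0, min(1, 1 - ev[2] / ev[1]))

  i_max <- which.max(y)
  asc <- seq_len(i_max)
  desc <- if (i_max < length(y)) seq.int(i_max + 1L, length(y)) else integer(0)
  partial <- length(asc) < 2 || length(desc) < 2

  act_thr <- if (length(asc) >= 2) {
    j <- which.max(diff(y[asc]))
    x[asc[j]]
  } else NA_real_
  deact <- if (length(desc) >= 2) {
    j <- which.min(diff(y[desc]))
    x[desc[j]]
  } else NA_real_

  gap <- 0
  if (!partial) {
    edges <- seq(0, 1 + bin_width, by = bin_width)
    ba <- findInterval(x[asc], edges, rightmost.closed = TRUE)
    bd <- findInterval(x[desc], edges, rightmost.closed = TRUE)
    shared <- intersect(unique(ba), unique(bd))
    if (length(shared)) {
      gaps <- vapply(shared, function(b)
        abs(mean(y[desc][bd == b]) - mean(y[asc][ba == b])), numeric(1))
      gap <- max(gaps)
    }
  }
  regime <- if (area < area_collapse && r2 > r2_collapse) "collapsed" else "orbit"
  structure(list(area = area, activation_threshold = act_thr,
                 deactivation_concentration = deact, hysteresis_gap = gap,
                 linearity_r2 = r2, regime = regime, partial = partial,
                 cell_id = orbit$cell_id, compartment = orbit$compartment),
            class = "orbit_metrics")
}

#' @export
print.orbit_metrics <- function(x, ...) {
  cat(sprintf("orbit_metrics '%s' (%s): regime %s%s\n", x$cell_id,
              x$compartment, x$regime, if (x$partial) " [partial]" else ""))
  cat(sprintf("  area %.3f, hysteresis gap %.3f, linearity R2 %.3f\n",
              x$area, x$hysteresis_gap, x$linearity_r2))
  cat(sprintf("  activation threshold %.3f, deactivation concentration %.3f\n",
              x$activation_threshold, x$deactivation_concentration))
  invisible(x)
}

#' @export
print.phase_orbit <- function(x, ...) {
  cat(sprintf("phase_orbit '%s' (%s): %d points, dt = %g min\n", x$cell_id,
              x$compartment, length(x$x), x$dt))
  invisible(x)
}

#' @export
plot.phase_orbit <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "o", pch = 16, cex = 0.6,
                 xlab = "cyclin-CDK concentration",
                 ylab = "activity readout", ...)
  invisible(x)
}

#' Cyclin concentration at an activation call
#'
#' Background-subtracted compartment mean intensity at the called
#' activation timepoint.
#'
#' @param series a [compartment_series()] (e.g. the cyclin channel).
#' @param call an `"activation_call"` (non-null).
#' @param background scalar background (AU).
#' @param compartment which compartment mean to read.
#' @return concentration (AU).
#' @export
cyclin_at_activation <- function(series, call, background = 0,
                                 compartment = c("nucleus", "cytoplasm")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(series, "compartment_series"),
            inherits(call, "activation_call"))
  if (is.na(call$time))
    stop("activation call is null", call. = FALSE)
  i <- match(call$time, series$time)
  if (is.na(i))
    stop(sprintf("activation time %g min is not a timepoint of the series",
                 call$time), call. = FALSE)
  v <- if (compartment == "nucleus") series$nuclear_mean[i]
       else series$cytoplasmic_mean[i]
  if (is.na(v))
    stop("series has a gap at the activation timepoint", call. = FALSE)
  v - background
}
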