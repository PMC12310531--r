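#' Top-fraction compartment mean estimator
#'
#' Estimates nuclear and cytoplasmic mean intensities from an unsegmented
#' in-cell pixel set: the brightest `frac` of pixels proxy the nucleus
#' (the nucleus occupies roughly that fraction of the projected cell area
#' and is the brightest region for nuclear-enriched markers), the remainder
#' proxy the cytoplasm.  `k = max(1, round(frac * N))` pixels are taken,
#' with ties at the cut broken towards brighter-or-equal pixels in stable
#' input order.
#'
#' @param pixels numeric vector of in-cell pixel intensities (length >= 20).
#' @param frac nuclear area fraction, in (0, 1); default 0.15.
#' @return named numeric vector with `nuclear_mean`, `cytoplasmic_mean`,
#'   `whole_mean`.
#' @examples
#' px <- c(rep(10, 3), rep(2, 17))
#' compartment_means_topfrac(px)  # nuclear 10, cytoplasmic 2, whole 3.2
#' @export
compartment_means_topfrac <- function(pixels, frac = 0.15) {
  if (!is.numeric(pixels) || length(pixels) < 20)
    stop("at least 20 in-cell pixels are required for top-fraction estimation",
         call. = FALSE)
  stop_if_not_scalar(frac, "frac", lower = 1e-9, upper = 1 - 1e-9)
  n <- length(pixels)
  k <- max(1L, as.integer(floor(frac * n + 0.5)))  # half-up rounding
  ord <- order(pixels, decreasing = TRUE)          # stable for ties
  top <- ord[seq_len(k)]
  c(nuclear_mean = mean(pixels[top]),
    cytoplasmic_mean = mean(pixels[-top]),
    whole_mean = mean(pixels))
}

#' Mask-based compartment mean estimator
#'
#' @param pixels numeric vector of in-cell pixel intensities.
#' @param nuclear_idx integer indices into `pixels` forming the nuclear mask;
#'   must be non-empty and strictly smaller than the cell pixel set.
#' @return named numeric vector with `nuclear_mean`, `cytoplasmic_mean`,
#'   `whole_mean`.
#' @export
compartment_means_masked <- function(pixels, nuclear_idx) {
  if (!is.numeric(pixels) || length(pixels) < 1)
    stop("'pixels' must be a non-empty numeric vector", call. = FALSE)
  nuclear_idx <- unique(as.integer(nuclear_idx))
  if (length(nuclear_idx) == 0)
    stop("nuclear mask is empty", call. = FALSE)
  if (any(nuclear_idx < 1L | nuclear_idx > length(pixels)))
    stop("nuclear mask indices outside the cell pixel set", call. = FALSE)
  if (length(nuclear_idx) >= length(pixels))
    stop("nuclear mask must be strictly smaller than the cell mask (empty cytoplasmic complement)",
         call. = FALSE)
  c(nuclear_mean = mean(pixels[nuclear_idx]),
    cytoplasmic_mean = mean(pixels[-nuclear_idx]),
    whole_mean = mean(pixels))
}

#' Build a compartment mean-intensity series from a long trace table
#'
#' @param traces long-format table as produced by [sample_traces()] (columns
#'   `cell_id`, `time_min`, `channel`, `nuclear_mean`, `cytoplasmic_mean`,
#'   `whole_mean`).
#' @param cell_id,channel which series to extract.
#' @param background optional scalar background (AU) carried with the series.
#' @param method provenance tag, `"top_fraction"` or `"mask"`.
#' @return object of class `"compartment_series"`.
#' @export
compartment_series <- function(traces, cell_id, channel, background = 0,
                               method = c("top_fraction", "mask")) {
  method <- match.arg(method)
  need <- c("cell_id", "time_min", "channel", "nuclear_mean",
            "cytoplasmic_mean", "whole_mean")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("trace table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- traces$cell_id == cell_id & traces$channel == channel
  if (!any(rows))
    stop(sprintf("no rows for cell '%s', channel '%s'", cell_id, channel),
         call. = FALSE)
  d <- traces[rows, , drop = FALSE]
  d <- d[order(d$time_min), , drop = FALSE]
  structure(list(cell_id = cell_id, channel = channel,
                 time = d$time_min, nuclear_mean = d$nuclear_mean,
                 cytoplasmic_mean = d$cytoplasmic_mean,
                 whole_mean = d$whole_mean,
                 background = background, method = method),
            class = "compartment_series")
}

#' @export
print.compartment_series <- function(x, ...) {
  cat(sprintf("compartment_series '%s' channel '%s': %d timepoints (%s method)\n",
              x$cell_id, x$channel, length(x$time), x$method))
  invisible(x)
}

#' Sensor readout (compartment intensity ratio)
#'
#' Background-subtracts both compartment means and forms the translocation
#' readout: cytoplasmic / nuclear for `NucCDK` (the sensor leaves the
#' nucleus when phosphorylated) and nuclear / cytoplasmic for `CytCDK` and
#' `CytCDKv2` (the sensor enters it), so every readout increases with CDK
#' activity.  Timepoints whose denominator is non-positive after subtraction
#' become missing values with a warning reporting the count; gaps are
#' propagated, never interpolated.
#'
#' @param series a [compartment_series()].
#' @param kind sensor kind; defaults to the series' channel label.
#' @param background scalar background to subtract (AU); defaults to the
#'   series' stored background.
#' @return object of class `"sensor_readout_trace"` with fields `cell_id`,
#'   `kind`, `time`, `readout`, `normalization` (`"raw"`).
#' @examples
#' tr <- data.frame(cell_id = "c", time_min = 0, channel = "NucCDK",
#'                  nuclear_mean = 8, cytoplasmic_mean = 4, whole_mean = 4.6)
#' sensor_readout(compartment_series(tr, "c", "NucCDK"), background = 2)
#' @export
sensor_readout <- function(series, kind = NULL, background = NULL) {
  stopifnot(inherits(series, "compartment_series"))
  kind <- kind %||% series$channel
  if (!kind %in% c("NucCDK", "CytCDK", "CytCDKv2"))
    stop("unknown sensor kind: ", kind, call. = FALSE)
  b <- background %||% series$background %||% 0
  nuc <- series$nuclear_mean - b
  cyt <- series$cytoplasmic_mean - b
  if (kind == "NucCDK") {
    num <- cyt; den <- nuc
  } else {
    num <- nuc; den <- cyt
  }
  bad <- !is.na(den) & den <= 0
  readout <- num / den
  readout[bad] <- NA_real_
  if (any(bad))
    warning(sprintf("%d timepoint(s) had non-positive denominator after background subtraction and were set to NA",
                    sum(bad)), call. = FALSE)
  structure(list(cell_id = series$cell_id, kind = kind,
                 time = series$time, readout = readout,
                 normalization = "raw"),
            class = "sensor_readout_trace")
}

#' Min--max normalise a readout trace
#'
#' Maps the readout onto `[0, 1]` via `(x - min) / (max - min)`, ignoring
#' missing values.  Idempotent; invariant to positive affine rescaling.
#'
#' @param trace a `"sensor_readout_trace"` (or bare numeric vector).
#' @return the same type of object with `normalization = "minmax"`.
#' @export
normalize_minmax <- function(trace) {
  x <- if (inherits(trace, "sensor_readout_trace")) trace$readout else trace
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0)
    stop("min-max normalization is undefined for a constant trace",
         call. = FALSE)
  y <- (x - rng[1]) / (rng[2] - rng[1])
  if (inherits(trace, "sensor_readout_trace")) {
    trace$readout <- y
    trace$normalization <- "minmax"
    trace
  } else y
}

#' @export
print.sensor_readout_trace <- function(x, ...) {
  cat(sprintf("sensor_readout_trace '%s' (%s, %s): %d timepoints, %d missing\n",
              x$cell_id, x$kind, x$normalization, length(x$readout),
              sum(is.na(x$readout))))
  invisible(x)
}

#' @export
plot.sensor_readout_trace <- function(x, ...) {
  graphics::plot(x$time, x$readout, type = "l", xlab = "time (min)",
                 ylab = sprintf("%s readout (%s)", x$kind, x$normalization),
                 ...)
  invisible(x)
}
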