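## Residual sum of squares of an independent straight-line fit on each
## candidate segment, computed in O(1) from cumulative sums.
segment_cost_table <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  cs <- function(v) c(0, cumsum(v))
  Sx <- cs(x); Sy <- cs(y); Sxx <- cs(x * x); Sxy <- cs(x * y); Syy <- cs(y * y)
  function(i, j) {
    m <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]; sy <- Sy[j + 1] - Sy[i]
    sxx <- Sxx[j + 1] - Sxx[i]; sxy <- Sxy[j + 1] - Sxy[i]
    syy <- Syy[j + 1] - Syy[i]
    cxx <- sxx - sx * sx / m
    cxy <- sxy - sx * sy / m
    cyy <- syy - sy * sy / m
    rss <- cyy - if (cxx > 0) cxy * cxy / cxx else 0
    max(rss, 0)
  }
}

## OLS line fit on a segment (slope/intercept in index coordinates)
segment_line <- function(y, i, j) {
  x <- i:j
  fit <- stats::lm.fit(cbind(1, x), y[i:j])
  c(intercept = unname(fit$coefficients[1]),
    slope = unname(fit$coefficients[2]),
    rss = sum(fit$residuals^2))
}

#' Exact piecewise-linear slope change-point detection
#'
#' Segments a trace into contiguous pieces, each fitted by its own
#' independent straight line, minimising the total residual sum of squares
#' by exact dynamic programming.  With `penalty = NULL` exactly
#' `max_changes` change points are placed; with a penalty, the number of
#' changes (from 0 to `max_changes`) is chosen by the penalised cost
#' `RSS + n_changes * penalty`.  Change points are reported as the index of
#' the **first point of the post-change segment**, in increasing order.
#'
#' @param values numeric trace (no missing values).
#' @param max_changes maximum (or, without penalty, exact) number of changes.
#' @param penalty cost penalty per change, or `NULL` for a fixed count.  Use
#'   [slope_change_penalty()] for a data-driven default.
#' @param min_seg minimum segment length (>= 3; a line needs two points and
#'   a third guards degenerate fits).
#' @return object of class `"slope_changes"`: `changepoints` (integer
#'   vector, possibly empty), `n_changes`, `cost` (total RSS),
#'   `cost_by_k` (RSS for 0..`max_changes` changes, `NA` if infeasible),
#'   `segments` (data.frame with `start`, `end`, `intercept`, `slope`,
#'   `rss`), `penalty`.
#' @examples
#' y <- c(rep(0, 6), 1:6)
#' detect_slope_changes(y, max_changes = 1)$changepoints  # 7
#' @export
detect_slope_changes <- function(values, max_changes = 1, penalty = NULL,
                                 min_seg = 3) {
  if (anyNA(values)) stop("trace contains missing values", call. = FALSE)
  n <- length(values)
  if (min_seg < 3) stop("min_seg must be >= 3", call. = FALSE)
  if (n < 2 * min_seg)
    stop(sprintf("trace too short to segment: need >= %d points, got %d",
                 2 * min_seg, n), call. = FALSE)
  max_changes <- as.integer(max_changes)
  kmax <- min(max_changes, n %/% min_seg - 1L)
  cost <- segment_cost_table(values)

  ## D[k+1, j]: minimal RSS of points 1..j using k changes
  D <- matrix(Inf, nrow = kmax + 1L, ncol = n)
  B <- matrix(NA_integer_, nrow = kmax + 1L, ncol = n)
  for (j in min_seg:n) D[1L, j] <- cost(1L, j)
  if (kmax >= 1L) for (k in seq_len(kmax)) {
    for (j in seq.int((k + 1L) * min_seg, n)) {
      best <- Inf; arg <- NA_integer_
      ## ties prefer the later breakpoint (the longest pre-change segment)
      for (i in seq.int(k * min_seg + 1L, j - min_seg + 1L)) {
        v <- D[k, i - 1L] + cost(i, j)
        if (v <= best) { best <- v; arg <- i }
      }
      D[k + 1L, j] <- best
      B[k + 1L, j] <- arg
    }
  }
  cost_by_k <- D[, n]
  cost_by_k[!is.finite(cost_by_k)] <- NA_real_

  if (is.null(penalty)) {
    k_use <- kmax
  } else {
    stop_if_not_scalar(penalty, "penalty", lower = 0)
    pen_cost <- cost_by_k + penalty * (0:kmax)
    k_use <- which.min(pen_cost) - 1L   # first minimum: prefer fewer changes
  }

  cps <- integer(0)
  j <- n
  k <- k_use
  while (k >= 1L) {
    i <- B[k + 1L, j]
    cps <- c(i, cps)
    j <- i - 1L
    k <- k - 1L
  }
  starts <- c(1L, cps)
  ends <- c(cps - 1L, n)
  segs <- do.call(rbind, lapply(seq_along(starts), function(s) {
    ln <- segment_line(values, starts[s], ends[s])
    data.frame(start = starts[s], end = ends[s],
               intercept = ln["intercept"], slope = ln["slope"],
               rss = ln["rss"], row.names = NULL)
  }))
  structure(list(changepoints = cps, n_changes = k_use,
                 cost = cost_by_k[k_use + 1L], cost_by_k = cost_by_k,
                 segments = segs, penalty = penalty,
                 min_seg = min_seg, n = n),
            class = "slope_changes")
}

#' Data-driven change penalty
#'
#' `2 * sigma^2 * log(n)` with the noise variance estimated from first
#' differences (`var(diff(y)) / 2`), a BIC-like default for use when the
#' number of changes is not fixed in advance.
#'
#' @param values numeric trace.
#' @return penalty in squared trace units.
#' @export
slope_change_penalty <- function(values) {
  sigma2 <- stats::var(diff(values)) / 2
  2 * sigma2 * log(length(values))
}

#' @export
print.slope_changes <- function(x, ...) {
  cat(sprintf("slope_changes: %d change point(s) on %d points, total RSS %.4g\n",
              x$n_changes, x$n, x$cost))
  if (x$n_changes > 0)
    cat("  post-change segment starts at index:",
        paste(x$changepoints, collapse = ", "), "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Crop a trace to the pre-peak analysis window
#'
#' Restricts a readout trace to `[argmax - n_before, argmax]`, the window in
#' which the mitotic rate change occurs; the earliest maximum is used on
#' ties.  If the peak sits closer than `n_before` points to the start, the
#' window is clipped to the trace start with a warning.
#'
#' @param values numeric trace.
#' @param n_before points retained before the peak (10--15 is sensible;
#'   default 12).
#' @return list with `values` (cropped), `offset` (index in the original
#'   trace of the first cropped point), `peak_index` (in the original trace).
#' @export
crop_prepeak <- function(values, n_before = 12) {
  n <- length(values)
  n_before <- as.integer(n_before)
  if (n <= n_before + 1L)
    stop("trace must be longer than n_before + 1", call. = FALSE)
  peak <- which.max(values)            # earliest maximum on ties
  start <- peak - n_before
  if (start < 1L) {
    warning("peak closer than n_before points to the trace start; window clipped",
            call. = FALSE)
    start <- 1L
  }
  list(values = values[start:peak], offset = start, peak_index = peak)
}
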