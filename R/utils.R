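`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

#' First upward crossing of a level, with linear interpolation
#'
#' Returns the interpolated time at which `values` first reaches or exceeds
#' `level` from below, or `NA_real_` if the level is never reached.
#'
#' @param time numeric vector of times (strictly increasing).
#' @param values numeric vector, same length as `time`.
#' @param level numeric scalar.
#' @return interpolated crossing time in the units of `time`, or `NA_real_`.
#' @keywords internal
#' @noRd
first_crossing <- function(time, values, level) {
  idx <- which(values >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(time[1L])
  y0 <- values[i - 1L]; y1 <- values[i]
  if (!is.finite(y0) || y1 == y0) return(time[i])
  time[i - 1L] + (level - y0) / (y1 - y0) * (time[i] - time[i - 1L])
}

## median-preserving lognormal jitter with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sigma))
}
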