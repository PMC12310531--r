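#' Savitzky--Golay smoothing with truncated end windows
#'
#' Least-squares local-polynomial smoothing: each point is replaced by the
#' value at its own position of a degree-`polyorder` polynomial fitted to the
#' `window` points centred on it.  At the trace ends the window is truncated
#' to the available points (and the local degree reduced if fewer points than
#' coefficients remain).  Polynomials of degree `<= polyorder` are
#' reproduced exactly; missing values are propagated and excluded from
#' neighbouring fits.
#'
#' @param values numeric vector.
#' @param window odd window length, `> polyorder` and `<= length(values)`.
#' @param polyorder local polynomial degree.
#' @return smoothed numeric vector, same length as `values`.
#' @examples
#' smooth_trace(c(1, 4, 9, 16, 25, 36, 49), window = 5, polyorder = 2)
#' @export
smooth_trace <- function(values, window = 5, polyorder = 2) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  n <- length(values)
  if (window %% 2 != 1) stop("'window' must be odd", call. = FALSE)
  if (window > n) stop("'window' must be <= trace length", call. = FALSE)
  if (window <= polyorder)
    stop("'window' must be > 'polyorder'", call. = FALSE)
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    lo <- max(1L, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    idx <- idx[!is.na(values[idx])]
    deg <- min(polyorder, length(idx) - 1L)
    if (deg < 0L) next
    x <- idx - i                       # centre at the evaluation point
    X <- outer(x, 0:deg, `^`)
    beta <- qr.coef(qr(X), values[idx])
    out[i] <- beta[1L]                 # polynomial value at x = 0
  }
  out
}
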