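#' Fit exponential decay kinetics after an acute perturbation
#'
#' Fits `y(t) = sum_i a_i * exp(-k_i * t)` with one or two components by
#' nonlinear least squares from multiple starting points (rates log-spaced
#' over `[1e-2, 1]` per minute, amplitudes from the initial value).  The
#' global half-life is the time at which the fitted curve reaches half of
#' its fitted initial value: `ln 2 / k` exactly for one component, solved
#' numerically for two.
#'
#' @param values decaying trace, starting at/after the perturbation.
#' @param time times since the perturbation (min); defaults to the sample
#'   index.
#' @param n_components 1 or 2.
#' @return object of class `"decay_fit"`: `amplitudes`, `rates` (min^-1,
#'   sorted decreasing), `half_life` (min), `residual_norm`, `fitted`,
#'   `n_components`.
#' @examples
#' t <- seq(0, 30, by = 3)
#' fit_decay(exp(-t * log(2) / 4), time = t)$half_life  # 4
#' @export
fit_decay <- function(values, time = NULL, n_components = 1) {
  time <- time %||% (seq_along(values) - 1)
  ok <- !is.na(values)
  y <- values[ok]; t <- time[ok]
  if (length(y) < 6) stop("decay fit needs >= 6 points", call. = FALSE)
  if (y[length(y)] >= y[1])
    stop("trace is not decreasing overall; is it cropped to the decay?",
         call. = FALSE)
  if (!n_components %in% c(1, 2))
    stop("n_components must be 1 or 2", call. = FALSE)
  y0 <- max(y[1], .Machine$double.eps)
  rate_grid <- 10^seq(-2, 0, length.out = 5)
  best <- NULL
  try_fit <- function(start, fml) {
    tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y), start = start,
                        lower = rep(1e-8, length(start)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (n_components == 1) {
    for (k0 in rate_grid) {
      f <- try_fit(list(a1 = y0, k1 = k0), y ~ a1 * exp(-k1 * t))
      if (!is.null(f)) {
        rss <- sum(stats::residuals(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
  } else {
    for (k_fast in rate_grid) for (k_slow in rate_grid) {
      if (k_slow > k_fast) next
      f <- try_fit(list(a1 = 0.6 * y0, k1 = k_fast,
                        a2 = 0.4 * y0, k2 = k_slow),
                   y ~ a1 * exp(-k1 * t) + a2 * exp(-k2 * t))
      if (!is.null(f)) {
        rss <- sum(stats::residuals(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
  }
  if (is.null(best))
    stop("decay fit failed to converge from any starting point",
         call. = FALSE)
  cf <- stats::coef(best$fit)
  if (n_components == 1) {
    a <- unname(cf["a1"]); k <- unname(cf["k1"])
    hl <- log(2) / k
    amps <- a; rates <- k
  } else {
    amps <- unname(c(cf["a1"], cf["a2"]))
    rates <- unname(c(cf["k1"], cf["k2"]))
    ord <- order(rates, decreasing = TRUE)
    amps <- amps[ord]; rates <- rates[ord]
    curve0 <- sum(amps)
    g <- function(tt) sum(amps * exp(-rates * tt)) - curve0 / 2
    upper <- log(2) / min(rates) * 4 + 1
    hl <- stats::uniroot(g, c(0, upper), tol = 1e-10)$root
  }
  structure(list(amplitudes = amps, rates = rates, half_life = hl,
                 residual_norm = sqrt(best$rss),
                 fitted = stats::fitted(best$fit), time = t,
                 n_components = n_components),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit (%d component%s): half-life %.3g min\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$half_life))
  for (i in seq_along(x$rates))
    cat(sprintf("  a%d = %.4g, k%d = %.4g /min (t1/2 = %.3g min)\n",
                i, x$amplitudes[i], i, x$rates[i], log(2) / x$rates[i]))
  cat(sprintf("  residual norm %.3g\n", x$residual_norm))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  stats::setNames(c(object$amplitudes, object$rates),
                  c(paste0("a", seq_along(object$amplitudes)),
                    paste0("k", seq_along(object$rates))))
}

#' Fit a four-parameter logistic dose--response curve
#'
#' `y(d) = floor + (ceiling - floor) / (1 + (d / IC50)^hill)`, fitted by
#' nonlinear least squares.  Doses are in inhibitor concentration units
#' (nM); dose zero is allowed (it contributes the ceiling directly, and is
#' plotted on a floor-shifted log axis).  The fit is invariant to a common
#' rescaling of all doses: the IC50 scales by the same factor.
#'
#' @param doses inhibitor concentrations (>= 5, spanning the transition).
#' @param readouts sensor readouts at those doses.
#' @return object of class `"dose_response_fit"`: `floor`, `ceiling`,
#'   `ic50`, `hill`, `residual_norm`, `fitted`.
#' @export
fit_dose_response <- function(doses, readouts) {
  if (length(doses) < 5 || length(doses) != length(readouts))
    stop("need >= 5 dose/readout pairs", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  rng <- range(readouts)
  if (diff(rng) <= 0 ||
      abs(readouts[which.max(doses)] - readouts[which.min(doses)]) <
        0.1 * diff(rng))
    stop("no dose-response transition within the dose range", call. = FALSE)
  pos <- doses[doses > 0]
  start <- list(fl = rng[1], ce = rng[2],
                lic50 = log(stats::median(pos)), hill = 1)
  fml <- y ~ fl + (ce - fl) / (1 + (d / exp(lic50))^hill)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(d = doses, y = readouts),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("dose-response fit failed: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  fl <- unname(cf["fl"]); ce <- unname(cf["ce"])
  if (fl > ce) {  # normalise orientation so floor < ceiling
    tmp <- fl; fl <- ce; ce <- tmp
  }
  structure(list(floor = fl, ceiling = ce, ic50 = exp(unname(cf["lic50"])),
                 hill = unname(cf["hill"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit), doses = doses),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose_response_fit: IC50 = %.4g nM, Hill slope = %.3g\n",
              x$ic50, x$hill))
  cat(sprintf("  floor %.4g, ceiling %.4g, residual norm %.3g\n",
              x$floor, x$ceiling, x$residual_norm))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(floor = object$floor, ceiling = object$ceiling, ic50 = object$ic50,
    hill = object$hill)
}

#' Lag from a perturbation to the first detectable readout change
#'
#' The lag is the first time after `t_perturb` at which the readout departs
#' from its pre-perturbation mean by more than `criterion` times the
#' trace's dynamic range, located by linear interpolation, minus
#' `t_perturb`.
#'
#' @param values readout trace spanning the perturbation.
#' @param time acquisition times (min).
#' @param t_perturb perturbation time (min); >= 3 samples must precede it.
#' @param criterion fractional departure threshold (default 0.01).
#' @param baseline_points number of pre-perturbation samples averaged for
#'   the baseline (all of them if fewer).
#' @param direction `"any"` counts departures in either direction;
#'   `"down"`/`"up"` count only departures below/above the baseline, which
#'   is the right reading when the perturbation has a known response
#'   direction and the trace may still carry its pre-perturbation trend
#'   (an inherited rise is not a response to an inhibition).
#' @return lag in minutes, or `NA` (attribute `reason`) if the readout
#'   never departs.
#' @export
response_lag <- function(values, time, t_perturb, criterion = 0.01,
                         baseline_points = 3,
                         direction = c("any", "down", "up")) {
  direction <- match.arg(direction)
  pre <- which(time <= t_perturb)
  if (length(pre) < 3)
    stop("need >= 3 pre-perturbation points", call. = FALSE)
  base_idx <- utils::tail(pre, baseline_points)
  baseline <- mean(values[base_idx], na.rm = TRUE)
  rng <- diff(range(values, na.rm = TRUE))
  if (rng <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "readout never departs from baseline (flat trace)"
    return(out)
  }
  thr <- criterion * rng
  post <- which(time >= t_perturb)
  dep <- switch(direction,
                any = abs(values[post] - baseline),
                down = baseline - values[post],
                up = values[post] - baseline)
  tc <- first_crossing(time[post], dep, thr)
  if (is.na(tc)) {
    out <- NA_real_
    attr(out, "reason") <- "readout never departs from baseline"
    return(out)
  }
  max(0, tc - t_perturb)
}
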