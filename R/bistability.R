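#' Settle the activity ODE at a clamped cyclin level
#'
#' Integrates `dA/dt = iota * k25(A) * (C - A) - kw(A) * A` for one
#' compartment with the total cyclin--CDK concentration `C` clamped, until
#' the derivative is below `tol` (steady state) or `t_max` is exceeded.
#' In AF mode the activity is identically `C`.
#'
#' @param params an [oscillator_params()] object.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param C clamped total concentration (AU).
#' @param A0 initial activity (AU), clipped to `[0, C]`.
#' @param iota catalytic activity fraction.
#' @param tol derivative magnitude defining steady state (AU min^-1).
#' @param dt integration step (min).
#' @param t_max settling time budget (min).
#' @return list with `A` (settled activity), `converged` (logical),
#'   `t` (time used).
#' @export
settle_activity <- function(params, compartment = c("nucleus", "cytoplasm"),
                            C, A0 = 0, iota = 1,
                            tol = 1e-10, dt = 0.1, t_max = 5000) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(params, "oscillator_params"))
  stop_if_not_scalar(C, "C", lower = 0)
  if (params$mode == "AF")
    return(list(A = C, converged = TRUE, t = 0))
  sw <- if (compartment == "nucleus") params$nuc else params$cyt
  h <- params$h
  f <- function(A) {
    Ah <- max(A, 0)^h
    kw <- sw$kw_lo + (sw$kw_hi - sw$kw_lo) * sw$K_w^h / (sw$K_w^h + Ah)
    k25 <- sw$k25_lo + (sw$k25_hi - sw$k25_lo) * Ah / (sw$K_25^h + Ah)
    iota * k25 * (C - A) - kw * A
  }
  A <- min(max(A0, 0), C)
  t <- 0
  repeat {
    d1 <- f(A)
    if (abs(d1) < tol) return(list(A = A, converged = TRUE, t = t))
    if (t >= t_max) return(list(A = A, converged = FALSE, t = t))
    k2 <- f(A + dt / 2 * d1)
    k3 <- f(A + dt / 2 * k2)
    k4 <- f(A + dt * k3)
    A <- A + dt / 6 * (d1 + 2 * k2 + 2 * k3 + k4)
    A <- min(max(A, 0), C)
    t <- t + dt
  }
}

#' Clamped-cyclin bistability scan
#'
#' For each clamped cyclin--CDK concentration on `cyclin_grid`, settles the
#' compartment's activity ODE from a low (`A0 = 0`) and a high (`A0 = C`)
#' initial condition.  Concentrations where the two settled branches
#' disagree form the bistable window; the ascending switching threshold is
#' the upper edge of that window (where the low-activity branch disappears)
#' and the descending threshold is its lower edge (where the high-activity
#' branch disappears).  Thresholds are reported at the midpoint between the
#' last bistable grid point and its monostable neighbour, so they are stable
#' to grid refinement within one grid step.
#'
#' @inheritParams settle_activity
#' @param cyclin_grid strictly increasing concentrations (AU), length >= 10.
#' @param branch_tol activity difference that marks branch disagreement (AU).
#' @return object of class `"cyclin_scan"`: data.frame `branches` with
#'   columns `C`, `A_low`, `A_high`, `bistable`, `converged`, plus
#'   `ascending_threshold`, `descending_threshold` and `hysteresis_width`
#'   (AU; 0 when no bistable window).
#' @examples
#' sc <- clamped_cyclin_scan(default_wt(), "nucleus",
#'                           cyclin_grid = seq(0.1, 2, by = 0.1))
#' sc$hysteresis_width
#' @export
clamped_cyclin_scan <- function(params, compartment = c("nucleus", "cytoplasm"),
                                cyclin_grid = seq(0.05, 2, by = 0.05),
                                iota = 1, branch_tol = 1e-3,
                                tol = 1e-10, dt = 0.1, t_max = 5000) {
  compartment <- match.arg(compartment)
  if (length(cyclin_grid) < 10 || any(diff(cyclin_grid) <= 0))
    stop("cyclin_grid must be strictly increasing with >= 10 points",
         call. = FALSE)
  n <- length(cyclin_grid)
  A_low <- A_high <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    C <- cyclin_grid[i]
    lo <- settle_activity(params, compartment, C, A0 = 0, iota = iota,
                          tol = tol, dt = dt, t_max = t_max)
    hi <- settle_activity(params, compartment, C, A0 = C, iota = iota,
                          tol = tol, dt = dt, t_max = t_max)
    A_low[i] <- lo$A; A_high[i] <- hi$A
    conv[i] <- lo$converged && hi$converged
  }
  bistable <- (A_high - A_low) > branch_tol & conv
  if (any(bistable)) {
    i_first <- which(bistable)[1L]
    i_last <- which(bistable)[sum(bistable)]
    asc <- if (i_last < n)
      (cyclin_grid[i_last] + cyclin_grid[i_last + 1L]) / 2
    else cyclin_grid[n]
    desc <- if (i_first > 1L)
      (cyclin_grid[i_first] + cyclin_grid[i_first - 1L]) / 2
    else cyclin_grid[1L]
    width <- asc - desc
  } else {
    asc <- desc <- NA_real_
    width <- 0
  }
  structure(list(
    branches = data.frame(C = cyclin_grid, A_low = A_low, A_high = A_high,
                          bistable = bistable, converged = conv),
    compartment = compartment, mode = params$mode, iota = iota,
    ascending_threshold = asc, descending_threshold = desc,
    hysteresis_width = width), class = "cyclin_scan")
}

#' @export
print.cyclin_scan <- function(x, ...) {
  cat(sprintf("cyclin_scan (%s, %s mode): %d grid points\n",
              x$compartment, x$mode, nrow(x$branches)))
  if (x$hysteresis_width > 0)
    cat(sprintf("  bistable window [%.3g, %.3g] AU, hysteresis width %.3g AU\n",
                x$descending_threshold, x$ascending_threshold,
                x$hysteresis_width))
  else cat("  monostable over the scanned range (hysteresis width 0)\n")
  if (any(!x$branches$converged))
    cat(sprintf("  %d non-convergent grid point(s) flagged\n",
                sum(!x$branches$converged)))
  invisible(x)
}

#' @export
plot.cyclin_scan <- function(x, ...) {
  b <- x$branches
  graphics::matplot(b$C, cbind(b$A_low, b$A_high), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "clamped cyclin-CDK (AU)", ylab = "settled activity (AU)",
                    ...)
  graphics::legend("topleft", c("from low", "from high"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  if (x$hysteresis_width > 0)
    graphics::abline(v = c(x$descending_threshold, x$ascending_threshold),
                     lty = 3, col = "grey50")
  invisible(x)
}
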