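#' Simulate a single-cell two-compartment cyclin--CDK trajectory
#'
#' Integrates the two-compartment oscillator with fixed-step fourth-order
#' Runge--Kutta.  Nuclear cyclin--CDK is synthesised while the cell grows and
#' its active fraction is governed by a Y15 feedback switch per compartment;
#' once the effective nuclear activity `iota * A_n` crosses `theta_act`, the
#' complex is exported to the cytoplasm after a lag `tau_exp` (carrying its
#' phosphostate, so exported molecules arrive active), and once the effective
#' cytoplasmic activity crosses `theta_apc` the APC/C triggers degradation
#' after `tau_apc`.  Translocation sensors ride on top of the activities
#' without feeding back.  Threshold crossings are located by linear
#' interpolation between integration steps.
#'
#' @param params an [oscillator_params()] object.
#' @param sensors a list of [sensor_params()] objects (may be empty).
#' @param protocol a [protocol_free_run()]-style inhibitor schedule.
#' @param duration total simulated time (min).
#' @param dt_sim integration step (min); the default 0.1 resolves the fastest
#'   sensor kinetics by more than an order of magnitude.
#' @param seed integer recorded with the trajectory (the trajectory itself is
#'   deterministic; measurement noise is added at the sampling stage).
#' @param cell_id identifier carried into exported tables.
#' @return an object of class `"cdk_trajectory"`: a list with `time`,
#'   `state` (matrix with columns `iota`, `C_n`, `C_c`, `A_n`, `A_c`, `L` and
#'   per-sensor `p_<kind>`, `f_<kind>`), `events` (data.frame with columns
#'   `cycle`, `event`, `time`), `params`, `sensors`, `seed`, `cell_id`.
#' @examples
#' tr <- simulate_trajectory(default_wt(), default_sensors(),
#'                           duration = 200, dt_sim = 0.1)
#' subset(tr$events, event == "activation_nuclear")
#' @export
simulate_trajectory <- function(params, sensors = default_sensors(),
                                protocol = protocol_free_run(),
                                duration = 260, dt_sim = 0.1,
                                seed = 1L, cell_id = "cell_1") {
  stopifnot(inherits(params, "oscillator_params"))
  if (inherits(sensors, "sensor_params")) sensors <- list(sensors)
  stopifnot(all(vapply(sensors, inherits, TRUE, "sensor_params")))
  stop_if_not_scalar(duration, "duration", lower = 1e-9)
  stop_if_not_scalar(dt_sim, "dt_sim", lower = 1e-9)

  n_steps <- as.integer(round(duration / dt_sim))
  times <- seq(0, by = dt_sim, length.out = n_steps + 1L)
  iota_t <- protocol_iota(protocol, times)
  ns <- length(sensors)
  af <- params$mode == "AF"
  w <- params$phi_n / (1 - params$phi_n)
  h <- params$h
  nuc <- params$nuc; cyt <- params$cyt

  kw <- function(sw, A) {
    Ah <- pmax(A, 0)^h
    sw$kw_lo + (sw$kw_hi - sw$kw_lo) * sw$K_w^h / (sw$K_w^h + Ah)
  }
  k25 <- function(sw, A) {
    Ah <- pmax(A, 0)^h
    sw$k25_lo + (sw$k25_hi - sw$k25_lo) * Ah / (sw$K_25^h + Ah)
  }

  ## state vector layout: C_n, C_c, A_n, A_c, then p_1..p_ns, f_1..f_ns
  ip <- if (ns) 4L + seq_len(ns) else integer(0)
  iff <- if (ns) 4L + ns + seq_len(ns) else integer(0)
  k_on <- vapply(sensors, `[[`, 0, "k_on")
  k_off <- vapply(sensors, `[[`, 0, "k_off")
  k_loc <- vapply(sensors, `[[`, 0, "k_loc")
  tau_loc <- vapply(sensors, function(s) s$tau_loc %||% 0, 0)
  if (any(tau_loc > 0 & tau_loc < dt_sim))
    stop("sensor tau_loc must be 0 or >= dt_sim", call. = FALSE)
  f_lo <- vapply(sensors, `[[`, 0, "f_min")
  f_hi <- vapply(sensors, `[[`, 0, "f_max")
  nuc_sensor <- vapply(sensors, function(s) s$kind == "NucCDK", TRUE)
  host_nuc <- vapply(sensors, function(s) s$host == "nucleus", TRUE)
  f_target <- function(p) ifelse(nuc_sensor, f_hi - (f_hi - f_lo) * p,
                                 f_lo + (f_hi - f_lo) * p)

  deriv <- function(x, iota, growing, kx, kd, p_del = NULL) {
    C_n <- x[1L]; C_c <- x[2L]; A_n <- x[3L]; A_c <- x[4L]
    dC_n <- params$k_syn * growing - (kx + kd) * C_n
    dC_c <- w * kx * C_n - kd * C_c
    if (af) {
      dA_n <- dC_n
      dA_c <- dC_c
    } else {
      dA_n <- iota * k25(nuc, A_n) * (C_n - A_n) - kw(nuc, A_n) * A_n -
        (kx + kd) * A_n
      dA_c <- iota * k25(cyt, A_c) * (C_c - A_c) - kw(cyt, A_c) * A_c +
        w * kx * A_n - kd * A_c
    }
    out <- c(dC_n, dC_c, dA_n, dA_c)
    if (ns) {
      p <- x[ip]; f <- x[iff]
      a <- iota * ifelse(host_nuc, A_n, A_c)
      dp <- k_on * a * (1 - p) - k_off * p
      ## sensors with a transport transit delay respond to the
      ## phosphostate as it was tau_loc minutes ago
      p_eff <- if (is.null(p_del)) p else ifelse(is.na(p_del), p, p_del)
      df <- k_loc * (f_target(p_eff) - f)
      out <- c(out, dp, df)
    }
    out
  }

  ## linear interpolation of recorded sensor phosphostate at time s
  p_history <- function(s) {
    vapply(seq_len(ns), function(j) {
      if (tau_loc[j] == 0) return(NA_real_)
      sj <- max(s - tau_loc[j], 0)
      r <- sj / dt_sim + 1
      r0 <- floor(r)
      w1 <- r - r0
      v0 <- state[r0, 6L + j]
      if (w1 == 0 || r0 + 1 > nrow(state)) v0
      else v0 * (1 - w1) + state[r0 + 1L, 6L + j] * w1
    }, numeric(1))
  }

  ## start the cell at its G2 quasi-steady state: activity on the low
  ## branch at C_n0 under the protocol's initial inhibitor level, sensors
  ## at their steady state for that activity (no artificial t = 0
  ## transient; the trace minimum is the true G2 baseline)
  init_state <- function() {
    x <- numeric(4L + 2L * ns)
    x[1L] <- params$C_n0
    iota0 <- iota_t[1L]
    x[3L] <- if (af) params$C_n0 else
      settle_activity(params, "nucleus", C = params$C_n0, A0 = 0,
                      iota = iota0, tol = 1e-12, dt = dt_sim)$A
    if (ns) {
      a0 <- iota0 * ifelse(host_nuc, x[3L], x[4L])
      p0 <- k_on * a0 / (k_on * a0 + k_off)
      x[ip] <- p0
      x[iff] <- f_target(p0)
    }
    x
  }

  x <- init_state()
  state <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 6L + 2L * ns)
  colnames(state) <- c("iota", "C_n", "C_c", "A_n", "A_c", "L",
                       if (ns) paste0("p_", vapply(sensors, `[[`, "", "kind")),
                       if (ns) paste0("f_", vapply(sensors, `[[`, "", "kind")))
  L <- params$L0
  cycle <- 1L
  events <- list()
  add_event <- function(ev, tt) {
    events[[length(events) + 1L]] <<- data.frame(
      cycle = cycle, event = ev, time = tt, stringsAsFactors = FALSE)
  }
  ## per-cycle pending switch times
  t_act_n <- NA_real_; t_act_c <- NA_real_
  t_export <- NA_real_; t_deg <- NA_real_; t_stop <- NA_real_
  t_reset <- NA_real_

  record <- function(i, x, iota) {
    state[i, ] <<- c(iota, x[1:4], L, if (ns) x[c(ip, iff)])
  }
  record(1L, x, iota_t[1L])

  for (i in seq_len(n_steps)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    iota0 <- iota_t[i]; iota1 <- iota_t[i + 1L]
    iota_mid <- protocol_iota(protocol, (t0 + t1) / 2)
    growing <- is.na(t_stop) || t0 < t_stop
    kx <- if (!is.na(t_export) && t0 >= t_export &&
              t0 < t_export + params$exp_duration) params$k_exp_max else 0
    kd <- params$k_deg_basal +
      if (!is.na(t_deg) && t0 >= t_deg) params$k_deg_max else 0

    any_delay <- ns > 0 && any(tau_loc > 0)
    pd0 <- if (any_delay) p_history(t0) else NULL
    pdm <- if (any_delay) p_history(t0 + dt_sim / 2) else NULL
    pd1 <- if (any_delay) p_history(t1) else NULL
    k1 <- deriv(x, iota0, growing, kx, kd, pd0)
    k2 <- deriv(x + dt_sim / 2 * k1, iota_mid, growing, kx, kd, pdm)
    k3 <- deriv(x + dt_sim / 2 * k2, iota_mid, growing, kx, kd, pdm)
    k4 <- deriv(x + dt_sim * k3, iota1, growing, kx, kd, pd1)
    dx <- dt_sim / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

    if (!all(is.finite(dx)))
      stop(sprintf(
        "integration produced a non-finite state at step %d (t = %g min); check parameter magnitudes",
        i, t0), call. = FALSE)
    ## change per step relative to each variable's characteristic scale
    ## (the system's cyclin scale for concentration-like states, full
    ## scale for fractions)
    conc_scale <- max(x[1L], 0.5)
    scale <- c(rep(conc_scale, 4L), rep(1, 2L * ns))
    rel <- max(abs(dx) / scale)
    if (rel > 0.2)
      stop(sprintf(
        "dt_sim = %g min is too coarse: state change of %.0f%% in one step at t = %g min; retry with dt_sim <= %g",
        dt_sim, 100 * rel, t0, signif(dt_sim * 0.2 / rel, 2)), call. = FALSE)

    x_new <- x + dx
    ## guard tiny integrator overshoot so state invariants hold exactly
    x_new[1:2] <- pmax(x_new[1:2], 0)
    x_new[3:4] <- pmin(pmax(x_new[3:4], 0), x_new[1:2])
    if (ns) {
      x_new[ip] <- pmin(pmax(x_new[ip], 0), 1)
      x_new[iff] <- pmin(pmax(x_new[iff], 0), 1)
    }

    ## growth (stop may fall inside the step)
    if (growing) {
      t_grow_end <- if (is.na(t_stop)) t1 else min(t1, t_stop)
      L <- L + params$r_len * max(0, t_grow_end - t0)
    }

    ## threshold crossings on effective activity, interpolated within step
    e_n0 <- iota0 * x[3L]; e_n1 <- iota1 * x_new[3L]
    e_c0 <- iota0 * x[4L]; e_c1 <- iota1 * x_new[4L]
    cross <- function(e0, e1, th) {
      if (e0 < th && e1 >= th) t0 + (th - e0) / (e1 - e0) * dt_sim else NA_real_
    }
    if (is.na(t_act_n)) {
      tc <- cross(e_n0, e_n1, params$theta_act)
      if (!is.na(tc)) {
        t_act_n <- tc
        add_event("activation_nuclear", tc)
        if (params$mode != "HPM" && params$k_exp_max > 0) {
          t_export <- tc + params$tau_exp
          add_event("export_onset", t_export)
          if (is.finite(params$exp_duration))
            add_event("export_end", t_export + params$exp_duration)
        }
        t_stop <- tc + params$tau_stop
        add_event("elongation_stop", t_stop)
      }
    }
    ## the cytoplasmic activation threshold is the amount-equivalent of
    ## theta_act: the same number of active molecules, diluted into the
    ## cytoplasmic volume, corresponds to a concentration scaled by
    ## phi_n / (1 - phi_n)
    if (is.na(t_act_c)) {
      tc <- cross(e_c0, e_c1, params$theta_act * w)
      if (!is.na(tc)) {
        t_act_c <- tc
        add_event("activation_cytoplasmic", tc)
      }
    }
    if (is.na(t_deg)) {
      tc <- cross(e_c0, e_c1, params$theta_apc)
      if (!is.na(tc)) {
        t_deg <- tc + params$tau_apc
        add_event("degradation_onset", t_deg)
        if (is.finite(params$reset_interval))
          t_reset <- t_deg + params$reset_interval
      }
    }

    x <- x_new

    ## division/reset for free-running multi-cycle protocols
    if (!is.na(t_reset) && t1 >= t_reset) {
      add_event("division_reset", t1)
      x <- init_state()
      L <- params$L0
      cycle <- cycle + 1L
      t_act_n <- t_act_c <- t_export <- t_deg <- t_stop <- t_reset <- NA_real_
    }

    record(i + 1L, x, iota1)
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(cycle = integer(0), event = character(0), time = numeric(0))
  structure(list(time = times, state = state, events = ev,
                 params = params, sensors = sensors,
                 protocol = protocol, dt_sim = dt_sim,
                 seed = seed, cell_id = cell_id),
            class = "cdk_trajectory")
}

#' Look up a ground-truth event time
#'
#' @param traj a `"cdk_trajectory"`.
#' @param event one of `"activation_nuclear"`, `"activation_cytoplasmic"`,
#'   `"export_onset"`, `"degradation_onset"`, `"elongation_stop"`,
#'   `"division_reset"`.
#' @param cycle which cycle's event (default first).
#' @return event time in minutes, or `NA_real_` if the event did not occur.
#' @export
event_time <- function(traj, event, cycle = 1L) {
  stopifnot(inherits(traj, "cdk_trajectory"))
  hit <- traj$events$event == event & traj$events$cycle == cycle
  if (!any(hit)) NA_real_ else traj$events$time[which(hit)[1L]]
}

#' Sample a trajectory onto the acquisition grid as a measurement table
#'
#' Converts the mechanistic state into per-channel compartment mean
#' intensities on the imaging grid, adding multiplicative lognormal
#' measurement noise.  The sensor channels report the sensor's nuclear and
#' cytoplasmic concentrations (`f / phi_n` and `(1 - f) / (1 - phi_n)` for a
#' unit sensor pool); the `cyclin` channel reports `C_n` and `C_c`.  The
#' whole-cell mean is the volume-weighted average of the two (noisy)
#' compartment means, as it would be when measured from the same pixels.
#'
#' @param traj a `"cdk_trajectory"`.
#' @param dt_img acquisition interval (min); must be an integer multiple of
#'   the simulation step.
#' @param noise_cv multiplicative measurement noise CV per timepoint.
#' @param gain,background detector gain and offset applied to every mean.
#' @param seed integer seed for the measurement noise.
#' @return a long-format data.frame with columns `cell_id`, `time_min`,
#'   `channel`, `nuclear_mean`, `cytoplasmic_mean`, `whole_mean`,
#'   `length_um`.
#' @export
sample_traces <- function(traj, dt_img = 5, noise_cv = 0.03,
                          gain = 1, background = 0, seed = NULL) {
  stopifnot(inherits(traj, "cdk_trajectory"))
  ratio <- dt_img / traj$dt_sim
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("dt_img must be an integer multiple of dt_sim", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- seq(1L, length(traj$time), by = as.integer(round(ratio)))
  tt <- traj$time[idx]
  phi <- traj$params$phi_n
  st <- traj$state[idx, , drop = FALSE]
  chans <- unname(c(vapply(traj$sensors, `[[`, "", "kind"), "cyclin"))
  out <- vector("list", length(chans))
  for (k in seq_along(chans)) {
    ch <- chans[k]
    if (ch == "cyclin") {
      nuc <- st[, "C_n"]; cyt <- st[, "C_c"]
    } else {
      f <- st[, paste0("f_", ch)]
      nuc <- f / phi
      cyt <- (1 - f) / (1 - phi)
    }
    nuc <- gain * nuc * rlnorm_cv(length(idx), noise_cv) + background
    cyt <- gain * cyt * rlnorm_cv(length(idx), noise_cv) + background
    out[[k]] <- data.frame(
      cell_id = traj$cell_id, time_min = tt, channel = ch,
      nuclear_mean = nuc, cytoplasmic_mean = cyt,
      whole_mean = phi * nuc + (1 - phi) * cyt,
      length_um = st[, "L"], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.cdk_trajectory <- function(x, ...) {
  cat(sprintf("cdk_trajectory '%s' [%s]: %g min at dt = %g min, %d sensor(s)\n",
              x$cell_id, x$params$mode, max(x$time), x$dt_sim,
              length(x$sensors)))
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  } else cat("events: none\n")
  invisible(x)
}

#' @export
plot.cdk_trajectory <- function(x, what = c("activity", "cyclin", "sensors"),
                                ...) {
  what <- match.arg(what)
  cols <- switch(what,
                 activity = c("A_n", "A_c"),
                 cyclin = c("C_n", "C_c"),
                 sensors = grep("^f_", colnames(x$state), value = TRUE))
  if (!length(cols)) stop("nothing to plot for '", what, "'", call. = FALSE)
  graphics::matplot(x$time, x$state[, cols, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)", ylab = what, ...)
  graphics::legend("topleft", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n")
  ev <- x$events
  if (nrow(ev)) graphics::abline(v = ev$time, col = "grey70", lty = 3)
  invisible(x)
}
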