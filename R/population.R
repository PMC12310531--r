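#' Default cell-to-cell variability map
#'
#' Lognormal coefficients of variation applied to the kinetic rates when a
#' population is drawn.  Thresholds, lags, half-saturations and geometry are
#' held fixed: between-cell variability in timing is dominated by rate
#' variation, which is what the generator emulates.
#'
#' @param cv coefficient of variation applied to every listed rate.
#' @return named numeric vector of CVs.
#' @export
default_variability <- function(cv = 0.10) {
  rates <- c("k_syn", "k_exp_max", "k_deg_max", "r_len",
             "nuc.kw_lo", "nuc.kw_hi", "nuc.k25_lo", "nuc.k25_hi",
             "cyt.kw_lo", "cyt.kw_hi", "cyt.k25_lo", "cyt.k25_hi")
  stats::setNames(rep(cv, length(rates)), rates)
}

perturb_params <- function(params, variability) {
  p <- params
  for (nm in names(variability)) {
    cv <- variability[[nm]]
    if (cv <= 0) next
    fac <- rlnorm_cv(1L, cv)
    if (grepl("^nuc\\.", nm)) {
      f <- sub("^nuc\\.", "", nm); p$nuc[[f]] <- p$nuc[[f]] * fac
    } else if (grepl("^cyt\\.", nm)) {
      f <- sub("^cyt\\.", "", nm); p$cyt[[f]] <- p$cyt[[f]] * fac
    } else {
      p[[nm]] <- p[[nm]] * fac
    }
  }
  ## keep switch-rate ordering invariants after jitter
  p$nuc$kw_hi <- max(p$nuc$kw_hi, p$nuc$kw_lo)
  p$nuc$k25_hi <- max(p$nuc$k25_hi, p$nuc$k25_lo)
  p$cyt$kw_hi <- max(p$cyt$kw_hi, p$cyt$kw_lo)
  p$cyt$k25_hi <- max(p$cyt$k25_hi, p$cyt$k25_lo)
  p
}

#' Simulate a population of cells
#'
#' Draws per-cell parameters lognormally around the supplied defaults,
#' simulates each cell with [simulate_trajectory()], and samples measurement
#' tables on the acquisition grid with multiplicative lognormal noise.
#' Cells whose integration fails are recorded in `$failed` with the error
#' message, never silently dropped.
#'
#' @param params an [oscillator_params()] object (per-cell defaults).
#' @param sensors list of [sensor_params()].
#' @param n_cells number of cells.
#' @param variability named CV map as in [default_variability()].
#' @param noise measurement noise CV passed to [sample_traces()].
#' @param seed integer seed governing all randomness.
#' @param protocol inhibitor schedule shared by all cells.
#' @param duration,dt_sim,dt_img simulation and acquisition grids (min).
#' @param division_margin each cell's exported trace ends this many minutes
#'   after its degradation onset (emulating traces that span birth to
#'   division); `Inf` keeps the full duration.  Cells without degradation
#'   keep the full duration.
#' @return an object of class `"cdk_population"`: list with `trajectories`
#'   (per-cell `"cdk_trajectory"`), `traces` (long measurement table),
#'   `truth` (per-cell ground-truth event times, with a `completed` flag
#'   marking cells whose mitotic exit fell within the acquisition), `failed`
#'   (data.frame of failures) and the call settings.
#' @examples
#' pop <- simulate_population(default_wt(), n_cells = 3, seed = 1,
#'                            duration = 200, dt_sim = 0.1)
#' head(pop$truth)
#' @export
simulate_population <- function(params = default_wt(),
                                sensors = default_sensors(),
                                n_cells = 100,
                                variability = default_variability(),
                                noise = 0.03, seed = 1L,
                                protocol = protocol_free_run(),
                                duration = 260, dt_sim = 0.1, dt_img = 5,
                                division_margin = 12) {
  stopifnot(n_cells >= 1)
  if (any(unlist(variability) < 0)) stop("CVs must be >= 0", call. = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  trajs <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  traces <- vector("list", n_cells)
  failed <- list()
  ev_names <- c("activation_nuclear", "activation_cytoplasmic",
                "export_onset", "degradation_onset", "elongation_stop")
  for (i in seq_len(n_cells)) {
    id <- sprintf("cell_%03d", i)
    set.seed(cell_seeds[i])
    p_i <- perturb_params(params, variability)
    tr <- tryCatch(
      simulate_trajectory(p_i, sensors, protocol, duration = duration,
                          dt_sim = dt_sim, seed = cell_seeds[i],
                          cell_id = id),
      error = function(e) e)
    if (inherits(tr, "error")) {
      failed[[length(failed) + 1L]] <-
        data.frame(cell_id = id, reason = conditionMessage(tr),
                   stringsAsFactors = FALSE)
      next
    }
    trajs[[i]] <- tr
    tt <- lapply(ev_names, function(ev) event_time(tr, ev))
    t_deg <- tt[[4L]]
    truth[[i]] <- data.frame(cell_id = id,
                             stats::setNames(tt, ev_names),
                             completed = !is.na(t_deg) && t_deg <= duration,
                             stringsAsFactors = FALSE)
    tri <- sample_traces(tr, dt_img = dt_img, noise_cv = noise)
    t_deg <- event_time(tr, "degradation_onset")
    if (is.finite(division_margin) && !is.na(t_deg))
      tri <- tri[tri$time_min <= t_deg + division_margin, , drop = FALSE]
    traces[[i]] <- tri
  }
  keep <- !vapply(trajs, is.null, TRUE)
  structure(list(
    trajectories = trajs[keep],
    truth = if (any(keep)) do.call(rbind, truth[keep]) else NULL,
    traces = if (any(keep)) do.call(rbind, traces[keep]) else NULL,
    failed = if (length(failed)) do.call(rbind, failed) else
      data.frame(cell_id = character(0), reason = character(0)),
    params = params, sensors = sensors, protocol = protocol,
    variability = variability, noise = noise, seed = seed,
    dt_img = dt_img), class = "cdk_population")
}

#' @export
print.cdk_population <- function(x, ...) {
  cat(sprintf("cdk_population: %d cell(s) [%s mode], dt_img = %g min, noise CV = %g\n",
              length(x$trajectories), x$params$mode, x$dt_img, x$noise))
  if (nrow(x$failed))
    cat(sprintf("  %d cell(s) failed (see $failed)\n", nrow(x$failed)))
  if (!is.null(x$truth)) {
    act <- x$truth$activation_nuclear
    cat(sprintf("  nuclear activation: %d/%d cells, mean %.1f min\n",
                sum(!is.na(act)), length(act), mean(act, na.rm = TRUE)))
  }
  invisible(x)
}
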