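#' Cells of a population entering the cohort analyses
#'
#' Mirrors the convention of analysing only cells whose full mitotic
#' progression fell within the acquisition: cells without a completed
#' mitotic exit are excluded, except in the HPM background, whose cells
#' block with the cytoplasm in a G2-like state and are analysed as such.
#'
#' @param pop a `"cdk_population"`.
#' @return character vector of cell ids.
#' @export
analysis_cells <- function(pop) {
  cells <- unique(pop$traces$cell_id)
  if (pop$params$mode == "HPM" || is.null(pop$truth$completed)) return(cells)
  done <- pop$truth$cell_id[pop$truth$completed]
  intersect(cells, done)
}

#' Extract sensor readout traces for every cell of a population
#'
#' @param pop a `"cdk_population"`.
#' @param kinds sensor channels to extract (default: all simulated sensors).
#' @return named list (per analysed cell, see [analysis_cells()]) of named
#'   lists (per kind) of `"sensor_readout_trace"` objects.
#' @export
population_readouts <- function(pop, kinds = NULL) {
  stopifnot(inherits(pop, "cdk_population"))
  kinds <- kinds %||% vapply(pop$sensors, `[[`, "", "kind")
  cells <- analysis_cells(pop)
  out <- lapply(cells, function(id) {
    per <- lapply(kinds, function(kd)
      sensor_readout(compartment_series(pop$traces, id, kd)))
    stats::setNames(per, kinds)
  })
  stats::setNames(out, cells)
}

#' Activation calls for every cell of a population
#'
#' @param pop a `"cdk_population"`.
#' @param kind sensor channel to call on.
#' @param config an [activation_config()].
#' @return list of `"activation_call"` objects (one per cell, nulls
#'   included).
#' @export
cohort_activation_calls <- function(pop, kind = "NucCDK",
                                    config = activation_config()) {
  ro <- population_readouts(pop, kinds = kind)
  lapply(ro, function(per) call_activation(per[[kind]], config))
}

#' Nuclear-to-cytoplasmic delay summary for a population
#'
#' Calls activation on the nuclear and cytoplasmic sensor channels of every
#' cell and summarises the paired delays with the acquisition interval as
#' histogram bin width.
#'
#' @param pop a `"cdk_population"`.
#' @param nuclear_kind,cytoplasmic_kind sensor channels.
#' @param config an [activation_config()].
#' @return a `"delay_summary"` (see [paired_delays()]).
#' @export
cohort_delay_summary <- function(pop, nuclear_kind = "NucCDK",
                                 cytoplasmic_kind = "CytCDK",
                                 config = activation_config()) {
  nc <- cohort_activation_calls(pop, nuclear_kind, config)
  cc <- cohort_activation_calls(pop, cytoplasmic_kind, config)
  paired_delays(nc, cc, bin_width = pop$dt_img)
}

#' Cohort mean two-curve delay at a threshold level
#'
#' Per cell, min--max normalises the nuclear and cytoplasmic sensor
#' readouts and measures the upward-crossing time difference at `level`
#' ([threshold_delay()]); reports all per-cell delays and their mean.
#'
#' @inheritParams cohort_delay_summary
#' @param level fraction of the normalised peak.
#' @return list with `delays` (per-cell, NA when a level is unreached),
#'   `mean`, `n`.
#' @export
cohort_threshold_delay <- function(pop, level = 0.75,
                                   nuclear_kind = "NucCDK",
                                   cytoplasmic_kind = "CytCDK") {
  ro <- population_readouts(pop, kinds = c(nuclear_kind, cytoplasmic_kind))
  d <- vapply(ro, function(per)
    as.numeric(threshold_delay(per[[nuclear_kind]],
                               per[[cytoplasmic_kind]], level = level)),
    numeric(1))
  list(delays = d, mean = mean(d, na.rm = TRUE), n = sum(!is.na(d)))
}

#' Cohort mean interval from called nuclear activation to called export
#'
#' Per cell, calls nuclear activation on the nuclear sensor channel and
#' export onset on the nuclear cyclin trace, and reports the mean of
#' `t_export - t_activation` over cells with both calls.
#'
#' @param pop a `"cdk_population"` whose traces carry a `cyclin` channel.
#' @param nuclear_kind sensor channel for the activation call.
#' @param config an [activation_config()] for the sensor-readout call.
#' @param export_config configuration for the export call on the cyclin
#'   intensity trace; the directly measured intensity channel carries less
#'   relative noise than a ratio readout, so it is smoothed minimally.
#' @return list with `intervals` (per-cell), `mean`, `n`.
#' @export
cohort_export_interval <- function(pop, nuclear_kind = "NucCDK",
                                   config = activation_config(),
                                   export_config = activation_config(
                                     smooth_window = 3, polyorder = 1)) {
  cells <- analysis_cells(pop)
  iv <- vapply(cells, function(id) {
    act <- call_activation(
      sensor_readout(compartment_series(pop$traces, id, nuclear_kind)),
      config)
    cyc <- compartment_series(pop$traces, id, "cyclin")
    exp_call <- call_export_onset(cyc$nuclear_mean, cyc$time, export_config,
                                  cell_id = id)
    if (is.na(act$time) || is.na(exp_call$time)) NA_real_
    else exp_call$time - act$time
  }, numeric(1))
  list(intervals = iv, mean = mean(iv, na.rm = TRUE), n = sum(!is.na(iv)))
}

#' Cohort mean difference between sensor rise onsets after release
#'
#' For a block-and-release population, measures per cell the
#' [response_lag()] of each sensor readout after the release time (first
#' departure from the pre-release baseline by `criterion` of the dynamic
#' range) and reports the mean cytoplasmic-minus-nuclear onset difference.
#'
#' @param pop a `"cdk_population"` simulated under
#'   [protocol_block_release()].
#' @inheritParams cohort_delay_summary
#' @param criterion fractional departure criterion; the default 0.05 sits
#'   well above the measurement noise of a single timepoint.
#' @param direction departure direction passed to [response_lag()]; the
#'   sensors rise after release, so only upward departures count.
#' @return list with `differences` (per-cell), `mean`, `sd`, `n`.
#' @export
cohort_onset_difference <- function(pop, nuclear_kind = "NucCDK",
                                    cytoplasmic_kind = "CytCDK",
                                    criterion = 0.05, direction = "up") {
  if (pop$protocol$type != "block_release")
    stop("population was not simulated under a block-release protocol",
         call. = FALSE)
  t_rel <- pop$protocol$t_release
  ro <- population_readouts(pop, kinds = c(nuclear_kind, cytoplasmic_kind))
  d <- vapply(ro, function(per) {
    ln <- response_lag(per[[nuclear_kind]]$readout, per[[nuclear_kind]]$time,
                       t_rel, criterion, direction = direction)
    lc <- response_lag(per[[cytoplasmic_kind]]$readout,
                       per[[cytoplasmic_kind]]$time, t_rel, criterion,
                       direction = direction)
    if (is.na(ln) || is.na(lc)) NA_real_ else lc - ln
  }, numeric(1))
  ok <- !is.na(d)
  list(differences = d, mean = mean(d[ok]), sd = stats::sd(d[ok]),
       n = sum(ok))
}

#' Acute-inhibition decay and response-lag analysis
#'
#' Simulates one noiseless cell to find its nuclear activation time, then
#' re-simulates with the inhibitor applied `t_peak_offset` minutes later
#' (at peak mitotic activity) and analyses the ensuing sensor decays: a
#' two-exponential fit for the nuclear sensor, a one-exponential fit for
#' the cytoplasmic one (each after subtracting the post-decay baseline),
#' and the response lag of each readout from the inhibition time.
#'
#' @param params an [oscillator_params()].
#' @param sensors sensor list; the first `NucCDK` and first `CytCDK`-family
#'   sensor are analysed.
#' @param t_peak_offset minutes after nuclear activation at which the
#'   inhibitor is applied.
#' @param dt_sample sampling interval of the decay curves (min).
#' @param fit_window length of the fitted decay window (min).
#' @param criterion response-lag departure criterion.
#' @return list with `fits` (named list of `"decay_fit"`), `lags` (named
#'   numeric), `t_inhibit`, `traces`.
#' @export
inhibition_analysis <- function(params = default_wt(),
                                sensors = default_sensors(),
                                t_peak_offset = 10, dt_sample = 1,
                                fit_window = 30, criterion = 0.01) {
  probe <- simulate_trajectory(params, sensors, protocol_free_run(),
                               duration = 260)
  t_act <- event_time(probe, "activation_nuclear")
  if (is.na(t_act)) stop("cell never activates; check parameters",
                         call. = FALSE)
  t_inh <- ceiling((t_act + t_peak_offset) / dt_sample) * dt_sample
  traj <- simulate_trajectory(params, sensors,
                              protocol_acute_inhibition(t_inh),
                              duration = t_inh + 2 * fit_window)
  traces <- sample_traces(traj, dt_img = dt_sample, noise_cv = 0)
  kinds <- vapply(sensors, `[[`, "", "kind")
  nuc_kind <- kinds[kinds == "NucCDK"][1]
  cyt_kind <- kinds[kinds %in% c("CytCDK", "CytCDKv2")][1]
  fits <- list(); lags <- c()
  for (kd in c(nuc_kind, cyt_kind)) {
    ro <- sensor_readout(compartment_series(traces, traj$cell_id, kd))
    ## inhibition can only lower the readout; an inherited rise carried
    ## through the sensor's transit delay is not a response
    lags[kd] <- response_lag(ro$readout, ro$time, t_inh, criterion,
                             direction = "down")
    sel <- ro$time >= t_inh & ro$time <= t_inh + 2 * fit_window
    y <- ro$readout[sel]; tt <- ro$time[sel] - t_inh
    ## crop the fitted decay at the post-inhibition maximum (the transit
    ## delay lets a readout coast upward briefly before it decays)
    i0 <- which.max(y)
    y <- y[i0:length(y)]; tt <- tt[i0:length(tt)] - tt[i0]
    baseline <- mean(utils::tail(y, 5))
    fit_sel <- tt <= fit_window
    fits[[kd]] <- fit_decay(y[fit_sel] - baseline, time = tt[fit_sel],
                            n_components = if (kd == nuc_kind) 2 else 1)
  }
  list(fits = fits, lags = lags, t_inhibit = t_inh, traces = traces)
}

#' Steady-state sensor readout at a fixed activity
#'
#' Closed-form steady state of the sensor ODEs at constant effective
#' activity: `p = k_on a / (k_on a + k_off)`, `f = f_target(p)`, readout
#' from the compartment concentrations of a unit sensor pool.
#'
#' @param sensor a [sensor_params()].
#' @param activity effective CDK activity `iota * A` (AU; vectorised).
#' @param phi_n nuclear volume fraction.
#' @return readout value(s).
#' @export
sensor_steady_readout <- function(sensor, activity, phi_n = 0.15) {
  a <- pmax(activity, 0)
  p <- sensor$k_on * a / (sensor$k_on * a + sensor$k_off)
  f <- sensor_f_target(sensor, p)
  nuc <- f / phi_n
  cyt <- (1 - f) / (1 - phi_n)
  if (sensor$kind == "NucCDK") cyt / nuc else nuc / cyt
}

#' Simulate a sensor inhibition dose--response curve
#'
#' Emulates the blocked-and-released dose--response assay in a
#' feedback-free background: cells at a fixed mitotic activity are released
#' into inhibitor at each dose, the catalytic fraction being
#' `iota = 1 / (1 + dose / Ki)`, and the steady-state readout recorded.
#'
#' @param sensor a [sensor_params()].
#' @param doses inhibitor concentrations (nM).
#' @param activity uninhibited mitotic activity (AU).
#' @param Ki inhibitor binding constant (nM).
#' @param phi_n nuclear volume fraction.
#' @return data.frame with `dose` and `readout`.
#' @export
simulate_dose_response <- function(sensor, doses = c(0, 10, 30, 100, 300,
                                                     1000, 3000, 10000),
                                   activity = 1, Ki = 100, phi_n = 0.15) {
  iota <- 1 / (1 + doses / Ki)
  data.frame(dose = doses,
             readout = sensor_steady_readout(sensor, iota * activity, phi_n))
}
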