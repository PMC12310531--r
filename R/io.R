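#' Write / read the shared long-format trace table
#'
#' CSV with columns `cell_id`, `time_min`, `channel`, `nuclear_mean`,
#' `cytoplasmic_mean`, `whole_mean`, `length_um` (the schema produced by
#' [sample_traces()] and consumed by [compartment_series()]).
#'
#' @param traces trace data.frame.
#' @param file path.
#' @return `read_traces()` returns the validated data.frame.
#' @export
write_traces <- function(traces, file) {
  utils::write.csv(traces, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "channel", "nuclear_mean",
            "cytoplasmic_mean", "whole_mean")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trace file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Write / read a full configuration as YAML
#'
#' Serialises an oscillator configuration, sensor set and imaging settings
#' into a single YAML file with `oscillator`, `sensors` and `imaging`
#' sections, and reconstructs the typed objects on reading.
#'
#' @param file path.
#' @param params an [oscillator_params()].
#' @param sensors list of [sensor_params()].
#' @param imaging an [imaging_config()].
#' @return `read_config()` returns `list(params, sensors, imaging)`.
#' @export
write_config <- function(file, params = default_wt(),
                         sensors = default_sensors(),
                         imaging = imaging_config()) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (inherits(v, "switch_rates")) unclass(v) else v)
  }
  yaml::write_yaml(list(oscillator = strip(params),
                        sensors = lapply(sensors, unclass),
                        imaging = unclass(imaging)), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  osc <- raw$oscillator
  params <- oscillator_params(
    k_syn = osc$k_syn,
    nuc = do.call(switch_rates, osc$nuc),
    cyt = do.call(switch_rates, osc$cyt),
    h = osc$h, k_exp_max = osc$k_exp_max, tau_exp = osc$tau_exp,
    exp_duration = osc$exp_duration %||% Inf,
    theta_act = osc$theta_act, theta_apc = osc$theta_apc,
    tau_apc = osc$tau_apc, k_deg_max = osc$k_deg_max,
    k_deg_basal = osc$k_deg_basal %||% 0,
    phi_n = osc$phi_n, mode = osc$mode, r_len = osc$r_len, L0 = osc$L0,
    tau_stop = osc$tau_stop, C_n0 = osc$C_n0,
    reset_interval = osc$reset_interval %||% Inf)
  sensors <- lapply(raw$sensors, function(s)
    sensor_params(kind = s$kind, k_on = s$k_on, k_off = s$k_off,
                  k_loc = s$k_loc, f_min = s$f_min, f_max = s$f_max,
                  host = s$host, tau_loc = s$tau_loc %||% 0))
  imaging <- do.call(imaging_config, raw$imaging)
  list(params = params, sensors = sensors, imaging = imaging)
}
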