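#' Y15-switch rate set for one compartment
#'
#' Rates of the inhibitory (Wee1-like) and activating (Cdc25-like) arms of
#' the CDK tyrosine-15 switch.  Both arms are themselves CDK-regulated:
#' the inhibitory rate falls from `kw_hi` to `kw_lo` as active CDK rises past
#' `K_w`, and the activating rate climbs from `k25_lo` to `k25_hi` past
#' `K_25`, each with Hill coefficient `h` (taken from the oscillator
#' parameters).  A wide `kw` span with a high half-saturation makes the
#' compartment strongly bistable; a narrow span makes it a weak switch.
#'
#' @param kw_lo,kw_hi inactivation rate bounds (min^-1), `kw_hi >= kw_lo`.
#' @param k25_lo,k25_hi activation rate bounds (min^-1), `k25_hi >= k25_lo`.
#' @param K_w,K_25 half-saturation constants (AU) of the two arms.
#' @return a list of class `"switch_rates"`.
#' @export
switch_rates <- function(kw_lo, kw_hi, k25_lo, k25_hi, K_w, K_25) {
  stop_if_not_scalar(kw_lo, "kw_lo", lower = 0)
  stop_if_not_scalar(kw_hi, "kw_hi", lower = 0)
  stop_if_not_scalar(k25_lo, "k25_lo", lower = 0)
  stop_if_not_scalar(k25_hi, "k25_hi", lower = 0)
  stop_if_not_scalar(K_w, "K_w", lower = 1e-12)
  stop_if_not_scalar(K_25, "K_25", lower = 1e-12)
  if (kw_hi < kw_lo) stop("kw_hi must be >= kw_lo", call. = FALSE)
  if (k25_hi < k25_lo) stop("k25_hi must be >= k25_lo", call. = FALSE)
  structure(list(kw_lo = kw_lo, kw_hi = kw_hi, k25_lo = k25_lo,
                 k25_hi = k25_hi, K_w = K_w, K_25 = K_25),
            class = "switch_rates")
}

#' Two-compartment cyclin--CDK oscillator parameters
#'
#' Mechanistic parameters of the synthetic ground-truth model: nuclear
#' cyclin--CDK synthesis, per-compartment Y15 feedback switches, nuclear
#' export of the active complex triggered at mitotic onset, APC/C-driven
#' degradation, cell growth, and the activity thresholds/lags that define the
#' ground-truth event times.  The shipped configurations [default_wt()],
#' [default_af()] and [default_hpm()] hold calibrated values for these
#' fields.
#'
#' Mitotic event switches (nuclear export, degradation) and the ground-truth
#' activation events are triggered when the inhibitor-scaled effective
#' activity `iota(t) * A` crosses a threshold: a catalytically inhibited
#' kinase cannot phosphorylate the downstream targets that execute these
#' transitions, whatever its Y15 state.
#'
#' @param k_syn nuclear cyclin--CDK synthesis rate while growing (AU min^-1).
#' @param nuc,cyt per-compartment [switch_rates()].
#' @param h Hill coefficient shared by both switch arms (>= 1).
#' @param k_exp_max nuclear export rate once export is on (min^-1).
#' @param tau_exp lag from nuclear activation to export onset (min).
#' @param exp_duration duration of the export wave (min); export is a
#'   transient translocation at mitotic onset with a beginning and an end,
#'   leaving a nuclear remnant of roughly
#'   `exp(-k_exp_max * exp_duration)`.  `Inf` exports indefinitely.
#' @param theta_act effective-activity threshold defining the ground-truth
#'   activation event, expressed as a nuclear concentration (AU).  The same
#'   active *amount* defines the cytoplasmic event, so the cytoplasmic
#'   concentration threshold is `theta_act * phi_n / (1 - phi_n)`.
#' @param theta_apc effective cytoplasmic activity threshold arming the
#'   APC/C (AU).
#' @param tau_apc lag from APC/C arming to degradation onset (min).
#' @param k_deg_max degradation rate once degradation is on (min^-1).
#' @param k_deg_basal slow constitutive cyclin--CDK turnover, always active
#'   in both compartments (min^-1).
#' @param phi_n nuclear volume fraction, in (0, 1).
#' @param mode `"WT"`, `"AF"` (Y15 sites unphosphorylatable, activity equals
#'   total cyclin--CDK) or `"HPM"` (cyclin hydrophobic-patch mutant, no
#'   nuclear export).
#' @param r_len elongation rate (um min^-1).
#' @param L0 initial cell length (um).
#' @param tau_stop lag from nuclear activation to elongation stop (min).
#' @param C_n0 initial nuclear cyclin--CDK concentration (AU).
#' @param reset_interval interval after degradation onset at which the
#'   free-running protocol resets the cell to its G1-like initial state
#'   (min); `Inf` (default) simulates a single cycle.
#' @return a list of class `"oscillator_params"`.
#' @seealso [default_wt()], [simulate_trajectory()]
#' @export
oscillator_params <- function(k_syn, nuc, cyt, h = 4,
                              k_exp_max, tau_exp, exp_duration = Inf,
                              theta_act, theta_apc, tau_apc, k_deg_max,
                              k_deg_basal = 0.0015, phi_n = 0.15, mode = c("WT", "AF", "HPM"),
                              r_len = 0.02, L0 = 8, tau_stop = 5,
                              C_n0 = 0.3, reset_interval = Inf) {
  mode <- match.arg(mode)
  stop_if_not_scalar(k_syn, "k_syn", lower = 0)
  stop_if_not_scalar(h, "h", lower = 1)
  stop_if_not_scalar(k_exp_max, "k_exp_max", lower = 0)
  stop_if_not_scalar(tau_exp, "tau_exp", lower = 0)
  if (!identical(exp_duration, Inf))
    stop_if_not_scalar(exp_duration, "exp_duration", lower = 0)
  stop_if_not_scalar(theta_act, "theta_act", lower = 0)
  stop_if_not_scalar(theta_apc, "theta_apc", lower = 0)
  stop_if_not_scalar(tau_apc, "tau_apc", lower = 0)
  stop_if_not_scalar(k_deg_max, "k_deg_max", lower = 0)
  stop_if_not_scalar(k_deg_basal, "k_deg_basal", lower = 0)
  stop_if_not_scalar(phi_n, "phi_n", lower = 1e-6, upper = 1 - 1e-6)
  stop_if_not_scalar(r_len, "r_len", lower = 0)
  stop_if_not_scalar(L0, "L0", lower = 0)
  stop_if_not_scalar(tau_stop, "tau_stop", lower = 0)
  stop_if_not_scalar(C_n0, "C_n0", lower = 0)
  if (!inherits(nuc, "switch_rates") || !inherits(cyt, "switch_rates"))
    stop("'nuc' and 'cyt' must be switch_rates objects", call. = FALSE)
  if (mode == "HPM") k_exp_max <- 0
  structure(list(k_syn = k_syn, nuc = nuc, cyt = cyt, h = h,
                 k_exp_max = k_exp_max, tau_exp = tau_exp,
                 exp_duration = exp_duration,
                 theta_act = theta_act, theta_apc = theta_apc,
                 tau_apc = tau_apc, k_deg_max = k_deg_max,
                 k_deg_basal = k_deg_basal, phi_n = phi_n, mode = mode,
                 r_len = r_len, L0 = L0, tau_stop = tau_stop,
                 C_n0 = C_n0, reset_interval = reset_interval),
            class = "oscillator_params")
}

#' Translocation biosensor parameters
#'
#' A sensor is a fixed pool of substrate whose phosphorylated fraction `p`
#' follows the effective activity of its host compartment
#' (`dp/dt = k_on * iota * A_host * (1 - p) - k_off * p`) and whose nuclear
#' localisation fraction `f` relaxes towards a target that is linear in `p`
#' (`df/dt = k_loc * (f_target(p) - f)`).  For `NucCDK` the target decreases
#' with `p` (phosphorylation exports the sensor); for `CytCDK`/`CytCDKv2` it
#' increases (phosphorylation imports it).  The ratio `k_on / k_off` sets the
#' sensitivity to CDK activity; `CytCDKv2` carries a higher ratio than
#' `CytCDK`.
#'
#' Sensor translocation takes time: besides the first-order relaxation rate
#' `k_loc`, a sensor may carry a transport transit delay `tau_loc` (min):
#' the localisation machinery responds to the phosphostate as it was
#' `tau_loc` minutes ago, giving the readout a genuine dead time.  The
#' cytoplasmic scaffold carries a non-zero transit delay (its readout is
#' observed to keep its prior course for a couple of minutes after an acute
#' activity change); the nuclear sensor responds without one.
#'
#' @param kind `"NucCDK"`, `"CytCDK"` or `"CytCDKv2"`.
#' @param k_on phosphorylation rate (AU^-1 min^-1).
#' @param k_off dephosphorylation rate (min^-1).
#' @param k_loc localisation relaxation rate (min^-1).
#' @param tau_loc transport transit delay (min, >= 0).
#' @param f_min,f_max bounds of the nuclear localisation fraction,
#'   `0 <= f_min < f_max <= 1`.
#' @param host compartment whose activity is sensed, `"nucleus"` or
#'   `"cytoplasm"`.
#' @return a list of class `"sensor_params"`.
#' @export
sensor_params <- function(kind = c("NucCDK", "CytCDK", "CytCDKv2"),
                          k_on, k_off, k_loc, f_min, f_max,
                          host = c("nucleus", "cytoplasm"), tau_loc = 0) {
  kind <- match.arg(kind)
  host <- match.arg(host)
  stop_if_not_scalar(k_on, "k_on", lower = 0)
  stop_if_not_scalar(k_off, "k_off", lower = 1e-12)
  stop_if_not_scalar(k_loc, "k_loc", lower = 1e-12)
  stop_if_not_scalar(tau_loc, "tau_loc", lower = 0)
  stop_if_not_scalar(f_min, "f_min", lower = 0, upper = 1)
  stop_if_not_scalar(f_max, "f_max", lower = 0, upper = 1)
  if (f_min >= f_max) stop("f_min must be < f_max", call. = FALSE)
  structure(list(kind = kind, k_on = k_on, k_off = k_off, k_loc = k_loc,
                 tau_loc = tau_loc, f_min = f_min, f_max = f_max,
                 host = host),
            class = "sensor_params")
}

## localisation target as a function of phosphorylated fraction
sensor_f_target <- function(sensor, p) {
  if (sensor$kind == "NucCDK")
    sensor$f_max - (sensor$f_max - sensor$f_min) * p
  else
    sensor$f_min + (sensor$f_max - sensor$f_min) * p
}

#' Shipped sensor configurations
#'
#' Calibrated defaults for the three translocation sensors.  `NucCDK` is
#' fast on both phosphorylation turnover and translocation and reads nuclear
#' activity; `CytCDK` reads cytoplasmic activity with a lower
#' `k_on`/`k_off` ratio (less sensitive to CDK activity) and slower
#' translocation; `CytCDKv2` restores a `NucCDK`-like sensitivity in the
#' cytoplasmic scaffold.
#'
#' @param kinds character vector of sensor kinds to return.
#' @return a named list of [sensor_params()] objects.
#' @export
default_sensors <- function(kinds = c("NucCDK", "CytCDK")) {
  all <- list(
    NucCDK = sensor_params("NucCDK", k_on = 14, k_off = 2.0, k_loc = 3.0,
                           f_min = 0.20, f_max = 0.90, host = "nucleus"),
    CytCDK = sensor_params("CytCDK", k_on = 10, k_off = 0.50, k_loc = 1.0,
                           f_min = 0.10, f_max = 0.80, host = "cytoplasm",
                           tau_loc = 2.6),
    CytCDKv2 = sensor_params("CytCDKv2", k_on = 25, k_off = 0.50,
                             k_loc = 1.0, f_min = 0.10, f_max = 0.80,
                             host = "cytoplasm", tau_loc = 2.6))
  kinds <- match.arg(kinds, names(all), several.ok = TRUE)
  all[kinds]
}

#' Calibrated oscillator configurations
#'
#' `default_wt()` is the wild-type configuration: a strongly bistable
#' nuclear Y15 switch with a high cyclin threshold, a weakly switched
#' cytoplasm with a low threshold, and export of active cyclin--CDK from the
#' nucleus `tau_exp` minutes after nuclear activation.  `default_af()` is the
#' same cell with the Y15 feedback abolished (activity identical to total
#' cyclin--CDK).  `default_hpm()` carries the cyclin hydrophobic-patch
#' mutation: the complex never reaches the spindle pole body, nuclear export
#' never switches on and the cytoplasm stays in a G2-like state.
#'
#' All rate values were fixed once by in-repo calibration
#' (`scripts/calibrate.R`) so that the emergent timing statistics of the
#' simulated populations match the experimentally reported scale of nuclear
#' versus cytoplasmic CDK activation timing.
#'
#' @return an [oscillator_params()] object.
#' @export
default_wt <- function() {
  oscillator_params(
    k_syn = 0.014,
    nuc = switch_rates(kw_lo = 0.01, kw_hi = 0.80, k25_lo = 0.020,
                       k25_hi = 1.20, K_w = 0.12, K_25 = 0.12),
    cyt = switch_rates(kw_lo = 0.005, kw_hi = 0.10, k25_lo = 0.02,
                       k25_hi = 0.35, K_w = 0.035, K_25 = 0.035),
    h = 6,
    k_exp_max = 0.5, tau_exp = 0, exp_duration = 3,
    theta_act = 0.45, theta_apc = 0.04, tau_apc = 8, k_deg_max = 0.06,
    phi_n = 0.15, mode = "WT",
    r_len = 0.02, L0 = 8, tau_stop = 5, C_n0 = 0.6)
}

#' Mode-appropriate G2 block-and-release protocol
#'
#' The emulated block-and-release experiments hold cells with the kinase
#' inhibited and then wash the inhibitor out.  Wild-type cells are held
#' long enough to accumulate cyclin--CDK far beyond the activation
#' threshold, so the Y15 switch fires almost immediately on washout.  In
#' the feedback-abolished (AF) background the hold is shorter, releasing
#' cells just under the activation threshold: without the switch, effective
#' activity grows only with cyclin synthesis, which is what extends the
#' delay between the nuclear and cytoplasmic sensor rises in that
#' background.
#'
#' @param params an [oscillator_params()]; the hold length depends on its
#'   mode and synthesis rate.
#' @param iota_block residual activity during the hold.
#' @param tau_washout washout time constant (min).
#' @return a [protocol_block_release()] object.
#' @export
default_block_release <- function(params, iota_block = 0.02,
                                  tau_washout = 7.5) {
  t_rel <- if (params$mode == "AF") {
    ## hold until cyclin sits ~25% above the activation threshold: the
    ## feedback-free activity then crosses the threshold as the inhibitor
    ## washes out, which is what spreads the cytoplasmic onset
    (1.22 * params$theta_act - params$C_n0) / params$k_syn
  } else 240
  protocol_block_release(t_release = t_rel, iota_block = iota_block,
                         tau_washout = tau_washout)
}

#' @rdname default_wt
#' @export
default_af <- function() {
  p <- default_wt()
  p$mode <- "AF"
  ## the feedback-abolished strain accumulates cyclin-CDK more slowly and
  ## enters mitosis from a lower load relative to its activation threshold
  ## (no switch overshoot); its cycle is correspondingly longer
  p$k_syn <- 0.004
  p$C_n0 <- 0.14
  p
}

#' @rdname default_wt
#' @export
default_hpm <- function() {
  p <- default_wt()
  p$mode <- "HPM"
  p$k_exp_max <- 0
  p
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat(sprintf("Two-compartment cyclin-CDK oscillator parameters [%s mode]\n",
              x$mode))
  cat(sprintf("  synthesis k_syn = %g AU/min, initial C_n = %g AU\n",
              x$k_syn, x$C_n0))
  cat(sprintf("  export: k_exp_max = %g /min after activation + %g min\n",
              x$k_exp_max, x$tau_exp))
  cat(sprintf("  thresholds: theta_act = %g, theta_apc = %g AU (tau_apc = %g min)\n",
              x$theta_act, x$theta_apc, x$tau_apc))
  cat(sprintf("  degradation k_deg_max = %g /min; phi_n = %g\n",
              x$k_deg_max, x$phi_n))
  for (cp in c("nuc", "cyt")) {
    s <- x[[cp]]
    cat(sprintf("  %s switch: kw %g-%g, k25 %g-%g (K_w %g, K_25 %g, h %g)\n",
                cp, s$kw_lo, s$kw_hi, s$k25_lo, s$k25_hi, s$K_w, s$K_25, x$h))
  }
  invisible(x)
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("%s sensor (host %s): k_on %g, k_off %g, k_loc %g, f in [%g, %g]\n",
              x$kind, x$host, x$k_on, x$k_off, x$k_loc, x$f_min, x$f_max))
  invisible(x)
}
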