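#' Configuration of the synthetic phosphosite timecourse generator
#'
#' Each compartment contributes `n_sites` late-phase, single-compartment
#' phosphosites whose true rate-change time is drawn normally around
#' `mean_t` (s.d. `sd_t`, truncated to (0, 1) by redrawing); phosphorylation
#' is flat (slope `slope_pre`) before the change and rises with
#' `slope_post` after it, with additive Gaussian noise.  IC50 values are
#' drawn lognormally, independently of timing.  Decoy sites (early-phase
#' and multi-compartment annotations) are added so the filtering step has
#' something to drop.
#'
#' The default compartment layout mirrors a compartment-annotated mitotic
#' phosphoproteomics timecourse: nuclear sites change earliest, and the
#' cytoplasmic-periphery and SPB cohorts have no timing variability.
#'
#' @param compartments data.frame with columns `compartment`, `n_sites`,
#'   `mean_t`, `sd_t`.
#' @param n_time timecourse length (>= 8).
#' @param slope_pre,slope_post phosphorylation slopes per unit normalised
#'   time before/after the change.
#' @param noise_sd additive noise s.d. (phosphorylation units).
#' @param ic50_meanlog,ic50_sdlog lognormal IC50 parameters (nM).
#' @param n_early,n_multi decoy site counts.
#' @return a list of class `"phospho_gen_config"`.
#' @export
phospho_gen_config <- function(
    compartments = data.frame(
      compartment = c("nucleus", "cytoplasm", "cytoplasmic_periphery",
                      "nuclear_envelope", "SPB"),
      n_sites = c(45L, 41L, 27L, 20L, 7L),
      mean_t = c(0.40, 0.47, 0.50, 0.48, 0.50),
      sd_t = c(0.04, 0.04, 0.00, 0.05, 0.00)),
    n_time = 21, slope_pre = 0.05, slope_post = 2.5,
    noise_sd = 0.02, ic50_meanlog = log(200), ic50_sdlog = 0.8,
    n_early = 10, n_multi = 5) {
  stopifnot(is.data.frame(compartments),
            all(c("compartment", "n_sites", "mean_t", "sd_t") %in%
                  names(compartments)))
  if (nrow(compartments) < 2)
    stop("configure >= 2 compartments", call. = FALSE)
  if (any(compartments$n_sites < 1))
    stop("site counts must be >= 1", call. = FALSE)
  if (any(compartments$mean_t <= 0 | compartments$mean_t >= 1))
    stop("mean change times must lie in (0, 1)", call. = FALSE)
  if (n_time < 8) stop("n_time must be >= 8", call. = FALSE)
  structure(list(compartments = compartments, n_time = n_time,
                 slope_pre = slope_pre, slope_post = slope_post,
                 noise_sd = noise_sd, ic50_meanlog = ic50_meanlog,
                 ic50_sdlog = ic50_sdlog, n_early = n_early,
                 n_multi = n_multi), class = "phospho_gen_config")
}

draw_change_time <- function(mean_t, sd_t, max_attempts = 100) {
  if (sd_t <= 0) return(mean_t)
  for (i in seq_len(max_attempts)) {
    tt <- stats::rnorm(1, mean_t, sd_t)
    if (tt > 0 && tt < 1) return(tt)
  }
  stop(sprintf("could not draw a change time in (0, 1) around %g (sd %g) in %d attempts",
               mean_t, sd_t, max_attempts), call. = FALSE)
}

#' Generate a synthetic phosphosite timecourse table
#'
#' @param config a [phospho_gen_config()].
#' @param seed integer seed.
#' @return data.frame with columns `site_id`, `protein`, `compartment`,
#'   `class` (`"early"`/`"late"`), `ic50`, `true_change_time`, and
#'   timecourse columns `t_0 .. t_<K>` over normalised cell-cycle time.
#' @examples
#' ph <- generate_phospho_dataset(seed = 1)
#' table(ph$compartment[ph$class == "late"])
#' @export
generate_phospho_dataset <- function(config = phospho_gen_config(),
                                     seed = 1L) {
  stopifnot(inherits(config, "phospho_gen_config"))
  set.seed(seed)
  tgrid <- seq(0, 1, length.out = config$n_time)
  make_course <- function(t_change) {
    base <- config$slope_pre * tgrid
    rise <- config$slope_post * pmax(tgrid - t_change, 0)
    base + rise + stats::rnorm(config$n_time, 0, config$noise_sd)
  }
  rows <- list()
  idx <- 0L
  add_site <- function(compartment, class, t_change) {
    idx <<- idx + 1L
    ic50 <- stats::rlnorm(1, config$ic50_meanlog, config$ic50_sdlog)
    vals <- make_course(t_change)
    rows[[idx]] <<- data.frame(
      site_id = sprintf("site_%03d", idx),
      protein = sprintf("prot_%03d", idx),
      compartment = compartment, class = class, ic50 = ic50,
      true_change_time = t_change,
      t(stats::setNames(vals, paste0("t_", seq_along(tgrid) - 1L))),
      stringsAsFactors = FALSE)
  }
  cmp <- config$compartments
  for (i in seq_len(nrow(cmp))) {
    for (s in seq_len(cmp$n_sites[i]))
      add_site(cmp$compartment[i], "late",
               draw_change_time(cmp$mean_t[i], cmp$sd_t[i]))
  }
  ## decoys removed by filtering: early-phase and dual-annotated sites
  for (s in seq_len(config$n_early))
    add_site(sample(cmp$compartment, 1), "early",
             draw_change_time(0.15, 0.03))
  for (s in seq_len(config$n_multi))
    add_site(paste(sample(cmp$compartment, 2), collapse = ";"), "late",
             draw_change_time(mean(cmp$mean_t), 0.05))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "time_grid") <- tgrid
  out
}
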