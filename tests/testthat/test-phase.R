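test_that("identical ramps give a diagonal orbit with zero area", {
  t <- seq(0, 95, by = 5)
  ramp <- t / 95
  orb <- build_orbit(ramp, ramp, time = t, smooth_window = 0)
  expect_equal(orb$x, orb$y)
  expect_equal(orbit_area(orb), 0, tolerance = 1e-12)
})

test_that("shoelace area: unit square, collinear points, sampled circle", {
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(orbit_area(sq), 1)
  expect_equal(orbit_area(list(x = 1:5, y = 2 * (1:5))), 0)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- list(x = 0.5 * cos(th), y = 0.5 * sin(th))
  expect_equal(orbit_area(circ), pi / 4, tolerance = pi / 4 * 0.005)
})

test_that("area is invariant to traversal direction and axis swap", {
  set.seed(12)
  th <- sort(stats::runif(30, 0, 2 * pi))
  x <- cos(th) + stats::rnorm(30, 0, 0.05)
  y <- sin(th) + stats::rnorm(30, 0, 0.05)
  a <- orbit_area(list(x = x, y = y))
  expect_equal(orbit_area(list(x = rev(x), y = rev(y))), a)
  expect_equal(orbit_area(list(x = y, y = x)), a)
})

test_that("orbit metrics classify a rectangle as orbit and a diagonal as collapsed", {
  rect <- structure(list(
    x = c(0, 0.5, 1, 1, 1, 0.5, 0, 0), y = c(0, 0, 0, 0.5, 1, 1, 1, 0.5),
    time = seq(0, 35, by = 5), dt = 5, normalized = c(TRUE, TRUE),
    cell_id = "r", compartment = "nucleus"), class = "phase_orbit")
  ## order points in acquisition order up to the activity maximum
  m <- orbit_metrics(rect)
  expect_equal(m$area, 1)
  expect_gt(m$hysteresis_gap, 0.9)
  expect_lt(m$linearity_r2, 0.5)
  expect_equal(m$regime, "orbit")

  t <- seq(0, 95, by = 5)
  diagonal <- build_orbit(t / 95, t / 95 + stats::rnorm(20, 0, 1e-4),
                          time = t, smooth_window = 0)
  md <- orbit_metrics(diagonal)
  expect_lt(md$area, 0.05)
  expect_gt(md$linearity_r2, 0.95)
  expect_equal(md$regime, "collapsed")
  expect_equal(md$hysteresis_gap, 0, tolerance = 0.01)
})

test_that("simulated nuclear orbits dwarf cytoplasmic ones and sit at higher thresholds", {
  pop <- wt_cohort(n = 12, seed = 55)
  cells <- analysis_cells(pop)
  met <- lapply(cells, function(id) {
    cyc <- compartment_series(pop$traces, id, "cyclin")
    ron <- sensor_readout(compartment_series(pop$traces, id, "NucCDK"))
    roc <- sensor_readout(compartment_series(pop$traces, id, "CytCDK"))
    ## size/threshold comparisons keep the concentration axis in AU (the
    ## readout axis alone is min-max normalised, as phase plots are drawn)
    on <- orbit_metrics(build_orbit(cyc$nuclear_mean, ron$readout,
                                    time = cyc$time, cell_id = id,
                                    normalize = c(FALSE, TRUE)))
    oc <- orbit_metrics(build_orbit(cyc$cytoplasmic_mean, roc$readout,
                                    time = cyc$time, cell_id = id,
                                    compartment = "cytoplasm",
                                    normalize = c(FALSE, TRUE)))
    ## the hysteresis gap is compared on fully normalised orbits
    gn <- orbit_metrics(build_orbit(cyc$nuclear_mean, ron$readout,
                                    time = cyc$time, cell_id = id,
                                    smooth_window = 5))
    gc <- orbit_metrics(build_orbit(cyc$cytoplasmic_mean, roc$readout,
                                    time = cyc$time, cell_id = id,
                                    compartment = "cytoplasm",
                                    smooth_window = 5))
    c(area_n = on$area, area_c = oc$area,
      thr_n = on$activation_threshold, thr_c = oc$activation_threshold,
      gap_n = gn$hysteresis_gap, gap_c = gc$hysteresis_gap)
  })
  met <- do.call(rbind, met)
  expect_gt(median(met[, "area_n"]), median(met[, "area_c"]))
  expect_gt(median(met[, "thr_n"]), median(met[, "thr_c"]))
  expect_gt(median(met[, "gap_n"]), median(met[, "gap_c"]))
})

test_that("collapse classification separates WT from AF cells", {
  n_each <- 30
  classify <- function(params, duration, compartment = "nucleus") {
    pop <- simulate_population(params, default_sensors(), n_cells = n_each,
                               seed = 77, duration = duration,
                               division_margin = 25)
    vapply(analysis_cells(pop), function(id) {
      cyc <- compartment_series(pop$traces, id, "cyclin")
      ron <- sensor_readout(compartment_series(pop$traces, id, "NucCDK"))
      orbit_metrics(build_orbit(cyc$nuclear_mean, ron$readout,
                                time = cyc$time, cell_id = id))$regime
    }, character(1))
  }
  wt <- classify(default_wt(), duration = 150)
  af <- classify(default_af(), duration = 130)
  expect_gte(mean(wt == "orbit"), 0.95)
  expect_gte(mean(af == "collapsed"), 0.95)
})

test_that("cyclin at activation reads the series at the call time", {
  tr <- data.frame(cell_id = "c", time_min = seq(0, 45, by = 5),
                   channel = "cyclin", nuclear_mean = 10,
                   cytoplasmic_mean = 3, whole_mean = 4.05)
  s <- compartment_series(tr, "c", "cyclin")
  call <- structure(list(cell_id = "c", time = 20), class = "activation_call")
  expect_equal(cyclin_at_activation(s, call, background = 2), 8)
  bad <- structure(list(cell_id = "c", time = 22), class = "activation_call")
  expect_error(cyclin_at_activation(s, bad, 2), "not a timepoint")
  nullc <- structure(list(cell_id = "c", time = NA_real_),
                     class = "activation_call")
  expect_error(cyclin_at_activation(s, nullc, 2), "null")
})

test_that("median nuclear cyclin at activation exceeds the cytoplasmic one", {
  pop <- wt_cohort(n = 12, seed = 55)
  cells <- analysis_cells(pop)
  vals <- lapply(cells, function(id) {
    cyc <- compartment_series(pop$traces, id, "cyclin")
    cn <- call_activation(sensor_readout(
      compartment_series(pop$traces, id, "NucCDK")))
    cc <- call_activation(sensor_readout(
      compartment_series(pop$traces, id, "CytCDK")))
    if (is.na(cn$time) || is.na(cc$time)) return(NULL)
    c(nuc = cyclin_at_activation(cyc, cn, 0, "nucleus"),
      cyt = cyclin_at_activation(cyc, cc, 0, "cytoplasm"))
  })
  vals <- do.call(rbind, vals)
  expect_gt(median(vals[, "nuc"]), median(vals[, "cyt"]))
})
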