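test_that("a flat-then-ramp readout is called at the ramp start", {
  t <- seq(0, 150, by = 5)
  y <- flat_then_ramp(t, t_break = 100)
  call <- call_activation(y, time = t)
  ## the first point of the post-change segment is the first rising frame;
  ## the kink itself belongs to the pre-change line
  expect_lt(abs(call$time - 100), 5 + 1e-9)
  expect_gt(call$slope_post, call$slope_pre)
})

test_that("activation calls are invariant to positive affine readout rescaling", {
  t <- seq(0, 150, by = 5)
  set.seed(2)
  y <- flat_then_ramp(t, 120) + stats::rnorm(length(t), 0, 0.01)
  base <- call_activation(y, time = t)
  for (a in c(0.2, 3, 40)) for (b in c(-5, 2)) {
    call <- call_activation(a * y + b, time = t)
    expect_equal(call$time, base$time)
  }
})

test_that("a shallow monotone trace (G2-arrest-like) yields a null call", {
  t <- seq(0, 150, by = 5)
  set.seed(8)
  y <- 1 + 0.002 * t + stats::rnorm(length(t), 0, 0.002)
  call <- call_activation(y, time = t)
  expect_true(is.na(call$time))
  expect_match(call$reason, "slope|significant")
})

test_that("calls on simulated noiseless cells land within one frame of the truth", {
  pop <- wt_cell()
  truth <- pop$truth
  ron <- sensor_readout(compartment_series(pop$traces, truth$cell_id, "NucCDK"))
  call <- call_activation(ron)
  ## the call marks the onset of the rapid rise, on the acquisition grid;
  ## the threshold-crossing event sits partway up the rise
  expect_lt(abs(call$time - truth$activation_nuclear), 2 * 5)
  expect_false(is.na(call$time))
})

test_that("small noise moves calls by at most one frame in almost all trials", {
  t <- seq(0, 150, by = 5)
  y <- flat_then_ramp(t, 100)
  rng <- diff(range(y))
  set.seed(31)
  base <- call_activation(y, time = t)$time
  moved <- replicate(200, {
    call <- call_activation(y + stats::rnorm(length(y), 0, 0.01 * rng),
                            time = t)
    abs(call$time - base)
  })
  expect_gte(mean(moved <= 5), 0.95)
})

test_that("paired delays: shifts, binning conventions, exclusions", {
  t <- seq(0, 150, by = 5)
  y <- flat_then_ramp(t, 100)
  mkcall <- function(id, shift) {
    call_activation(flat_then_ramp(t, 100 + shift), time = t, cell_id = id)
  }
  nuc <- lapply(1:5, function(i) mkcall(paste0("c", i), 0))
  cyt <- lapply(1:5, function(i) mkcall(paste0("c", i), 10))
  ds <- paired_delays(nuc, cyt, bin_width = 5)
  expect_equal(ds$delays$delay, rep(10, 5))
  expect_equal(ds$sd, 0)

  ## binning: delays {4,6,8}, bin width 5 -> [0,5) holds 1, [5,10] holds 2
  fake <- function(id, tt)
    structure(list(cell_id = id, time = tt), class = "activation_call")
  a <- list(fake("x", 0), fake("y", 0), fake("z", 0))
  b <- list(fake("x", 4), fake("y", 6), fake("z", 8))
  ds2 <- paired_delays(a, b, bin_width = 5)
  expect_equal(ds2$breaks, c(0, 5, 10))
  expect_equal(ds2$counts, c(1L, 2L))

  ## unmatched and null calls are excluded with a count
  b2 <- list(fake("x", 4), fake("q", 6), fake("z", NA_real_))
  ds3 <- paired_delays(a, b2, bin_width = 5)
  expect_equal(ds3$n, 1L)
  expect_equal(ds3$n_excluded, 2L)
  expect_error(paired_delays(a, list(fake("w", 3)), 5), "no matched")
})

test_that("threshold delays between offset ramps equal the offset", {
  t <- seq(0, 100, by = 5)
  nuc <- pmin(t / 50, 1)
  cyt <- pmin(pmax(t - 7, 0) / 50, 1)
  expect_equal(as.numeric(threshold_delay(nuc, cyt, level = 0.75, time = t)),
               7, tolerance = 1e-10)
  ## level 1.0 with simultaneous peaks
  expect_equal(as.numeric(threshold_delay(nuc, nuc, level = 1, time = t)), 0)
  ## a constant trace cannot be normalised
  expect_error(threshold_delay(nuc, rep(1, 21), level = 0.9, time = t),
               "constant")
})

test_that("elongation stop is called at the growth plateau", {
  t <- seq(0, 250, by = 5)
  L <- 7 + 0.02 * pmin(t, 200)
  call <- call_elongation_stop(L, t)
  expect_lt(abs(call$time - 200), 5 + 1e-9)
  ## pure linear growth: no plateau, null call
  expect_true(is.na(call_elongation_stop(7 + 0.02 * t, t)$time))
})

test_that("on simulated cells elongation stops after the activation call", {
  pop <- wt_cell()
  d <- pop$traces[pop$traces$channel == "NucCDK", ]
  act <- call_activation(sensor_readout(
    compartment_series(pop$traces, d$cell_id[1], "NucCDK")))
  stop_call <- call_elongation_stop(d$length_um, d$time_min)
  expect_false(is.na(stop_call$time))
  expect_gte(stop_call$time, act$time)
})

test_that("site change times are recovered exactly on clean timecourses", {
  tt <- seq(0, 1, length.out = 21)
  y <- 0.05 * tt + 2.5 * pmax(tt - 0.45, 0)
  expect_lt(abs(site_change_time(y, tt) - 0.45), 0.5 * diff(tt)[1] + 1e-9)
  ## an abrupt jump between two grid points
  y2 <- c(rep(1, 10), 2 + 0.4 * (0:10))
  expect_lt(abs(site_change_time(y2, tt) - tt[11]), 0.5 * diff(tt)[1] + 1e-9)
  expect_error(site_change_time(y[1:6]), ">= 8")
})

test_that("delay estimator is unbiased to within half a frame on known shifts", {
  t <- seq(0, 150, by = 5)
  set.seed(17)
  shifts <- sample(c(5, 10, 15), 30, replace = TRUE)
  est <- vapply(seq_along(shifts), function(i) {
    noise <- function() stats::rnorm(length(t), 0, 0.005)
    a <- call_activation(flat_then_ramp(t, 108) + noise(), time = t,
                         cell_id = "c")
    b <- call_activation(flat_then_ramp(t, 108 + shifts[i]) + noise(),
                         time = t, cell_id = "c")
    b$time - a$time
  }, numeric(1))
  expect_lt(abs(mean(est - shifts)), 2.5)
})
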