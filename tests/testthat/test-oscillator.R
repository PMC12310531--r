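test_that("AF mode pins activity to total cyclin-CDK at every step", {
  p <- default_af()
  tr <- simulate_trajectory(p, list(), duration = 80, dt_sim = 0.2)
  expect_equal(tr$state[, "A_n"], tr$state[, "C_n"], tolerance = 1e-12)
  expect_equal(tr$state[, "A_c"], tr$state[, "C_c"], tolerance = 1e-12)
})

test_that("HPM mode never exports: empty cytoplasm, no cytoplasmic events", {
  tr <- simulate_trajectory(default_hpm(), default_sensors(),
                            duration = 150, dt_sim = 0.1)
  expect_true(all(tr$state[, "C_c"] == 0))
  expect_false("export_onset" %in% tr$events$event)
  expect_false("activation_cytoplasmic" %in% tr$events$event)
  expect_true("activation_nuclear" %in% tr$events$event)
})

test_that("state invariants hold along wild-type trajectories", {
  tr <- wt_cell()$trajectories[[1]]
  st <- tr$state
  expect_true(all(st[, "A_n"] <= st[, "C_n"] + 1e-9))
  expect_true(all(st[, "A_c"] <= st[, "C_c"] + 1e-9))
  expect_true(all(st[, c("C_n", "C_c", "A_n", "A_c")] >= 0))
  pf <- st[, grep("^[pf]_", colnames(st)), drop = FALSE]
  expect_true(all(pf >= 0 & pf <= 1))
  ## length non-decreasing, constant after elongation stop
  expect_true(all(diff(st[, "L"]) >= -1e-12))
  t_stop <- event_time(tr, "elongation_stop")
  expect_equal(stats::sd(st[tr$time > t_stop + 0.2, "L"]), 0)
})

test_that("event chain is ordered: activation, export, cytoplasmic, exit", {
  tr <- wt_cell()$trajectories[[1]]
  act_n <- event_time(tr, "activation_nuclear")
  exp_on <- event_time(tr, "export_onset")
  act_c <- event_time(tr, "activation_cytoplasmic")
  deg <- event_time(tr, "degradation_onset")
  expect_true(act_n <= exp_on)
  expect_true(exp_on < act_c)
  expect_true(act_n < deg)
})

test_that("mass is conserved: volume-weighted total follows synthesis minus degradation", {
  tr <- simulate_trajectory(default_wt(), list(), duration = 150,
                            dt_sim = 0.1)
  phi <- tr$params$phi_n
  M <- phi * tr$state[, "C_n"] + (1 - phi) * tr$state[, "C_c"]
  t_stop <- event_time(tr, "elongation_stop")
  t_deg <- event_time(tr, "degradation_onset")
  growing <- tr$time < t_stop
  kd <- tr$params$k_deg_basal +
    ifelse(tr$time >= t_deg, tr$params$k_deg_max, 0)
  ## per-step increment of M against the scalar balance ODE (transport
  ## between compartments must cancel exactly)
  n <- length(M)
  rhs <- phi * tr$params$k_syn * growing - kd * M
  dM <- diff(M)
  pred <- 0.1 * (rhs[-n] + rhs[-1]) / 2
  ## ignore the steps containing a switch discontinuity
  sw <- sort(unique(c(findInterval(tr$events$time, tr$time),
                      findInterval(t_stop, tr$time))))
  keep <- setdiff(seq_len(n - 1L), c(sw - 1L, sw, sw + 1L))
  expect_lt(max(abs(dM[keep] - pred[keep])), 1e-6)
})

test_that("trajectories are bit-identical given the same seed and config", {
  a <- simulate_population(default_wt(), default_sensors(), n_cells = 2,
                           seed = 42, duration = 120)
  b <- simulate_population(default_wt(), default_sensors(), n_cells = 2,
                           seed = 42, duration = 120)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
})

test_that("a too-coarse integration step is refused with a suggestion", {
  expect_error(
    simulate_trajectory(default_wt(), default_sensors(), duration = 120,
                        dt_sim = 1),
    "too coarse.*dt_sim")
})

test_that("clamped high-cyclin settling agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- default_wt()
  C <- 1.9  # above the ascending threshold: single high steady state
  lo <- settle_activity(p, "nucleus", C = C, A0 = 0)
  hi <- settle_activity(p, "nucleus", C = C, A0 = C)
  expect_true(lo$converged && hi$converged)
  expect_equal(lo$A, hi$A, tolerance = 1e-6)
  rhs <- function(t, A, parms) {
    sw <- p$nuc; h <- p$h
    kw <- sw$kw_lo + (sw$kw_hi - sw$kw_lo) * sw$K_w^h / (sw$K_w^h + A^h)
    k25 <- sw$k25_lo + (sw$k25_hi - sw$k25_lo) * A^h / (sw$K_25^h + A^h)
    list(k25 * (C - A) - kw * A)
  }
  ode <- deSolve::ode(y = c(A = 0), times = c(0, 4000), func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(lo$A, unname(ode[2, "A"]), tolerance = 1e-6)
})

test_that("populations record failed cells instead of dropping them", {
  pop <- simulate_population(default_wt(), default_sensors(), n_cells = 3,
                             seed = 1, duration = 120, dt_sim = 1)
  expect_equal(nrow(pop$failed), 3L)
  expect_match(pop$failed$reason[1], "too coarse")
})

test_that("zero variability and zero noise give identical cells", {
  pop <- simulate_population(default_wt(), default_sensors(), n_cells = 3,
                             variability = default_variability(0), noise = 0,
                             seed = 5, duration = 120)
  tr <- split(pop$traces[, c("channel", "time_min", "nuclear_mean",
                             "cytoplasmic_mean")], pop$traces$cell_id)
  for (i in 2:3) {
    a <- tr[[1]]; b <- tr[[i]]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("in wild-type populations cytoplasmic activation never precedes nuclear", {
  pop <- wt_cohort()
  ok <- !is.na(pop$truth$activation_cytoplasmic)
  expect_gt(sum(ok), 0)
  expect_true(all(pop$truth$activation_cytoplasmic[ok] >
                    pop$truth$activation_nuclear[ok]))
})

test_that("division reset restarts the cycle for free-running cells", {
  p <- default_wt()
  p$reset_interval <- 15
  tr <- simulate_trajectory(p, list(), duration = 240, dt_sim = 0.1)
  expect_true("division_reset" %in% tr$events$event)
  expect_gte(max(tr$events$cycle), 2L)
})

test_that("config YAML round-trips the full parameter set", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(f, default_wt(), default_sensors(c("NucCDK", "CytCDK")))
  back <- read_config(f)
  expect_equal(back$params, default_wt())
  expect_equal(back$sensors, unname(default_sensors(c("NucCDK", "CytCDK"))),
               ignore_attr = TRUE)
})
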