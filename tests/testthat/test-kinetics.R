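test_that("single-exponential decay recovers the exact half-life", {
  t <- seq(0, 30, by = 2)
  fit <- fit_decay(exp(-t * log(2) / 4), time = t, n_components = 1)
  expect_equal(fit$half_life, 4, tolerance = 1e-6)
  expect_equal(unname(fit$rates), log(2) / 4, tolerance = 1e-6)
  ## half-life identity for one component
  expect_equal(fit$half_life, log(2) / fit$rates)
})

test_that("two-exponential decay recovers parameters and the global half-life", {
  t <- seq(0, 30, by = 1)
  y <- 0.7 * exp(-t * log(2) / 2) + 0.3 * exp(-t * log(2) / 10)
  fit <- fit_decay(y, time = t, n_components = 2)
  expect_equal(sort(fit$rates), sort(log(2) / c(2, 10)), tolerance = 0.01)
  expect_equal(sort(fit$amplitudes), c(0.3, 0.7), tolerance = 0.01)
  ## bisection oracle on the true curve
  g <- function(tt) 0.7 * exp(-tt * log(2) / 2) + 0.3 * exp(-tt * log(2) / 10) - 0.5
  true_hl <- stats::uniroot(g, c(0, 20), tol = 1e-12)$root
  expect_lt(abs(fit$half_life - true_hl), 0.05)
})

test_that("decay fits reject unusable traces", {
  expect_error(fit_decay(exp(-(0:4))), ">= 6")
  expect_error(fit_decay(seq(1, 2, length.out = 10)), "not decreasing")
})

test_that("noisy decay datasets are recovered with small median half-life error", {
  t <- seq(0, 24, by = 2)
  set.seed(21)
  errs <- replicate(100, {
    hl <- stats::runif(1, 2, 8)
    y <- exp(-t * log(2) / hl) * exp(stats::rnorm(length(t), 0, 0.03))
    fit <- fit_decay(y, time = t, n_components = 1)
    abs(fit$half_life - hl) / hl
  })
  expect_lt(median(errs), 0.05)
})

test_that("noiseless four-parameter logistic curves are recovered exactly", {
  d <- c(0, 10, 30, 100, 300, 1000, 3000)
  y <- 0.2 + (1.5 - 0.2) / (1 + (d / 100)^2)
  fit <- fit_dose_response(d, y)
  expect_equal(fit$ic50, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)
  expect_equal(fit$floor, 0.2, tolerance = 1e-6)
  expect_equal(fit$ceiling, 1.5, tolerance = 1e-6)
})

test_that("dose rescaling rescales the fitted IC50 by the same factor", {
  d <- c(0, 10, 30, 100, 300, 1000, 3000)
  y <- 0.1 + 0.9 / (1 + (d / 150)^1.5)
  f1 <- fit_dose_response(d, y)
  f2 <- fit_dose_response(10 * d, y)
  expect_equal(f2$ic50 / f1$ic50, 10, tolerance = 1e-4)
})

test_that("a transition-free dose range is refused", {
  d <- c(0, 1, 2, 3, 4, 5)
  expect_error(fit_dose_response(d, rep(1, 6) + c(0, 1e-9, 0, 0, 0, 0)),
               "transition|constant")
})

test_that("simulated sensor dose-response curves order sensitivities correctly", {
  sens <- default_sensors(c("NucCDK", "CytCDK", "CytCDKv2"))
  ## each sensor reads its own compartment's mitotic activity scale
  act <- c(NucCDK = 1.4, CytCDK = 0.2, CytCDKv2 = 0.2)
  fits <- lapply(names(sens), function(k) {
    dr <- simulate_dose_response(sens[[k]],
                                 doses = c(0, 3, 10, 30, 100, 300, 1000,
                                           3000, 10000),
                                 activity = act[[k]])
    fit_dose_response(dr$dose, dr$readout)
  })
  names(fits) <- names(sens)
  ic50 <- vapply(fits, `[[`, 0, "ic50")
  ## the nuclear sensor is the more CDK-sensitive of the pair: its readout
  ## survives deeper inhibition, i.e. the larger IC50
  expect_gt(ic50["NucCDK"], ic50["CytCDK"])
  expect_lt(abs(ic50["CytCDKv2"] - ic50["NucCDK"]) / ic50["NucCDK"], 0.2)
})

test_that("response lags follow the interpolated departure criterion", {
  t <- seq(0, 60, by = 1)
  y <- ifelse(t <= 30, 1, 1 - 0.5 * (t - 30))  # steep decline from t = 30
  expect_equal(response_lag(y, t, t_perturb = 27), 3, tolerance = 0.2)
  y2 <- ifelse(t <= 30, 1, 0)  # step: departure exactly at the perturbation
  expect_lt(response_lag(y2, t, t_perturb = 30), 0.05)
  flat <- rep(1, length(t))
  out <- response_lag(flat, t, 30)
  expect_true(is.na(out))
})

test_that("acute inhibition: fast decay half-lives, nuclear immediate, cytoplasmic lagged", {
  ia <- inhibition_analysis(default_wt(), default_sensors())
  hl <- vapply(ia$fits, `[[`, 0, "half_life")
  expect_lt(max(hl), 5)
  expect_lt(ia$lags[["NucCDK"]], 1)
  expect_gt(ia$lags[["CytCDK"]], 1.5)
  expect_equal(ia$fits$NucCDK$n_components, 2)
  expect_equal(ia$fits$CytCDK$n_components, 1)
})
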