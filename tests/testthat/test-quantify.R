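test_that("top-fraction estimator matches the sort-and-slice computation", {
  px <- c(rep(10, 3), rep(2, 17))
  m <- compartment_means_topfrac(px, frac = 0.15)
  expect_equal(unname(m), c(10, 2, 3.2))

  ## random pixel sets against an independent sort-based oracle
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    px <- stats::rlnorm(n, 5, 0.6)
    frac <- stats::runif(1, 0.05, 0.5)
    m <- compartment_means_topfrac(px, frac)
    k <- max(1, floor(frac * n + 0.5))
    srt <- sort(px, decreasing = TRUE)
    expect_equal(unname(m["nuclear_mean"]), mean(srt[1:k]))
    expect_equal(unname(m["cytoplasmic_mean"]), mean(srt[-(1:k)]))
    ## ordering and weighted-mean identities
    expect_true(m["nuclear_mean"] >= m["whole_mean"])
    expect_true(m["whole_mean"] >= m["cytoplasmic_mean"])
    expect_equal(unname(m["whole_mean"]),
                 unname((k * m["nuclear_mean"] +
                           (n - k) * m["cytoplasmic_mean"]) / n))
  }
})

test_that("uniform pixels give equal compartment means", {
  m <- compartment_means_topfrac(rep(7, 40))
  expect_equal(unname(m), c(7, 7, 7))
})

test_that("top-fraction estimation refuses tiny pixel sets", {
  expect_error(compartment_means_topfrac(rep(1, 19)), "20")
})

test_that("mask estimator agrees with top-fraction on the same partition", {
  px <- c(rep(10, 3), rep(2, 17))
  m1 <- compartment_means_topfrac(px, 0.15)
  m2 <- compartment_means_masked(px, nuclear_idx = 1:3)
  expect_equal(m1, m2)
  expect_error(compartment_means_masked(px, integer(0)), "empty")
  expect_error(compartment_means_masked(px, seq_along(px)), "complement")
})

test_that("sensor readout directions and background subtraction are correct", {
  tr <- data.frame(cell_id = "c", time_min = c(0, 5), channel = "NucCDK",
                   nuclear_mean = 8, cytoplasmic_mean = 4, whole_mean = 4.6)
  s <- compartment_series(tr, "c", "NucCDK")
  expect_equal(sensor_readout(s, background = 2)$readout, c(1/3, 1/3))
  expect_equal(sensor_readout(s, kind = "CytCDK", background = 2)$readout,
               c(3, 3))
})

test_that("non-positive denominators become missing values with a warning", {
  tr <- data.frame(cell_id = "c", time_min = c(0, 5), channel = "NucCDK",
                   nuclear_mean = c(8, 3), cytoplasmic_mean = 4,
                   whole_mean = 4.6)
  s <- compartment_series(tr, "c", "NucCDK")
  expect_warning(ro <- sensor_readout(s, background = 3), "non-positive")
  expect_true(is.na(ro$readout[2]))
  expect_false(is.na(ro$readout[1]))
})

test_that("min-max normalization: examples, idempotence, affine invariance", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1, 0.5)
  expect_equal(normalize_minmax(x), x)  # already normalized: unchanged
  set.seed(3)
  for (i in 1:10) {
    y <- stats::rnorm(30)
    a <- stats::runif(1, 0.1, 50); b <- stats::rnorm(1, 0, 10)
    expect_equal(normalize_minmax(a * y + b), normalize_minmax(y),
                 tolerance = 1e-12)
    expect_true(all(normalize_minmax(y) >= 0 & normalize_minmax(y) <= 1))
  }
  expect_error(normalize_minmax(rep(1, 5)), "constant")
})
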