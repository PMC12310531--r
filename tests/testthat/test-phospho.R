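test_that("site filtering keeps late single-compartment sites and reports drops", {
  tab <- data.frame(
    site_id = paste0("s", 1:5),
    compartment = c("nucleus", "cytoplasm", "nucleus", "nucleus;cytoplasm",
                    "SPB"),
    class = c("late", "late", "early", "late", "late"),
    t_0 = 0, t_1 = 0.5, t_2 = 1)
  kept <- load_filter_sites(tab)
  expect_equal(nrow(kept), 3L)
  expect_equal(attr(kept, "n_dropped_early"), 1L)
  expect_equal(attr(kept, "n_dropped_multi"), 1L)
  ## idempotent
  again <- load_filter_sites(kept)
  expect_equal(nrow(again), 3L)
  expect_error(load_filter_sites(tab[0, ]), "empty")
  expect_error(load_filter_sites(data.frame(a = 1)), "missing")
})

test_that("generated default tables carry the configured per-compartment counts", {
  ph <- generate_phospho_dataset(seed = 3)
  kept <- load_filter_sites(ph)
  counts <- table(kept$compartment)
  expect_equal(unname(counts[c("nucleus", "cytoplasm",
                               "cytoplasmic_periphery", "nuclear_envelope",
                               "SPB")]),
               c(45L, 41L, 27L, 20L, 7L), ignore_attr = TRUE)
  expect_gt(nrow(ph), nrow(kept))  # decoys present before filtering
})

test_that("noiseless sites are timed exactly and compartment order is recovered", {
  cfg <- phospho_gen_config(noise_sd = 0)
  ph <- load_filter_sites(generate_phospho_dataset(cfg, seed = 5))
  timing <- compartment_change_times(ph)
  merged <- merge(timing$sites[, c("site_id", "change_time")],
                  ph[, c("site_id", "true_change_time")])
  expect_lt(max(abs(merged$change_time - merged$true_change_time)),
            0.5 / 20 + 1e-9)
  s <- timing$summary
  nuc <- s$mean[s$compartment == "nucleus"]
  expect_true(all(nuc < s$mean[s$compartment != "nucleus"]))
  ## the zero-variability compartments carry the flag
  expect_true(all(s$zero_variance[s$compartment %in%
                                    c("cytoplasmic_periphery", "SPB")]))
  expect_equal(s$sem[s$compartment == "SPB"], 0)
})

test_that("impossible change-time draws fail after bounded retries", {
  cfg <- phospho_gen_config()
  cfg$compartments$mean_t[1] <- 0.5
  cfg$compartments$sd_t[1] <- 60   # essentially never inside (0, 1)
  expect_error(generate_phospho_dataset(cfg, seed = 1), "100 attempts")
})

test_that("left-tailed Welch test matches hand computation and symmetry", {
  res <- welch_left_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, (2 - 5) / sqrt(2 / 3))  # -3.674
  expect_equal(res$df, 4)
  expect_equal(res$p, stats::pt((2 - 5) / sqrt(2 / 3), 4))
  expect_equal(res$p, 0.0107, tolerance = 1e-2)

  same <- welch_left_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  fwd <- welch_left_tailed(c(1, 2, 4, 3), c(2, 5, 4, 7))
  rev <- welch_left_tailed(c(2, 5, 4, 7), c(1, 2, 4, 3))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, 1 - rev$p)
})

test_that("Welch test agrees with t.test and an integrated CDF oracle", {
  set.seed(9)
  for (na in c(3, 7, 20)) for (nb in c(3, 12)) for (shift in c(-1, 0, 0.5)) {
    a <- stats::rnorm(na)
    b <- stats::rnorm(nb, shift, 1.7)
    mine <- welch_left_tailed(a, b)
    ref <- stats::t.test(a, b, alternative = "less", var.equal = FALSE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    ## numerically integrated t density as an independent CDF oracle
    dens <- function(x) (1 + x^2 / mine$df)^(-(mine$df + 1) / 2)
    norm <- stats::integrate(dens, -Inf, Inf)$value
    p_num <- stats::integrate(dens, -Inf, mine$t)$value / norm
    expect_equal(mine$p, p_num, tolerance = 1e-6)
  }
})

test_that("zero-variance groups take the flagged degenerate path", {
  expect_warning(res <- welch_left_tailed(c(1, 1, 1), c(2, 2, 2)),
                 "zero variance")
  expect_true(res$zero_variance)
  expect_equal(res$p, 0)
  expect_warning(res2 <- welch_left_tailed(c(3, 3), c(2, 2, 2)))
  expect_equal(res2$p, 1)
})

test_that("IC50 is uncorrelated with timing in the generator, and edge cases error", {
  ph <- load_filter_sites(generate_phospho_dataset(
    phospho_gen_config(n_early = 0, n_multi = 0), seed = 12))
  timing <- compartment_change_times(ph)
  res <- ic50_timing_correlation(timing$sites)
  expect_lt(abs(res$r), 0.2)
  expect_gt(res$p, 0.05)
  expect_gte(res$n, 100)

  perfect <- data.frame(ic50 = 10^(1:6), change_time = (1:6) / 10)
  expect_equal(ic50_timing_correlation(perfect)$r, 1, tolerance = 1e-12)
  expect_error(ic50_timing_correlation(perfect[1:4, ]), ">= 5")
  const <- data.frame(ic50 = rep(10, 6), change_time = (1:6) / 10)
  expect_error(ic50_timing_correlation(const), "constant")
})

test_that("the pipeline recovers nucleus-first ordering with significant left tails", {
  hits <- vapply(1:30, function(s) {
    ph <- load_filter_sites(generate_phospho_dataset(seed = 1000 + s))
    timing <- compartment_change_times(ph)
    cmp <- compare_compartments(timing, reference = "nucleus")
    all(cmp$p < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
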