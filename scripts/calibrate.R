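#!/usr/bin/env Rscript

## Calibration harness for the shipped default configurations.
##
## Simulates the standard study conditions (free-running, block-and-release
## and acute-inhibition cohorts) and prints the emergent timing statistics
## that the defaults were calibrated to.  Used interactively while fixing
## the values in default_wt()/default_af()/default_sensors(); kept in the
## repository so the calibration is reproducible:
##
##   Rscript scripts/calibrate.R [--seed <int>] [--quick]

suppressPackageStartupMessages(library(mitoclock))

args <- commandArgs(trailingOnly = TRUE)
seed <- {
  i <- which(args == "--seed")
  if (length(i) == 1 && i < length(args)) as.integer(args[i + 1]) else 1L
}
quick <- "--quick" %in% args

n_free <- if (quick) 30 else 100
n_exp <- if (quick) 30 else 76

wt <- default_wt(); af <- default_af()
sensors <- default_sensors()
t0 <- proc.time()[3]

pop <- simulate_population(wt, sensors, n_cells = n_free, seed = seed,
                           duration = 170)
ds <- cohort_delay_summary(pop)
t9 <- cohort_threshold_delay(pop, 0.1)$mean
t10 <- cohort_threshold_delay(pop, 0.75)$mean

pop8 <- simulate_population(wt, sensors, n_cells = n_exp, seed = seed + 1,
                            duration = 170)
t8 <- cohort_export_interval(pop8)$mean

pr_wt <- default_block_release(wt)
pop4 <- simulate_population(wt, sensors, n_cells = 18, seed = seed + 2,
                            protocol = pr_wt,
                            duration = pr_wt$t_release + 60)
t4 <- cohort_onset_difference(pop4)$mean

pr_af <- default_block_release(af)
pop5 <- simulate_population(af, sensors, n_cells = 30, seed = seed + 3,
                            protocol = pr_af,
                            duration = pr_af$t_release + 70)
t5 <- cohort_onset_difference(pop5)$mean

ia <- inhibition_analysis(wt, sensors)

cat(sprintf("elapsed %.1f s (seed %d)\n", proc.time()[3] - t0, seed))
cat(sprintf("change-point delay mean        %6.2f min (n = %d)  [5-10]\n",
            ds$mean, ds$n))
cat(sprintf("WT block-release onset diff    %6.2f min            [~6]\n", t4))
cat(sprintf("AF block-release onset diff    %6.2f min            [~13]\n", t5))
cat(sprintf("max decay half-life            %6.2f min            [<5]\n",
            max(vapply(ia$fits, `[[`, 0, "half_life"))))
cat(sprintf("CytCDK inhibition lag          %6.2f min            [~3]\n",
            ia$lags[["CytCDK"]]))
cat(sprintf("activation-to-export interval  %6.2f min            [~5]\n", t8))
cat(sprintf("two-curve delay at 10%% level   %6.2f min            [~12]\n", t9))
cat(sprintf("two-curve delay at 75%% level   %6.2f min            [~7]\n", t10))
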