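# mitoclock

Tools for asking *where* and *when* mitotic CDK (cyclin-dependent kinase)
activity switches on in a single cell.  In fission yeast, cyclin B–CDK
accumulates in the nucleus through G2; at mitotic onset the nuclear
Y15-phosphorylation feedback switch (Wee1/Cdc25) flips, nuclear CDK activity
rises abruptly, part of the active complex is exported to the cytoplasm, and
cytoplasmic CDK activity follows minutes later.  `mitoclock` packages the
full quantitative workflow around that question:

* a **mechanistic synthetic-data generator** — a two-compartment bistable
  cyclin–CDK oscillator with translocation-biosensor kinetics, perturbation
  protocols (G2 block-and-release, acute inhibition), a synthetic timelapse
  image renderer, and a phosphosite timecourse generator — so every analysis
  stage can be tested against known ground truth;
* **compartment quantification**: the top-15%/bottom-85% pixel estimator of
  nuclear/cytoplasmic mean intensity, the nuclear-mask estimator, sensor
  ratio readouts (C/N and N/C) and min–max normalisation;
* **activation timing**: Savitzky–Golay smoothing, pre-peak cropping and
  exact dynamic-programming piecewise-linear change-point detection to call
  mitotic activation, cyclin-export onset and elongation stop, with paired
  nuclear→cytoplasmic delay statistics;
* **phase-plane analysis**: single-cell (cyclin–CDK concentration, activity)
  orbits, shoelace areas, hysteresis gaps, activation thresholds and
  collapse classification;
* **kinetics fits**: one/two-exponential sensor decay after acute CDK
  inhibition, four-parameter logistic dose–response curves, and
  perturbation response lags;
* **phosphosite timing**: filtering of annotated phosphosite timecourses,
  per-site rate-change times, left-tailed Welch comparisons between
  compartments, and the IC50–timing correlation.

## The model in brief

Per compartment `i ∈ {n, c}` the generator integrates (RK4, 0.1 min step)

    dC_n/dt = k_syn·1{growing} − (k_exp(t) + k_deg(t))·C_n
    dC_c/dt = φ/(1−φ)·k_exp(t)·C_n − k_deg(t)·C_c
    dA_i/dt = ι(t)·k25_i(A_i)·(C_i − A_i) − kw_i(A_i)·A_i + transport terms

where `kw_i(A)` falls and `k25_i(A)` rises with active CDK (Hill switches) —
a strongly bistable nucleus with a high cyclin threshold and a weakly
switched cytoplasm with a low one — and `ι(t)` is the inhibitor schedule.
Export and APC/C degradation are threshold-plus-lag switches on the
effective activity `ι·A`; exported complexes carry their phosphostate.
Sensors follow `dp/dt = k_on·ι·A_host·(1−p) − k_off·p` with localisation
relaxing to a linear target of `p` (after a transport transit delay for the
cytoplasmic scaffold).  See the methods vignette
(`vignettes/mitoclock-methods.Rmd`) for assumptions, defaults and their
rationale.

## Worked example

```r
library(mitoclock)

pop <- simulate_population(default_wt(), default_sensors(),
                           n_cells = 20, seed = 1, duration = 170)
ds <- cohort_delay_summary(pop)
print(ds)
#> delay_summary: n = 20 cells (excluded 0), mean 8.25 min, sd 3.35 min
#>   histogram (bin width 5 min):
#>  [5,10) [10,15]
#>       9      11
```

Per cell, the NucCDK (cytoplasmic/nuclear ratio) and CytCDK
(nuclear/cytoplasmic ratio) readouts are smoothed, cropped to the 12
acquisition frames before their peak, and segmented into two straight lines
by exact dynamic programming; the call is the first frame of the steeper
segment.  The mean paired delay above says that in this simulated cohort
cytoplasmic CDK activation is called 8.25 minutes after nuclear activation
— the nucleus-first ordering with a delay in the reported 5–10 min range.

```r
ia <- inhibition_analysis(default_wt())
ia$fits$CytCDK$half_life   # 1.65 min readout decay after full inhibition
round(ia$lags, 2)          # NucCDK 0.00, CytCDK 2.52 min response lag
```

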