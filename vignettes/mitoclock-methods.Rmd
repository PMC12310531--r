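---
title: "Compartment-resolved CDK activation timing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved CDK activation timing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoclock)
```

# The scientific problem

A eukaryotic cell entering mitosis must coordinate CDK activation across
its compartments.  In fission yeast the picture this package is built
around is: cyclin B–CDK accumulates in the nucleus during G2; the nuclear
Y15 feedback switch (Wee1-like inhibition, Cdc25-like activation, both
themselves CDK-regulated) makes nuclear activity bistable with a high
cyclin threshold; when the switch fires, part of the active complex is
exported to the cytoplasm, where a much lower threshold lets cytoplasmic
CDK activate on the imported material — so nuclear activation precedes
cytoplasmic activation by minutes, and the nuclear phase orbit encloses a
far larger region of (cyclin, activity) space than the cytoplasmic one.

Because raw single-cell imaging data of this kind are rarely shareable at
analysis-development time, the package pairs every analysis stage with a
mechanistic synthetic-data generator, so that each estimator can be tested
against exact ground truth, and the full pipeline can be exercised
end-to-end on cohorts whose true event times are known.

# The two-compartment oscillator

## Equations

With `φ` the nuclear volume fraction and `w = φ/(1−φ)`, concentrations
`C_n, C_c` (total cyclin–CDK) and `A_n, A_c` (active, i.e.
Y15-dephosphorylated) evolve as

$$\frac{dC_n}{dt} = k_{syn}\,\mathbf 1\{\text{growing}\} - (k_{exp}(t) + k_{deg}(t))\,C_n,$$
$$\frac{dC_c}{dt} = w\,k_{exp}(t)\,C_n - k_{deg}(t)\,C_c,$$
$$\frac{dA_i}{dt} = \iota(t)\,k_{25,i}(A_i)(C_i - A_i) - k_{w,i}(A_i)\,A_i + \text{transport} - \text{degradation},$$

with Hill-switched arms
`k_w(A) = k_w^{lo} + (k_w^{hi}-k_w^{lo})\,K_w^h/(K_w^h + A^h)` and
`k_{25}(A) = k_{25}^{lo} + (k_{25}^{hi}-k_{25}^{lo})\,A^h/(K_{25}^h + A^h)`.
The `w` weighting makes export conserve molecule number while states stay
concentrations; exported complexes carry their phosphostate, so the
cytoplasmic activity is fed directly by import of active material.
`ι(t) ∈ [0,1]` is the inhibitor schedule (an ATP-analogue on an
analogue-sensitive kinase, modelled as a multiplicative activity factor).
A slow constitutive turnover `k_{deg}^{basal}` acts on both compartments at
all times; it matters only for cells that arrest with high activity, whose
readouts would otherwise have no defined maximum.

Integration is fixed-step RK4 at `dt_sim = 0.1` min; threshold crossings
are located by linear interpolation between steps; a step producing a
state change above 20% of the system's concentration scale aborts with a
suggested smaller step.

## Event switches

Export, APC/C-driven degradation and the ground-truth activation events
are **threshold-plus-lag switches on the effective activity** `ι·A`, not
additional ODEs: the data this emulates report timing relationships, not
mechanisms, and a catalytically inhibited kinase cannot phosphorylate the
targets that execute these transitions regardless of its Y15 state.
Export is a transient wave: it starts `τ_exp` after the nuclear effective
activity crosses `θ_act` and lasts `exp_duration` minutes, leaving a
nuclear remnant — the observed nuclear cyclin trace falls during the wave
and then plateaus until degradation.  The cytoplasmic activation event
uses the *amount-equivalent* threshold `θ_act·w`: the same number of
active molecules, diluted into the larger cytoplasmic volume.  Elongation
stops `τ_stop` after nuclear activation.

Mutant modes: `AF` (Y15 sites unphosphorylatable) pins `A ≡ C`, removing
the switch entirely; `HPM` (cyclin hydrophobic-patch mutant, never reaches
the spindle pole body) forces `k_exp = 0`, so the cytoplasm stays in a
G2-like state while the nucleus activates — the cell arrests.

## Sensors

A sensor is a unit substrate pool with phosphorylated fraction
`dp/dt = k_on·ι·A_{host}·(1-p) - k_off·p` and nuclear localisation
fraction `f` relaxing at rate `k_loc` to a target linear in `p`
(decreasing for the nuclear sensor, which leaves the nucleus when
phosphorylated; increasing for the cytoplasmic ones).  The cytoplasmic
scaffold additionally carries a transport transit delay `τ_loc ≈ 2` min:
its localisation machinery sees the phosphostate as it was `τ_loc` minutes
ago.  This single dead-time parameter is what reproduces the observed
behaviour that, after acute inhibition, the nuclear readout reacts
immediately while the cytoplasmic readout keeps its prior course for about
three minutes — no combination of first-order rates can produce a
multi-minute dead time while keeping the decay half-life under five
minutes.  Readouts are compartment mean-intensity ratios
(cytoplasmic/nuclear for `NucCDK`, nuclear/cytoplasmic for the others), so
all readouts increase with CDK activity; the `N/C` direction for the
cytoplasmic sensors is a package convention (the source conventions leave
it open).

Sensitivity is the ratio `k_on/k_off` against the host compartment's
activity scale: the nuclear sensor is the most CDK-sensitive, the
first-generation cytoplasmic sensor markedly less so, and the
second-generation one (`CytCDKv2`) restores nuclear-like sensitivity.  In
an inhibitor dose–response, a *more* sensitive sensor keeps its readout
until deeper inhibition, i.e. fits a *larger* IC50 — the package's tests
assert that ordering.

## Calibration and what the defaults are

All defaults ship in `default_wt()`, `default_af()`, `default_hpm()` and
`default_sensors()`, and were fixed once with `scripts/calibrate.R` so
that the emergent statistics of simulated cohorts land on the
experimentally reported timing scale: a 5–10 min change-point delay
between nuclear and cytoplasmic activation calls (free-running cells),
about 6 min between sensor-rise onsets after a wild-type G2
block-and-release and about 13 min in the feedback-abolished background,
called nuclear activation about 5 min before called cyclin-export onset,
two-curve threshold delays of about 12 min (10% level) and 7 min (75%
level), decay half-lives under 5 min and a ~3 min cytoplasmic response
lag after acute inhibition.  The calibration dials were the mechanistic
rates and thresholds; the study conditions — 5-min acquisition interval,
lognormal cell-to-cell rate variability at CV 0.10, multiplicative
measurement noise at CV 0.03, cohort sizes — were fixed a priori and
never used as dials.

Three deliberate configuration asymmetries.  First, the AF configuration
is a distinct strain: it synthesises cyclin–CDK more slowly (longer
cycle), which is also what gives its phase orbits enough sample points to
classify as collapsed at a 5-min acquisition interval.  Second, the
block-and-release protocols use an exponential inhibitor washout (time
constant 7.5 min); the wild-type hold accumulates cyclin far beyond the
activation threshold, so the Y15 switch fires early in the washout, while
the AF hold stops at ~22% above threshold, so the feedback-free effective
activity crosses the threshold only late in the washout — this is the
package's account of why the feedback-abolished onset difference roughly
doubles.  Third, the HPM cohorts are acquired at 10-min intervals over a
long window, as arrested cells are in practice, which is also what makes
their readout maximum well defined.

## What the generator does and does not emulate

It emulates: gradual G2 readout rise followed by an abrupt mitotic rise;
nuclear-before-cytoplasmic activation with minutes of delay; a transient
cyclin export wave at mitotic onset; AF-linearised traces; HPM arrest
without cytoplasmic activation; per-cell rate variability and
multiplicative measurement noise; traces cropped at division.  It does not
emulate: stochastic chemical kinetics, spatial gradients or diffusion,
explicit Wee1/Cdc25 protein dynamics, phosphatase branches beyond a
constant sensor dephosphorylation rate, photobleaching, segmentation or
tracking errors, or 3-D imaging.  Passing tests on generated cohorts
therefore demonstrates correctness of the estimators under the model's
assumptions, not robustness to every artefact of real microscopy.

# Analysis conventions

## Compartment quantification

The top-fraction estimator takes the brightest `k = max(1, round(0.15·N))`
in-cell pixels (half-up rounding, ties broken towards brighter-or-equal
pixels in stable order) as the nuclear proxy — the nucleus occupies about
15% of the projected cell area — and the rest as cytoplasm; the identity
`whole = (k·nuclear + (N−k)·cytoplasmic)/N` holds exactly.  Background is
an optional scalar (per-frame median of non-cell pixels when images are
available) subtracted from both compartments before ratios are formed;
non-positive denominators become missing values and gaps are never
interpolated.

## Rate-change calling

The pipeline is smooth → crop → one-change piecewise-linear fit:

* **Smoothing**: Savitzky–Golay, window 5, order 2 ("light"); ends are
  handled by truncated-window polynomial fits.  Detection runs on the
  smoothed trace; figures should show raw data.
* **Cropping**: the 12 acquisition frames before the readout maximum
  (earliest maximum on ties), a window configurable in the 10–15 range.
* **Segmentation**: exact dynamic programming over independent per-segment
  straight-line fits, minimum segment length 3 (a line needs two points; a
  third guards degenerate fits).  Change points are reported as the first
  frame of the post-change segment, at acquisition-grid resolution.  When
  the number of changes is left free, the penalty default is
  `2·σ̂²·log(n)` with `σ̂²` from first differences; the headline pipeline
  fixes one change.
* **Acceptance**: post-change slope positive and above the pre-change
  slope; fractional RSS improvement of the two-line fit at least 0.6; and
  a signal-to-noise requirement — the accumulated slope change over the
  post segment must exceed 8 noise standard deviations, with the noise
  scale estimated robustly from the raw trace's first differences.  The
  SNR rule is what keeps changeless noisy traces (e.g. the cytoplasmic
  channel of arrested HPM cells) from yielding spurious calls: because
  the analysis window is anchored at the trace maximum, a single break on
  pure noise can explain much of the window's residual, but it
  accumulates only a few noise standard deviations, whereas a genuine
  mitotic switch accumulates tens.  If the best single change is a slope
  *decrease*, the window overran the true peak into an arrest plateau;
  the window is re-anchored at the detected break and re-fitted once.
* Cohort analyses include only cells whose mitotic exit fell inside the
  acquisition (as one would analyse only cells that divided within the
  timelapse), except in the HPM background, where cells arrest by design.

Export onset is called with the same machinery on the nuclear cyclin
trace around its maximum (accepted change: rise to decline), with minimal
smoothing (window 3, order 1): the directly measured intensity channel
carries less relative noise than a ratio of two noisy means, and heavier
smoothing would push the detected break one frame past the peak.
Elongation stop is called on the length trace anchored at the trace end
(accepted change: positive slope to near-zero, post-slope below a quarter
of the pre-slope in magnitude).

## Delays and histograms

Paired delays are `t_cytoplasmic − t_nuclear` over cells with both calls;
histograms use left-closed bins of one acquisition interval, right-open
except for the last bin.  Two-curve threshold delays min–max normalise
both readouts and take the difference of first upward level crossings
(linear interpolation); the "near the beginning of the rapid rise"
measurement uses a 0.1 level — a declared convention, since no printed
threshold defines "near the beginning" — and the near-peak one uses 0.75.
Block-and-release onset differences use the first departure from the
pre-release baseline by 5% of the dynamic range, upward only (the 5%
criterion sits far above single-frame noise; the 1% default of
`response_lag()` is appropriate for noiseless perturbation analyses).
After an acute *inhibition* only downward departures count as a response:
a rise inherited through the cytoplasmic sensor's transit delay is
momentum, not response.

## Phase orbits

Orbits pair the concentration and activity traces pointwise in
acquisition order after light smoothing (window 7 — phase plots tolerate
slightly heavier smoothing than change-point detection, which must
preserve the break).  The activity axis is min–max normalised as phase
plots are drawn; the concentration axis may be kept in intensity units,
which is how the compartment comparisons (area, activation threshold) are
made.  The area is
the absolute shoelace sum after closing last→first (signed cancellation
for self-intersections).  The ascending branch runs to the activity
maximum; the activation threshold is the concentration at the largest
single-step activity increase on that branch, the hysteresis gap the
maximum over concentration bins (width 0.05) of the descending-minus-
ascending mean activity difference, and linearity the total-least-squares
index `1 − λ₂/λ₁` from the principal components (1 for a line, 0 for an
isotropic cloud; well defined even for vertical lines, where a Pearson
correlation would not be).  An orbit is *collapsed* when area < 0.05 and
linearity > 0.95 — declared numerical definitions for a phenomenon the
source material treats qualitatively, shipped as config defaults and
reported alongside results.

## Kinetics fits

Decay fits are nonlinear least squares over `Σ aᵢ·exp(−kᵢt)` from
multi-start initials (rates log-spaced over `[10⁻², 1]` min⁻¹); the
global half-life is the time for the fitted curve to reach half its
fitted initial value — `ln 2/k` exactly for one component, solved
numerically for two, since a single reported bound must summarise two
rates.  Sensor readouts decay to a nonzero floor (the unphosphorylated
localisation equilibrium), so the inhibition analysis subtracts the
post-decay baseline and crops at the post-inhibition maximum before
fitting.  Dose–response curves are four-parameter logistics
`floor + (ceiling−floor)/(1+(d/IC50)^h)`; dose zero contributes the
ceiling directly and needs no log-axis shift at fit time.

## Phosphosite timing

Only late-phase, single-compartment sites are analysed (multi-compartment
annotations are `;`-separated); per-site rate-change times use the same
one-change fit over the full normalised timecourse.  Compartment
comparisons use the left-tailed unequal-variance Welch test computed in
closed form, with a flagged degenerate path when both groups have zero
variance (the generator deliberately ships two zero-variability
compartments so that path is exercised) — `p` is then 0 or 1 by the sign
of the mean difference, with a warning, rather than a silent `NaN`.  The
IC50–timing correlation is Pearson on `log10(IC50)` (dose scales are
multiplicative), with a rank-based alternative switchable by argument.

# Problem sizes and determinism

The shipped test-suite and acceptance cohorts use 100 free-running cells
(170 min at 0.1-min integration steps, 5-min acquisitions), 76 cells for
the export interval, 18/30 cells for the block-and-release protocols, 100
HPM cells at 10-min acquisitions, 100-dataset decay-recovery and
40-cohort phosphosite-ordering property runs; each simulated cohort
completes in well under a minute per hundred cells on one CPU.  All
randomness flows from a single integer seed per cohort (cell-level seeds
are drawn from it), so identical seeds and configurations give
bit-identical outputs.

# Known limitations

* The ODE is a minimal Y15-switch skeleton: no explicit Wee1/Cdc25
  species, no Greatwall/PP2A branch, no spindle-pole-body mechanism beyond
  the binary export switch; the coupling of spindle-pole localisation to
  export is a stand-in threshold-plus-lag rule.
* Whether degradation should begin strictly after spindle assembly (an
  unmodelled event) is approximated by the cytoplasmic activity threshold
  with a lag.
* Grid effects: calls are reported at acquisition resolution, so cohort
  mean delays carry a quantisation component comparable to half the
  acquisition interval.
* The renderer draws a single plane (analyses consume projected images), a
  centred axial nuclear disk, and Poisson-plus-Gaussian detection; it does
  not simulate z-stacks, bleaching or segmentation error.
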