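## Shared fixtures are built in code, once per test run, and cached here.
.fixtures <- new.env(parent = emptyenv())

## Small wild-type cohort reused by several timing tests (cells complete
## mitosis well inside the duration at the default synthesis rate).
wt_cohort <- function(n = 20, seed = 101, duration = 150) {
  key <- sprintf("wt_%d_%d_%d", n, seed, duration)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_population(
      default_wt(), default_sensors(), n_cells = n, seed = seed,
      duration = duration)
  .fixtures[[key]]
}

## One noiseless, variability-free wild-type cell.
wt_cell <- function(duration = 150) {
  if (is.null(.fixtures$wt_cell))
    .fixtures$wt_cell <- simulate_population(
      default_wt(), default_sensors(), n_cells = 1,
      variability = default_variability(0), noise = 0, seed = 7,
      duration = duration)
  .fixtures$wt_cell
}

## Brute-force piecewise-linear segmentation: enumerate all admissible
## breakpoint sets of size <= kmax and minimise the total per-segment OLS
## residual.  Independent of the dynamic-programming implementation.
brute_force_segmentation <- function(y, kmax, min_seg = 3) {
  n <- length(y)
  seg_rss <- function(i, j) {
    x <- i:j
    fit <- stats::lm.fit(cbind(1, x), y[i:j])
    sum(fit$residuals^2)
  }
  best <- list(cost = Inf, cps = integer(0))
  consider <- function(cps) {
    starts <- c(1L, cps)
    ends <- c(cps - 1L, n)
    if (any(ends - starts + 1L < min_seg)) return()
    cost <- sum(mapply(seg_rss, starts, ends))
    if (cost < best$cost - 1e-12) best <<- list(cost = cost, cps = cps)
  }
  consider(integer(0))
  if (kmax >= 1) for (c1 in seq_len(n)) consider(c1)
  if (kmax >= 2) for (c1 in seq_len(n)) for (c2 in seq_len(n))
    if (c2 > c1) consider(c(c1, c2))
  best
}

## Ramp trace with a known slope break, on a uniform grid.
flat_then_ramp <- function(t, t_break, slope = 0.2, base = 1) {
  base + slope * pmax(t - t_break, 0)
}
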