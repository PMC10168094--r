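---
title: "Methods: lagged climate sensitivity of boreal productivity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged climate sensitivity of boreal productivity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealsens)
```

# Scope and model

`borealsens` classifies, cell by cell on a coarse consistent grid, how
annual forest-productivity indices respond to summer temperature and
precipitation of the current (lag 0) and previous (lag 1) year. The three
index types it is designed around behave differently: tree-ring width
indices (RWI) integrate carbon storage and drought carry-over and show
lag-1 responses (negative to previous-summer temperature, positive to
previous-summer precipitation in water-limited regions); satellite
greenness composites show the same pattern more weakly; modelled net
primary production (NPP) responds mostly to the current summer, positively.
The package's job is to make that contrast measurable, reproducible, and
testable against data with known structure.

The statistical engine is deliberately classical: per-cell Pearson
correlation with a two-sided t-test on $n-2$ degrees of freedom, a fixed
per-cell significance level $\alpha = 0.05$, and counts of significant
positive/negative cells per variable. **No multiple-testing correction is
applied across cells** — the output is a response-function map, not a
family-wise inference; users should read the percentage tables as
descriptive summaries of the correlation field. With the default 25-year
window the critical $|r|$ is about $0.396$.

# Chronology building

Raw ring widths (0.01 mm units, Tucson `.rwl` interchange format) are
detrended per tree with a cubic smoothing spline parameterized by its
frequency response. We implement the spline as the discrete
second-difference penalized smoother on the annual grid,
$\hat{x} = (I + \lambda D^\top D)^{-1} y$, whose transfer function is
$H(f) = 1/(1 + 16\lambda\sin^4(\pi f))$. Solving $H = 0.5$ at the cutoff
wavelength (default 128 years) gives $\lambda$ in closed form. This is the
equally spaced form of the cubic smoothing spline with natural boundary
conditions; we verify the parameterization by measuring the realized
amplitude gain on sinusoidal inputs (0.50 at 128 years, $<0.05$ at 8
years, $>0.95$ at 512 years) rather than by matching any particular legacy
implementation, so the filter property — the thing that matters
scientifically — is what is pinned down.

Numerical choices:

* the linear system is symmetric positive definite and solved densely
  (series are at most a few thousand years; no sparse machinery needed);
* the fitted curve is floored at 5% of the series mean before ratio
  division, the standard guard against index blow-ups on near-zero fits; a
  warning reports when the floor engages (it can, on short series with
  strong planted signals);
* series shorter than 10 years are refused.

The ratio index $w_t / \hat{c}_t$ is exactly the right inverse of a
multiplicative (lognormal) growth model, which is also how the synthetic
generator builds trees — so detrending on synthetic data is a clean oracle,
not an approximation. Site chronologies are arithmetic means of tree
indices ("averaging the standardized ring widths" read literally); a Tukey
biweight robust mean (c = 9) is available as an option for users who want
legacy-software behaviour, but is off by default.

Chronology quality uses the expressed population signal,
$\mathrm{EPS} = n\bar r / (n\bar r + (1-\bar r))$, computed once over the
common post-1950 period (not as a running window), with $\bar r$ the mean
pairwise interseries correlation over tree pairs with at least 10
overlapping years. Screening retains sites with $\mathrm{EPS} > 0.85$
(strict), and rejects sites where EPS is undefined (fewer than two usable
trees) as insufficiently replicated. Negative $\bar r$ reports EPS 0. Site
selection applies latitude $> 50^\circ$N strictly, elevation $< 2000$ m
strictly, and last year $\ge 1990$ — the inclusive reading of "ending
after 1990", chosen because chronology end-years are calendar labels and
excluding exactly-1990 would be an arbitrary off-by-one.

# Grid, compositing, windows

The consistent grid defaults to $2.81^\circ$ cells anchored at
$50^\circ$N / $180^\circ$W. No registration is canonical for such grids, so
we fix one and make it configurable; cells are half-open on both axes,
which makes point-in-cell membership a total function (a site on a shared
edge belongs to exactly one cell). Aggregation is by unweighted
center-membership averaging for points and finer grids, and nearest-cell
sampling when the native model grid is as coarse as or coarser than the
target. Area weighting was deliberately left out: at these latitudes and
cell sizes the within-target-cell area variation is second-order to the
site-sampling noise, and center membership keeps the operation exactly
invertible for the test oracles. No land/sea or forest mask is applied —
in practice the analysis universe is restricted to cells that carry
tree-ring data, which is where the comparison is meaningful.

Summer is July only at cell-center latitudes $\ge 67^\circ$N (the Arctic
circle rounded to the conventional value, boundary inclusive) and
June–August from 50 to 67°N. Summer precipitation is the **mean** of
monthly totals, not the sum; correlations are invariant to this scaling,
and outputs are labelled accordingly. Annual NPP is the sum of 12 monthly
values; per-second flux input is converted with true month lengths on a
365-day no-leap calendar (the common coupled-model convention,
configurable).

Correlation windows are 25 years: fixed 1982–2006 for satellite-like and
model-like fields, trailing (last year minus 24 to last year, per cell)
for tree-ring cells whose chronologies end at different dates. Cells with
fewer than the full window of years are excluded; within a window at least
20 of 25 complete pairs are required, else the cell is undefined.

Selections: "strongest correlation" means largest **absolute** $r$ — the
only reading under which a negative response can ever be the strongest —
with exact ties resolved to lag 0, and to temperature in cross-variable
comparisons. The dominant-variable table counts, among
temperature-dominant cells, those whose dominant correlation is
significantly positive/negative (and likewise for precipitation). This is
what separates "temperature matters negatively" (per-variable view) from
"but precipitation matters more" (dominance view): a field where every
cell has a significant negative temperature correlation masked by a larger
precipitation correlation yields 100% `Negative_t` in the first view and
100% precipitation-dominant in the second — an invariant the test suite
checks by brute force.

Histograms use fixed bins of width 0.1 on $[-1, 1]$, half-open with closed
outer edges. Density summaries use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth on a fixed 401-point grid over $[-1, 1]$; neither
choice is canonical in the field, so we picked the most standard ones and
exposed the values. The trapezoid integral of the density is within 1% of
unity for interior-concentrated data; reported peaks ignore local maxima
below 10% of the mode, which suppresses numerical wiggle on flat tails.

# The synthetic generator: what it emulates, and what it does not

The generator exists so that every pipeline stage has a parameter-recovery
test with no external archive. Per cell, interannual summer anomalies are
independent standard Gaussian draws ($z_T$, $z_P$), shared by all summer
months of a year, so the summer composite has an exactly known z-score.
Precipitation anomalies are truncated at zero, with default parameters
(60 ± 12 mm/month around a seasonal cycle) that make truncation
negligible, so z-scores remain well defined — a deliberate simplification
over gamma-like rainfall. Anomalies are independent across years by
default (an AR(1) knob exists, off in all tests): under independence a
target built as $b^\top z + \varepsilon$ has theoretical correlation
$r = b/\sqrt{\sum b^2 + \sigma^2}$ with each anomaly, which is the
closed-form oracle the recovery tests and the acceptance script use.
`noise_sd_for_r()` inverts it.

Trees multiply a negative-exponential age curve
($a e^{-\mathrm{age}/\tau} + c$, defaults 1.5 mm amplitude, 80-year
time constant, 0.5 mm asymptote) by $\exp(\text{signal} + \varepsilon)$
with lognormal tree noise (SD 0.3), quantized to 0.01 mm. The default
study conditions are 30 index years (1977–2006, so the fixed 1982–2006
window and the lag-1 predictor year both fit), two sites of eight trees
per cell, and sensitivity $b_{T1} = -0.6$, $b_{P1} = +0.6$ for the
tree-ring-like target, weaker mixed coefficients for the greenness-like
target, and $b_{T0} = b_{P0} = +0.6$ for the NPP-like target — the
qualitative structure the pipeline is designed to detect, at effect sizes
(theoretical $|r| = 0.6$ with $\sigma = \sqrt{0.28}$) where a 25-year
window has roughly 90% power per cell at $\alpha = .05$.

The NPP-like monthly field spreads each year's annual total over months by
a fixed Gaussian phenology centred on July (SD 1.3 months), keeping winter
months below 5% of the annual sum; it does not emulate model physics,
snow seasons, or ensemble spread beyond an element-wise ensemble mean.
Likewise the greenness-like field is an affine map of the standardized
signal into (0, 1), not a radiative-transfer NDVI: no orbital drift,
no bimonthly maximum-value compositing, no cloud contamination.
Consequently, passing recovery tests demonstrates that the *pipeline*
recovers planted lag/sign/effect-size structure through detrending,
aggregation, compositing, and windowed correlation — it does not
demonstrate anything about real archives, where autocorrelation,
non-stationarity, spatial correlation of climate fields (synthetic cells
are independent), and observation error are all present.

Recovery through the full tree-ring route (widths → spline detrending →
ratio indices → chronology → grid cell → lagged correlation) is tested at
the cell-level effective correlation implied by eight trees of noise 0.3
(about $|r| \approx 0.7$); the exact-theoretical-$|r| = 0.6$ recovery
rates are measured on grid-level index fields, where the closed form holds
exactly by construction.

# Workflow, formats, determinism

`run_pipeline()` executes simulate → chronologies → regrid → composite →
correlate → summarize from one flat YAML/list config (unknown keys are
errors), writing only plain-text artifacts: Tucson `.rwl` files, CSV
tables, long-format CSV gridded fields with a self-describing header line
(NetCDF I/O is available through optional `ncdf4` support), and a manifest
of MD5 checksums headed by the package version and seed. All randomness
derives from the single config seed, and a rerun with the same config
reproduces every checksum bit for bit — the end-to-end determinism test.
A stage failure aborts with the stage name; artifacts of completed stages
are retained. The `report_summary()` function prints the count tables,
dominance tables and density-peak locations from a run directory, and a
thin Rscript wrapper (`inst/scripts/borealsens.R`) exposes `run-all` and
`summarize` for shell use.

Problem sizes throughout the test suite were chosen as the smallest at
which the statistical properties are stable: 1280-year series for filter
gain measurement (edge-trimmed), 200 cells × 25-year windows for recovery
rates (binomial SE ≈ 2 percentage points, comfortably inside the 80% /
15% acceptance margins), 24-cell demo runs for end-to-end checks. The
demo pipeline completes in a few seconds on one CPU.

# Known limitations

* No ARSTAN-style residual/arstan chronology variants, variance
  stabilization, pith-offset or regional-curve standardization.
* No conservative (flux-preserving) regridding and no curvilinear model
  grids; center membership only.
* Growing season is fixed by latitude band, never detected from data.
* Per-cell inference only; no field-significance testing, no partial or
  detrended correlations, no moving-window sensitivity analyses.
* The synthetic climate has no spatial correlation structure, so
  cross-cell count percentages on synthetic data have smaller sampling
  variance than they would on real, spatially coherent fields.
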