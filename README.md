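# borealsens

Lagged climate sensitivity of circumboreal forest productivity indices.

## The problem

Over boreal forests, three very different measurements stand in for "how much
the forest grew this year": tree-ring width index (RWI) chronologies from
field-sampled cores, satellite greenness (NDVI-like) composites, and net
primary production (NPP) simulated by the land carbon components of Earth
system models. A robust feature of the observational indices — and a known
blind spot of models — is a *one-year time lag*: in dry continental regions,
tree growth correlates **negatively with the previous summer's temperature**
and **positively with the previous summer's precipitation**, whereas modelled
NPP responds almost entirely, and positively, to the *current* summer.

`borealsens` implements the full comparison pipeline that detects and
quantifies this contrast, for anyone who wants to run the analysis on their
own chronology/greenness/model archives or study its statistical behaviour
under controlled conditions:

1. **Chronology building** — Tucson `.rwl` parsing, cubic smoothing-spline
   detrending with a 50% frequency cutoff at a 128-year wavelength, ratio
   indices, site averaging, and screening by the expressed population signal
   (EPS > 0.85 over the post-1950 period), with site selection north of
   50°N, below 2000 m, chronologies ending 1990 or later.
2. **Grid harmonization** — a consistent 2.81° × 2.81° half-open grid;
   point chronologies are averaged per cell, finer satellite/model grids are
   averaged by cell-center membership, coarser model grids are sampled at
   cell centers.
3. **Seasonal compositing** — latitude-dependent summer definition (July
   only at ≥ 67°N, June–August between 50°N and 67°N), summer means of
   monthly temperature/precipitation, annual sums of monthly NPP (with
   per-second flux conversion on a no-leap calendar).
4. **Lagged correlation classification** — per-cell Pearson correlations of
   each index with summer temperature and precipitation at lag 0 (current
   year) and lag 1 (previous year) over 25-year windows (fixed 1982–2006,
   or trailing from each tree-ring cell's last year), classified at
   p < .05 into `Positive_t` / `Negative_t` / `Positive_p` / `Negative_p`
   count tables, best-of-lag and dominant-variable selections, fixed-bin
   histograms, and Gaussian-kernel density summaries of strongest
   correlations.
5. **Synthetic data** — a generator with *known* lag structure. Indices are
   built from standardized summer anomalies `z` as
   `b_T0·zT_t + b_T1·zT_(t−1) + b_P0·zP_t + b_P1·zP_(t−1) + ε`, so the
   theoretical per-cell correlation with one climate variable is
   `r = b / sqrt(Σb² + σ²)` and every stage of the pipeline has an exact
   parameter-recovery oracle.

The key statistics, in the field's standard notation:

- spline filter: amplitude response `H(f) = 1 / (1 + 16λ sin⁴(πf))`, with λ
  chosen so `H = 0.5` at the cutoff wavelength;
- `EPS = n·r̄ / (n·r̄ + (1 − r̄))` with `n` trees and mean interseries
  correlation `r̄`;
- per-cell Pearson `r` with two-sided p from `t = r√((n−2)/(1−r²))` on
  `n − 2` df (critical |r| ≈ 0.396 at n = 25, α = .05).

## Worked example

```r
library(borealsens)
out <- file.path(tempdir(), "demo")
run_pipeline(system.file("extdata", "demo_config.yaml", package = "borealsens"),
             out = out)
report_summary(out)
```

prints (4 × 6 cells, 2 sites × 8 trees per cell, years 1977–2006, seed 1):

```
== Significant responses per index and lag (count / % of universe) ==
rwi   lag 0 (n=24): Positive_t 1 (4.2%), Negative_t 0 (0.0%), Positive_p 0 (0.0%), Negative_p 1 (4.2%)
rwi   lag 1 (n=24): Positive_t 0 (0.0%), Negative_t 23 (95.8%), Positive_p 22 (91.7%), Negative_p 0 (0.0%)
ndvi  lag 0 (n=24): Positive_t 16 (66.7%), Negative_t 0 (0.0%), Positive_p 3 (12.5%), Negative_p 0 (0.0%)
ndvi  lag 1 (n=24): Positive_t 0 (0.0%), Negative_t 7 (29.2%), Positive_p 3 (12.5%), Negative_p 0 (0.0%)
npp   lag 0 (n=24): Positive_t 23 (95.8%), Negative_t 0 (0.0%), Positive_p 21 (87.5%), Negative_p 0 (0.0%)
npp   lag 1 (n=24): Positive_t 1 (4.2%), Negative_t 3 (12.5%), Positive_p 2 (8.3%), Negative_p 1 (4.2%)

== Dominant-variable counts ==
rwi  : Positive_t 0, Negative_t 17, Positive_p 7, Negative_p 0
ndvi : Positive_t 13, Negative_t 3, Positive_p 4, Negative_p 0
npp  : Positive_t 13, Negative_t 1, Positive_p 10, Negative_p 0

== Density peaks of strongest correlations ==
ndvi : peaks at -0.35, 0.56
npp  : peaks at 0.72
rwi  : peaks at -0.69, 0.69
```

Reading it: the synthetic tree-ring network was generated with a lag-1
negative temperature and lag-1 positive precipitation response, and the
pipeline recovers exactly that — 95.8% of cells `Negative_t` and 91.7%
`Positive_p` at lag 1, essentially nothing at lag 0. The NPP-like field was
generated current-year-dominated and positive, and shows the mirror-image
pattern (95.8% `Positive_t` at lag 0). The greenness-like field sits in
between, with weaker coefficients. The bimodal density peaks of the
tree-ring index (−0.69 / +0.69) versus the single positive mode of the
NPP-like index (+0.72) summarize the same observation–model contrast in
distribution form. Every output (`summary_counts.csv`,
`dominance_counts.csv`, `correlations.csv`, `histograms.csv`, `density.csv`,
chronology and screening tables, `.rwl` files, the run manifest with MD5
checksums) is a plain-text file under `out`.

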