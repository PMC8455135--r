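---
title: "Modelling live-fast-die-young dynamics under feast and famine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling live-fast-die-young dynamics under feast and famine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastslow)
```

## The model

Budding yeast can carry heritable, protein-based epigenetic states that trade
faster proliferation for shorter lifespan. `fastslow` models a population in
which each cell has committed to one of two strategies: **live slow, die old**
(LS-DO, the naive state) or **live fast, die young** (LF-DY, the prion-bearing
state). The environment alternates between a nutrient-replete interval of
duration $\tau_1$ and a starvation interval of duration $\tau_2$.

During repletion both sub-populations grow exponentially,
$x_j(t) = x_j(0)\,e^{\mu_j t}$, and during starvation they decay
exponentially, $x_j(t) = x_j(0)\,e^{-\delta_j t}$, for $j \in \{0, 1\}$. Lag
and stationary phases are neglected because the *ratio* of the
sub-populations does not change during them, and only the ratio is modelled
(no carrying-capacity coupling). One feast/famine cycle therefore multiplies
the ratio by

$$
\frac{x_1}{x_0}\Big|_{t+\tau_1+\tau_2}
  = \frac{x_1}{x_0}\Big|_{t}\,
    e^{(\mu_1\tau_1 - \delta_1\tau_2) - (\mu_0\tau_1 - \delta_0\tau_2)},
$$

so after $N$ cycles the log ratio changes by
$N\left[(\mu_1-\mu_0)\tau_1 - (\delta_1-\delta_0)\tau_2\right]$. The package
keeps all abundances in natural-log space (`population_pair`), which makes
the recursion exact over arbitrarily many cycles; `run_cycles()` applies the
phase-by-phase recursion and `analytic_log_ratio()` evaluates the closed
form — the two agree to better than $10^{-10}$ in log space, and the test
suite enforces that.

```{r model}
naive <- strategy_rates(1, 1, "LS-DO")
prion <- strategy_rates(1.01, 1.01, "LF-DY")
traj <- run_cycles(population_pair(), naive, prion, environment_cycle(2, 1, 30))
log_ratio(traj$final)  # 30 * (0.01*2 - 0.01*1) = 0.3
```

When growth and starvation last equally long and the growth advantage equals
the death-rate cost, the two strategies are exactly neutral; longer feasts
favour LF-DY, longer famines favour LS-DO. `phase_space_scan()` maps these
regimes, exporting $\log_{10}(x_1/x_0)$ (grids are plotted on a log scale);
`equal_fitness_boundary()` returns the neutral duration ratio
$\tau_2/\tau_1 = \Delta\mu / \Delta\delta$.

A note on the "1% advantage" parameterization: published phase-space
figures of this kind state a percentage advantage without the baseline
rates. We interpret the offsets as *additive* on rates normalized to a unit
baseline ($\mu_0 = \delta_0 = 1$, $\mu_1 = \delta_1 = 1.01$), the only
reading that makes equal advantages exactly neutral at equal durations;
explicit rates can always be supplied instead.

## Estimating the rate constants

* **Growth constant** (`estimate_growth_constant`): the maximal proliferation
  rate is the *peak of the derivative of the growth data*. The series is
  smoothed with a centered moving average (default 5 points) and
  differentiated by central differences. The default `"specific"` mode
  differentiates log-OD, yielding the exponential growth constant the model
  consumes; `"absolute"` differentiates OD itself, matching plate-reader bar
  summaries. Because a symmetric moving average multiplies a pure
  exponential by a constant, the specific estimator has no smoothing bias in
  exponential phase. For noisy low-density readings an OD floor (`min_od`)
  restricts the peak search; since the specific rate of a logistic curve is
  $\mu(1 - x/K)$, thresholding at a common OD rescales both strains by the
  same factor and leaves their *ratio* unbiased. For 10-minute plate-reader
  sampling with ~0.003 OD additive noise we use a 15-point (2.5 h) window
  and `min_od = 0.2` (~67 times the noise SD), at which the log-derivative
  noise is negligible relative to the rates of interest.
* **Death constant** (`estimate_decay_constant`): chronological-lifespan
  viability series are fit by least squares on $\ln(\mathrm{CFU})$ versus
  day; the decay constant is the negated slope. Zero CFU counts cannot enter
  the log-linear model class and are dropped with a warning rather than
  imputed.
* **Selection coefficient** (`estimate_selection_coefficient`): under
  constant selection the log odds of the marked sub-population is linear in
  generations; $s$ is the least-squares slope of
  $\ln\!\big(f/(1-f)\big)$. Raw colony counts are transformed with the
  Haldane–Anscombe correction $(r + 0.5)/(n + 1)$ so boundary counts remain
  usable. Swapping marker labels negates $s$ exactly.
* **Replicative lifespan** (`median_survival`): division counts are complete
  observations, so the median (midpoint convention for even $n$) and the
  empirical complementary CDF need no censoring machinery.

Per-replicate estimates are collected in `rate_distribution()` objects,
which store the raw sample plus its mean and SD.

## Monte Carlo prediction of competitive fitness

`predict_competition()` propagates measurement uncertainty into the model's
prediction: growth and death rates for both strategies are drawn **with
replacement from the empirical samples** (the measured distributions are not
assumed Gaussian; a Gaussian mode exists as an option), the recursion is run
for each of 1000 draws (the conventional ensemble size here), and the
ensemble is summarized per timepoint by its median and the empirical
2.5–97.5 percentile band (linear interpolation). Draws pair $(\mu, \delta)$
independently per strategy; no correlation structure is imposed because
none is measured.

The serial-passage protocol (`competition_protocol`) mirrors the
experimental design: 1:1000 dilutions allow ~10 bulk generations of regrowth
per passage, for 10 passages (~100 generations). How stationary-phase death
entered the published forward simulation is not stated, so the starvation
interval per passage is an explicit parameter (default 0 h, growth-only).
The mapping from generations to growth time uses the reference strain's
clock, $\tau_1 = g\ln 2/\mu_0$: the culture's doubling cadence is set by the
majority (naive) strain, and a growth advantage then appears as a
per-generation log-fitness gap of $(\mu_1 - \mu_0)\ln 2/\mu_0$. With a fixed
seed the whole ensemble is bit-reproducible; with degenerate one-point rate
pools the ensemble median equals the deterministic model exactly.
`compare_to_observed()` scores an observed trajectory against the band
(per-point residuals and coverage); the model's claim is forward-prediction
agreement, so no fitting to the observed competition is provided.

## Phenotype quantifications

* **Large cells** (`large_cell_stats`): threshold = naive mean area + one
  naive SD (sample SD, $n-1$; the convention is not dictated by the
  procedure's description); cells with area $\ge$ threshold are "large". The
  threshold is computed from the pooled reference sample.
* **Sphere volumes** (`sphere_volume_stats`): radius $\sqrt{A/\pi}$; the
  percent volume difference $100[(A_b/A_a)^{3/2} - 1]$ depends only on the
  area ratio. Mean areas 22.01 and 25.36 µm² give radii 2.65 and 2.84 µm and
  a ~23% volume increase.
* **G1 occupancy** (`budding_reduction`): relative drop in the unbudded
  fraction, $100(f_n - f_t)/f_n$; 36.2% versus 27.2% is a ~25% reduction.
* **Polysome/monosome ratio** (`polysome_monosome_ratio`): the lowest
  absorbance between the monosome and disome peaks (located as the trace
  minimum between the two annotated peaks' maxima) defines zero; after
  subtraction, negative values are clipped at zero (the rule defines only
  the zero point) and regions are integrated by trapezoid. The ratio is
  exactly invariant to constant offsets and to rescaling the absorbance
  axis; a sloped baseline is not removed by the zeroing rule, but realistic
  slopes move the ratio by far less than replicate scatter.
* **Dual-luciferase normalization** (`normalize_luciferase`): firefly is
  divided by the co-expressed Renilla control per well; per genotype means
  are scaled so the naive mean is 1.0 within each reporter-codon variant.
* **Screen calls** (`screen_zscore_differential`): each replicate's GFP/OD
  values are Z-scored across proteins within each background independently,
  cancelling per-replicate multiplicative gain. "Robustly quantified" is
  read as replicate-to-replicate SD of Z below a threshold (default 1) in
  both backgrounds — the phrasing is ambiguous, so the threshold is an
  explicit parameter — and calls require $|\Delta Z| \ge 1$ (at-least, also
  configurable).
* **CAI profiles** (`cai_profile`): positional CAI is the geometric mean of
  Sharp–Li relative-adaptiveness weights over a window (default 21 codons)
  centered at each codon, averaged across sequences long enough to cover the
  position; `cai_weights()` builds weights from any codon-usage table, since
  the appropriate reference set is an analysis choice. Comparing subsets
  (e.g. up-regulated genes versus all) is left to the caller.

## Synthetic data

The generators in `gen_*()` emulate the statistical structure each estimator
assumes, with seeded, fully reproducible output (identical spec + seed ⇒
identical table; the caller's RNG stream is untouched):

| generator | family | key defaults |
|---|---|---|
| `gen_growth_curves` | logistic + additive Gaussian OD noise | rates 0.35/0.56 h⁻¹ (a 60% gap), K = 1.5 OD, inoculum 0.01, 10-min grid for 48 h, noise SD 0.003, 4 replicates |
| `gen_viability_series` | exponential decay + Poisson plating counts | decay 0.04/0.08 day⁻¹, days 0–80 by 10, 8 replicates |
| `gen_lifespans` | discretized Gompertz | medians 30/23 divisions, shape 0.15, n = 280 |
| `gen_competition` | logit-linear drift + binomial colonies | s = 0.01, 1000 colonies, every 10 generations to 100 |
| `gen_polysome_trace` | Gaussian peaks on a linear baseline | polysome:monosome area 3.2 |
| `gen_luciferase_plate` | lognormal multiplicative noise | fold 1.5, 8 wells, 5% CV |
| `gen_screen` | shared lognormal baseline + gain noise | 4 replicates; effects as Z offsets |
| `gen_cell_areas` | lognormal (or Gaussian) | means 22.01/25.36 µm², CV 35% |

Distribution families are modelling choices (no family is dictated by the
assays themselves): logistic kinetics are the standard plate-reader model,
Poisson is the natural plating-count noise, the Gompertz law is the standard
replicative-aging hazard (rate calibrated as
$b = g\ln 2 / (e^{gm} - 1)$ for target median $m$), and lognormals capture
the multiplicative noise of luminescence and expression measurements. The
chronological-lifespan decay constants (0.04/0.08 per day) and most noise
scales are realistic values chosen once, not measured quantities. Screen
effects are injected on the measured-value scale in units of the
cross-protein SD, so a planted +2 effect produces a $\Delta Z$ of ~2 by
construction.

What passing the loop-closure tests shows — and does not show: each
generator/estimator pair recovers the generating parameter at paper-scale
replicate counts, which validates the estimators *under the assumed noise
families*. Real plate-reader drift, plating efficiency trends, gradient
baseline curvature, and position effects on screens are not simulated, so
agreement here does not certify the estimators against those artifacts.

## Numerical choices and problem sizes

All model arithmetic is in natural-log space; phase grids export log10
ratios. Percentiles use R's default type-7 (linear interpolation) quantiles.
The polysome default trace uses a 0.05-resolution grid with peak SD 0.8 and
peak spacing 6, keeping tail leakage between adjacent peaks below 0.1% of a
peak area. Grid scans default to `n_cycles = 30` with equal starting
populations. The verification scripts and tests use ensembles of 200–1000
draws, 100-seed recovery studies for the cheap estimators, and 30-seed
studies for the growth-curve estimator (8 curves × 289 points each), sizes
at which every recovery criterion is resolved well beyond its tolerance.

## Interfaces

Tables move through schema-validated CSV (`load_table`, `write_table`,
`table_schemas`); wide plate-reader exports with a time-like first column
are auto-melted by `read_growth_curves`. Coding sequences are read from
FASTA (`read_coding_sequences`). The package's functions, the generators
above, and `scripts/acceptance.R` (which regenerates the headline numbers
end-to-end from a single seed) are the intended entry points; no separate
command-line binary is shipped.

## Known limitations

- The deterministic model has no demographic noise, no lag/stationary
  kinetics and no carrying-capacity coupling; it tracks only the ratio.
- The duration/advantage phase grids are parameterized rather than fixed to
  any particular published axis range.
- Decay-constant fitting is log-linear least squares; a count-based
  Poisson GLM mode is deliberately out of scope.
- Lifespan handling assumes complete observations (no censoring).
- Polysome peak *detection* is out of scope: region boundaries arrive as
  annotations.
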