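---
title: "Estimating excess mortality from monthly death panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess mortality from monthly death panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmort)
```

## The estimation problem

Excess mortality compares the all-cause deaths observed in a target
year against a counterfactual baseline projected from pre-pandemic
years. It sidesteps two defects of reported epidemic deaths: dependence
on testing capacity and on cause-of-death coding practice. `exmort`
works at the resolution most national statistical offices publish —
monthly death counts per geographic unit, with annual person-years
exposures — and estimates excess per unit for the full year and for
quarters, with uncertainty, then relates the estimates to reported
epidemic burden across units.

## Rates and the month-length adjustment

Raw monthly counts are not comparable across months: a 31-day month
carries about 10% more deaths than February at the same underlying
hazard. Counts are therefore rescaled to the average month length
before any modelling:

$$D^{*}_{y,m,a} = D_{y,m,a} \cdot \frac{\text{days in year}(y)/12}{\text{days in month}(y,m)},
\qquad
\mathrm{CDR}_{y,m,a} = \frac{D^{*}_{y,m,a}}{P_{y,a}/12} \times 100{,}000 .$$

The adjustment is leap-aware (February 2020 has 29 days in a 366-day
year). Monthly exposure is exactly one twelfth of the annual exposure;
no within-year interpolation is attempted, because subannual population
estimates are rarely available at regional level and a smooth
interpolation would add assumptions without changing excess estimates
appreciably. A consequence worth knowing: summing $D^*$ over a year
reproduces the annual death count only when the daily death rate is
constant across months (the test suite asserts this identity on a
uniform fixture).

## Baseline models

Three baselines are fitted per unit on a reference window, by default
the five years 2015–2019 (configurable down to four, for units with
shorter available series).

**Method A (seasonal averages).** $\mathrm{CDR}(t,m) = \alpha_m +
\varepsilon_{t,m}$; the expected rate for any future year is
$\hat\alpha_m$, the within-month mean. This is the convention of many
statistical offices and media trackers, and it is unbiased only when
mortality fluctuates around a stable level.

**Method B (seasonal averages + secular trend).** $\mathrm{CDR}(t,m) =
\alpha_m + \beta t + \varepsilon_{t,m}$, fitted by ordinary least
squares; the expected rate for target year $y^*$ is $\hat\alpha_m +
\hat\beta y^*$. Where crude rates decline steeply (falling mortality)
or rise (rapid ageing), Method A's baseline is off by $\beta \times
(y^* - \bar t)$ — three years' worth of trend for a 2015–2019 window
and a 2020 target — and its excess estimate is displaced by the same
amount in the opposite direction. The design is balanced (every
reference year contributes all 12 months), so the fit has a closed
form: the slope is the regression of year row-sums on the centred year,
and the month intercepts are month means net of the trend. This closed
form is what the package computes; it is numerically identical to
`lm(cdr ~ 0 + factor(month) + year)` and is cross-checked in the tests
against a brute-force normal-equations solve. No exposure weighting is
applied: estimates are per unit, and within a unit the exposure is
constant in the fitting window up to small annual changes. Predictions
are invariant to affine recoding of the year covariate, so whether the
year enters centred or uncentred is immaterial (a property the tests
assert).

**Lee-Carter (sensitivity).** The demographic factor model, adapted
with calendar months as strata in place of age groups (no age data are
in scope): $\log \mathrm{CDR}(t,m) = a_m + b_m k_t + \epsilon$. $a_m$
is the time-mean of log rates; $(b_m, k_t)$ is the leading singular
component of the centred log-rate matrix under the identification
constraints $\sum_m b_m = 1$ and $\sum_t k_t = 0$ (dividing the
singular vector by its sum also fixes the sign, and the level shift
from re-centring $k$ is folded into $a$). The time index is carried
forward by random walk with drift, $\text{drift} = (k_N - k_1)/(N-1)$,
rather than refitting an ARIMA — with five reference points the
endpoint-difference drift is the only stable choice. Whether the
original sensitivity analyses ran the model on monthly or annual rates
is not documented in the sources this design follows; month-as-stratum
was adopted because it uses the same information set as Methods A and
B, making the three baselines directly comparable. Reference rates must
be strictly positive (log scale); zero monthly counts at very small
exposures are a domain error rather than silently smoothed.

## Excess measures and periods

For a period (year, Q2, Q3, Q4), observed and expected rates are
unweighted means of the annualised monthly CDRs over the period's
months — the month-length adjustment has already equalised month
lengths, so no day-weighting is needed. Absolute excess is observed
minus expected (per 100,000/year); relative excess is
$100 \times$ absolute/expected (%). Q2 is defined as the four months
March–June, capturing the full first pandemic wave; Q3 and Q4 are the
usual three-month quarters. That makes the annual value an exact
month-count-weighted combination:

$$E_{\text{year}} = \tfrac{1}{12}\left(2 E_{\text{Jan-Feb}} + 4 E_{Q2} + 3 E_{Q3} + 3 E_{Q4}\right),$$

an identity the acceptance tests verify both algebraically and against
published quarterly/annual value sets. The four-month Q2 is applied
uniformly to all quarterly estimates, not only to plots.

## Bootstrap confidence intervals

The interval scheme is a residual bootstrap of the baseline fit:

1. pool the reference-window residuals $\varepsilon_{t,m}$ within the
   unit, rescaled by $\sqrt{n/(n-p)}$ to undo the variance deflation of
   fitting $p$ parameters on $n = 12N$ observations (12 for Method A,
   13 for Method B, $22 + N$ for the constrained factor model);
2. resample with replacement, add to the fitted reference surface,
   refit the baseline, and recompute the expected period rate;
3. perturb the observed target-year monthly rates with independently
   resampled residuals on each replicate;
4. report percentile 2.5/97.5 bounds of the replicate excess values.

Step 3 deserves a note. A bootstrap that resamples only the baseline
side treats the observed 2020 rate as a constant, which is defensible
for very large populations but understates uncertainty at regional
exposures, where one month's Poisson noise is comparable to the
baseline's estimation error; an interval for *excess* — a difference of
two noisy quantities — must carry both components, and the package's
simulation study (below) confirms the combined scheme attains its
nominal coverage while the baseline-only variant cannot. The reference
residual pool is used as the noise model for the observed year, which
assumes noise stationarity across the window — reasonable for Poisson
counts at stable exposure.

Percentile intervals (not BCa) are used: the replicate distribution is
close to symmetric and percentile bounds keep the scheme transparent.
All replicates derive from a single integer seed; rerunning with the
same seed gives identical bounds. Degenerate inputs are handled
explicitly: a noiseless panel (all residuals zero) collapses the
interval to the point estimate with a classed warning rather than an
error; fewer than 100 replicates is rejected.

## Association and spatial clustering

Cross-unit association between excess and reported cases/deaths uses
OLS for the slope and the Pearson correlation with the exact t-transform
p-value on $n-2$ degrees of freedom (at least three paired units, both
variables non-constant). Quadrant profiles run the same estimator per
period, which is how a positive first-wave correlation and negative
later-wave correlations — the signature of burden-dependent
under-ascertainment — show up.

Cluster detection uses Anselin's local Moran's I with row-standardised
user-supplied adjacency weights:

$$I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j, \qquad m_2 = \tfrac{1}{n}\sum_i z_i^2 .$$

The population ($n$-denominator) variance is used deliberately: it is
the convention under which the mean of the local statistics equals the
global Moran's I exactly, an identity the tests check against an
independent brute-force implementation on every random instance.
Inference is by conditional permutation — the value at unit $i$ stays
fixed, its neighbours are redrawn without replacement from the
remaining units — with the two-sided pseudo p-value
$(1 + \#\{|I^{perm}| \ge |I^{obs}|\})/(1 + \text{perms})$, 999
permutations by default. Quadrants (HH, LL, HL, LH) are assigned from
the signs of $z_i$ and its spatial lag only below the significance
threshold (default 0.05); isolated units get `NA` statistics, a
warning, and are excluded from the global identity. No geometry is
processed: weights come from an adjacency CSV, since regional
contiguity lists are small and auditable by hand.

## Weekly-to-monthly disaggregation

Units published as ISO-week series (STMF style) are converted by
spreading each week's deaths uniformly over its seven days and
allocating by calendar day count, so a week straddling a month boundary
splits proportionally (3/7 vs 4/7 for a Wednesday boundary). Whether
the original transformations used day-proportional splitting or
whole-week assignment is not documented; day-proportional is adopted
as the only rule that conserves totals over any fully covered span and
maps a constant weekly rate to counts proportional to days-in-month
(both properties are asserted exactly in tests). Fractional monthly
counts are retained — downstream rates are continuous, and rounding
would break conservation. A target month with any uncovered day raises
a coverage error instead of silently scaling.

## The synthetic generator

`scenario_config()` defines the study conditions; `generate_panel()`
realises them and records the truth. Expected monthly rates are

$$\mathrm{CDR}(t,m,u) = \text{base}_u \cdot s_m + \beta_u (t - t_0) + W_u(m)\,[t = y^*],$$

with $s_m$ a 12-month multiplicative seasonality profile (mean 1),
$\beta_u$ an additive secular trend, and $W_u$ piecewise-linear
epidemic waves (ramp up to a peak month, ramp down, possibly running
past December). The trend enters additively, exactly matching the
model Method B fits, so that the noiseless closed loop is exact: an
alternative that scales the trend by the seasonal factor would make
month-specific slopes $\beta s_m$, put the truth outside the fitted
model family, and turn "recovery to machine precision" into an
approximation — the additive form is the one consistent with the
fixed-effects-plus-trend framework this package implements. Expected
rates convert back to expected counts by inverting the month-length
adjustment, and realised counts are Poisson (`noise = "none"` returns
the exact expectations, fractional deaths allowed). Poisson is the
minimal count-noise model; overdispersion is deliberately out of scope.

Defaults: reference years 2015–2019, target 2020, base level 1200 per
100,000, exposure $10^6$ person-years, seed 20200101. The default
seasonality is a cosine with a 20% January elevation — strong,
winter-dominant seasonality chosen so that the seasonal signal clearly
dominates month-mean Poisson noise at regional exposures (signal-to-
noise ≈ 10 at the defaults), which keeps recovery tests sharp; the
generator makes no attempt to calibrate magnitudes to any real national
series. True excess per period is defined as the period-mean of the
injected wave intensity, so estimator bias is measurable exactly.

Reported covariates derive from the truth: true epidemic deaths are a
configured share (default 0.7) of true excess, infections follow
through an infection fatality ratio (default 0.01), and reported values
scale by per-unit ascertainment and death-reporting fractions. The
`"inverse_burden"` ascertainment mode sets ascertainment proportional
to $\text{burden}^{-2}$ (capped at 0.9), making reported cases decay
with true burden; exactly inverse-proportional ascertainment would make
reported cases *constant* across units and the correlation undefined,
so the steeper exponent is the meaningful encoding of "the hardest-hit
units test least". `scenario_russia_like()` bundles the qualitative
2020 pattern: declining trend, a spring wave confined to two
metropolitan units, a moderate summer wave in about half the units, and
a large autumn–winter wave everywhere with the heaviest amplitudes in
an "eastern" block.

What the generator does **not** emulate: age structure (and hence
age-standardisation or life-expectancy measures), overdispersed or
autocorrelated count noise, migration-driven exposure changes within a
year, reporting delays, and epidemic dynamics (waves are shapes, not
SEIR trajectories). Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

* Noiseless-recovery assertions use relative tolerance $10^{-10}$; the
  closed-form OLS achieves it, while an uncentred normal-equations
  solve (used only as a test oracle) carries ~7 significant digits.
* Ranking ties break lexicographically by unit id, making rankings
  deterministic.
* Duplicate (unit, year, month) rows, negative deaths, non-positive
  exposures and incomplete reference coverage are classed errors at
  read/fit time; units with incomplete coverage are dropped with a
  logged warning by the pipeline rather than imputed.
* Zero/negative rates under the log-scale factor model raise a domain
  error; a degenerate flat singular component falls back to a unit
  scale factor instead of dividing by ~0.
* All file formats are plain delimited text (comma/semicolon/tab
  auto-detected, UTF-8, decimal point), and fitted models serialise to
  a documented JSON layout.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(normal-equations OLS, `lm()`, brute-force global Moran's I, exact date
arithmetic) and runs a simulation study at sizes chosen to make the
statistical assertions sharp while keeping the suite quick: 500
simulated 5-unit panels at exposure $10^6$ with an injected annual
excess of 250 per 100,000 and a −15/year trend for bias and coverage
(bootstrap B = 500), and 500 spatially random 4×4 fields at 999
permutations for the cluster statistic's size. `scripts/acceptance.R`
re-runs the same designs (300 panels) from a command-line seed and
writes the resulting quantities as JSON.

## Limitations

Crude rates confound mortality change with population ageing; a linear
trend in CDR is a pragmatic, not structural, correction, which is why
the factor-model baseline is carried as a sensitivity check. Without
age- and sex-specific data, neither age-standardised excess nor
life-expectancy losses can be computed. The bootstrap quantifies
baseline-estimation and count-sampling noise but not exposure
(denominator) error. Ecological correlations across units cannot be
read as individual-level effects, and the cluster statistic's quadrant
labels are exploratory — no multiple-testing correction across units is
applied.
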