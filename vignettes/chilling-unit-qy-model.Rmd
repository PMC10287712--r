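---
title: "Modelling winter cold damage to Eucalyptus leaves with chilling accumulation units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter cold damage to Eucalyptus leaves with chilling accumulation units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillqy)
```

## The problem and the model

*Eucalyptus globulus* is a fast-growing plantation tree whose range is
limited by winter cold. Leaf damage can be tracked non-destructively
through the photosynthetic quantum yield (QY) of photosystem II, a
proportion in $[0, 1]$ that collapses as leaves are damaged by chilling
and recovers in spring. The package models QY from daily temperature
records alone, so that damage can be predicted anywhere a weather station
exists.

Cold exposure is summarized by a *chilling accumulation unit* (CU): over
the $L$-day window ending on (and including) day $d$, using one daily
temperature statistic $T$ (maximum, minimum or average) and a threshold
$Th$,

* the **day count** $CU_d$ is $\#\{\delta : T(\delta) < Th\}$, and
* the **temperature sum** $CU_t$ is $\sum_{T(\delta) < Th} (Th - T(\delta))$,

the familiar chilling / degree-day deficit convention, which keeps values
nonnegative and monotone in both $Th$ and $L$. The inequality is strict
("below" the threshold); on a 0.25 °C threshold grid with continuous
temperatures the choice is essentially tie-free, and
`compute_cu(raw_sum = TRUE)` provides the variant that accumulates the raw
sub-threshold temperatures instead, since the verbal definition of $CU_t$
admits both readings. The window *ends on* the observation day: damage
measured on a day plausibly reflects that same day's cold, and with a
46-day window the two conventions differ by a single day.

QY is modelled linearly on the log-odds scale,

$$\mathrm{logit}(QY) = a \cdot CU + b + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

fitted by ordinary least squares. Because observed QY can be exactly 0 in
deep winter, proportions are clamped to $[\epsilon, 1-\epsilon]$ with
$\epsilon = 10^{-3}$ before the transform.

## Model selection

Every CU definition on a grid — 2 CU types × 3 statistics × 61 thresholds
(a 15 °C span in 0.25 °C steps, per-statistic ranges bracketing each
family's optimum) × 70 windows (1–70 days) = 25,620 configurations — is
fitted and compared by AIC with $k = 3$ parameters and the
maximum-likelihood variance $\hat\sigma^2 = RSS/n$:

$$\log L = -\tfrac{n}{2}\left(\log(2\pi\hat\sigma^2) + 1\right),
  \qquad AIC = 6 - 2\log L.$$

This is the Gaussian-`glm` AIC convention, chosen over the unbiased
$RSS/(n-2)$ so that AIC values are comparable with that widespread
default. The search is exact and exhaustive: for each threshold one
cumulative-sum pass over the series yields the CU for *every* window at
once, so the full 25,620-model search runs in well under a second, and a
test verifies it is identical to fitting each configuration separately
with `lm()`.

Ties deserve a note. AIC values within $10^{-9}$ of the minimum are
reported in `tie_report` and broken deterministically by grid order (CU
type, then statistic in the order max, min, avg, then threshold, then
window). With the synthetic generator's fixed diurnal offset, the daily
maximum, average and minimum are exact translates of one another, so a
day-count CU of the maximum below $Th$ coincides with one of the average
below $Th - 4.5$ whenever both thresholds lie on the grid — a three-way
tie that real data, whose diurnal range fluctuates, will not produce.

Configurations whose CU is constant over the observation dates (e.g. a
threshold below every temperature ever recorded) leave the slope
unidentifiable; they are kept in the table as failed fits with $+\infty$
AIC so the AIC surface stays rectangular for plotting.

### Aggregation of replicate leaves

Three leaves per clonal line are measured per date. The default design
averages replicates within line × date on the QY scale *before* the logit
transform (`per_line_date_mean`), which matches the modest per-season
regression counts such data sets report; `per_observation` keeps each
leaf. The choice is exposed because field practice varies.

## Intervals and validation

Out-of-sample evaluation refits nothing: the selected model predicts a
held-out season, and observations are counted inside 95% bands.
Intervals use the standard simple-regression geometry on the logit scale
with the *unbiased* $s^2 = RSS/(n-2)$ and Student-$t$ quantiles — the
convention under which the calibration guarantees are exact — and are
mapped through the monotone inverse logit so endpoints transform to
endpoints and coverage counts are identical on either scale. The
mean-response confidence band and the new-observation prediction band are
both produced; coverage counting defaults to the confidence band to
mirror common plotting practice, but a Monte-Carlo test confirms the
*prediction* band is the one with ~95% coverage of new observations —
published "confidence" ribbons that contain ~96% of observations are in
effect prediction bands, and `interval_kind = "prediction"` is the
defensible choice for observation-coverage claims.

## The synthetic-data generator

The raw field QY observations and station extracts this class of study
uses are typically not deposited, so the package ships a generator whose
defaults *are* the study conditions, and the whole pipeline is exercised
against it:

* **Climate** (`climate_params()`): daily mean =
  $14.5 - 11\cos(2\pi(\mathrm{doy} - 25)/365.25)$ °C — a Tsukuba-like
  humid temperate cycle with its minimum anchored to late January
  (day-of-year 25) — plus i.i.d. $N(0, 2^2)$ day-to-day noise, an
  optional linear warming trend, and a fixed ±4.5 °C diurnal offset for
  the daily maximum/minimum. A configurable fraction of days is missing,
  all three statistics at once, as in station outages.
* **Truth** (`true_model()`): day-count CU of the daily maximum with
  $Th = 9.5$ °C and $L = 46$ days; $a = -0.082$, $b = 0.85$, so predicted
  QY spans ≈ 0.70 (no chilling) down to ≈ 0.05 (saturated chilling), and
  at $CU = 35$ predicted QY ≈ 0.12 — the neighbourhood of the classical
  suitability cutoff. Logit-scale observation noise sd 0.1.
* **Sampling**: biweekly from Nov 1 to Mar 31 (11 dates per season), 2
  clonal lines × 3 replicate leaves, three training seasons ≈ 66
  aggregated response points.

What the generator does *not* emulate: autocorrelated weather (each day's
noise is independent), variable diurnal range, spatially correlated noise
between sites (only the latitude-driven mean gradient links them), and
any replicate-level variance structure beyond i.i.d. logit-scale noise —
the within-date covariance of real leaves is simply unknown. Passing
tests therefore demonstrate the *statistical machinery* (selection
consistency, interval calibration, monotonicity), not that real
*Eucalyptus* data obey the model.

Under these conditions the full grid search recovers the generating
threshold and window as the modal selection across 10 seeds — the check
`scripts/acceptance.R` reproduces.

## Geographic and warming simulations

For suitability mapping, each site's record passes the missing-rate
filter (≤ 10%, boundary inclusive — the printed rule), single missing
days are filled with the arithmetic mean of the flanking days and longer
runs by linear interpolation (the natural extension of that rule;
boundary gaps are rejected), and the *period-maximum CU* is taken.
Site values are interpolated to a regular lat/lon lattice (cell centres
from the bounding box's south-west corner) by an RBF-kernel support
vector machine — the tool this literature itself uses — in regression
mode for CU fields or classification mode for suitability booleans.
Coordinates enter as raw degrees to mirror that usage; a
cos(latitude) longitude scaling is available by flag for high-latitude
work. The RBF bandwidth estimate subsamples, so a seed argument makes
interpolation reproducible. Cells are suitable when period-max CU ≤ 35
(inclusive; "below 35" is ambiguous exactly at the boundary, so the
inclusive reading is fixed and documented).

The warming analysis computes, per site and season (default window Oct
1 – Mar 31, labelled by start year), the minimum daily predicted QY;
regresses it on year (`lm`, ≥ 3 seasons); extrapolates the line to a
target year, clamped into $[0, 1]$ because QY is a proportion; counts
sites *strictly* exceeding the QY threshold (0.20 by default, with 0.4
retained as the named alternative since both conventions circulate); and
maps the decision boundary with the classification SVM. The national-grid
resolution defaults to 0.1° with 0.05° selectable, again because both
conventions appear in practice. The warming scenario's default imposed
trend is 0.02 °C/yr, a realistic recent-decades magnitude for mid-latitude
Japanese stations; under it the 97-site synthetic network shows a positive
median QY trend (~0.008 QY/decade, matching the ~0.01/decade scale such
records show) and a poleward-moving suitability boundary.

## Numerical choices and desk-scale sizes

* OLS is closed-form (sufficient statistics); predictors with centred
  sum of squares below $10^{-12}$ are declared constant.
* $RSS$ is floored at 0 against cancellation; a perfect fit yields
  $\log L = +\infty$ and $AIC = -\infty$, which the argmin handles.
* All randomness flows through explicit per-call seeds; the caller's RNG
  stream is saved and restored, so no call has hidden global effects.
* Test and example problem sizes are deliberately desk-scale: 3-season
  records, 97-site networks, 16–25 season warming records, 200-series
  brute-force comparisons, 500-replicate calibration loops. The full
  25,620-model search itself is cheap (< 1 s), so it is always run whole.

## Known limitations

Single-predictor linear structure (no precipitation, elevation or
radiation covariates; the geographic maps inherit that omission); no
mixed-effects structure for clonal lines; no hourly chilling models
(Utah/Dynamic); linear trend extrapolation rather than climate-model
forcing; and SVM interpolation in raw degrees distorts distances at high
latitude unless the cosine scaling is enabled.
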