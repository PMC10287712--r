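# chillqy

Winter cold limits where *Eucalyptus globulus* can be planted. Leaf
damage can be tracked non-destructively through the photosynthetic
quantum yield (QY) of photosystem II — a proportion in [0, 1] that
collapses during cold spells — and, crucially, it can be predicted from
daily temperature records alone. `chillqy` implements that pipeline for
forestry researchers and biostatisticians:

1. **Chilling accumulation units (CU).** Over the *L*-day window ending
   on day *d*, from one daily statistic *T* ∈ {max, min, avg}:
   day count `CU_d = #{δ : T(δ) < Th}` or temperature-deficit sum
   `CU_t = Σ_{T(δ)<Th} (Th − T(δ))`, for a threshold *Th*.
2. **Model selection.** QY is modelled as
   `logit(QY) = a·CU + b + ε`, `ε ~ N(0, σ²)`, fitted by OLS for every CU
   definition on a 61-threshold × 70-window grid across all six
   (type, statistic) families — 25,620 models — and the minimum-AIC model
   is selected (`AIC = 6 − 2·logL`, ML variance, k = 3).
3. **Validation.** Out-of-sample prediction of a held-out season with
   95% confidence and prediction intervals on the QY scale, coverage
   counts, Pearson *r* and predictive *R²*.
4. **Geographic suitability.** Per-site period-maximum CU (after a ≤10%
   missing-rate filter and neighbour-mean/linear imputation),
   SVM-interpolated to a lat/lon grid and thresholded (CU ≤ 35).
5. **Warming trends.** Per-site annual-minimum predicted QY, linear
   trends, extrapolation to a future year, suitable-site counts and the
   shifting SVM decision boundary.

Because raw QY field observations are rarely deposited, the package
includes a synthetic climate + QY generator (`climate_params()`,
`true_model()`, `gen_qy_observations()`) whose defaults emulate the
Tsukuba study conditions, so the entire pipeline is testable at desk
scale.

## Worked example

```r
library(chillqy)

# three seasons of synthetic Tsukuba-like climate and biweekly QY surveys
climate <- climate_params()
series  <- gen_temperature_series(climate, as.Date("2013-08-01"), 1354,
                                  seed = 1)
truth   <- true_model()   # day-count CU of daily max, Th = 9.5, L = 46
obs <- do.call(rbind, lapply(1:3, function(k)
  gen_qy_observations(series, truth,
                      first_date = as.Date(sprintf("%d-11-01", 2012 + k)),
                      last_date  = as.Date(sprintf("%d-03-31", 2013 + k)),
                      seed = 100 + k)))
class(obs) <- c("qy_obs", "data.frame")

search <- cu_grid_search(series, obs)   # all 25,620 models, < 1 s
search
#> Chilling-unit AIC grid search: 25620 configurations, 66 response points
#>   failed fits (AIC = +Inf): 4192
#>   AIC ties at the minimum: 3 (first in grid order selected)
#> Selected (minimum AIC):
#> Logit-linear QY chilling-unit model
#>   unit: day_count of daily max, Th = 9.5 degC, L = 46 days
#>   logit(QY) = -0.0817 * CU + 0.8543   (sigma_ML = 0.0603, n = 66)
#>   logLik = 91.709, AIC = -177.418, R^2 = 0.9969
```

The search recovers the generating configuration (threshold 9.5 °C,
46-day window) from the noisy observations alone. The fitted slope and
intercept sit at the generator's truth (−0.082, 0.85), and the 4,192
failed fits are thresholds that never accumulate chill (their AIC is
+Inf so the table stays rectangular). The three-way AIC tie is a
synthetic-data artifact: with a fixed diurnal offset, day counts of
tmax/tavg/tmin coincide at grid-aligned threshold shifts.

Validate on a held-out season and read off the suitability conversion:

```r
hold <- gen_qy_observations(series, truth,
                            first_date = as.Date("2016-11-01"),
                            last_date  = as.Date("2017-03-31"), seed = 999)
validate_season(search$best, series, hold, season = "2016-2017",
                interval_kind = "prediction")
#> QY validation, 2016-2017: 21/22 points within the 95% prediction interval
#>   r = 0.998, predictive R^2 = 0.996 (logit scale)

predict(search$best, 35, interval = "confidence")
#>   cu       fit       lwr       upr
#> 1 35 0.1186416 0.1158749 0.1214652
```

21 of 22 held-out points (≈ 95%) fall inside the prediction band, and a
period-maximum CU of 35 — the classical plantation-suitability cutoff —
corresponds to a predicted winter QY of about 0.12.

`run_pipeline(pipeline_config())` chains all stages (simulation, filter,
search, validation, geographic map, warming trends) and writes the CSV
artifacts; `plot(search)` draws the AIC surface over threshold × window.

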