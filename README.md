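# wearsel

Activity-aware sensor selection for power-efficient heart-rate prediction
from multimodal wearable data.

Body sensor networks stream many modalities — ambient temperature and
humidity, skin temperature, wrist and ankle 3-axis acceleration,
electrodermal activity (EDA), and EKG-based heart rate — and keeping all
of them powered dominates the battery budget. wearsel implements a
context-aware strategy for trimming that budget while keeping heart-rate
prediction accurate:

1. **Activity clustering.** Sliding-window features of the ankle
   accelerometer (21 per window) are reduced to 3 dimensions with locality
   preserving projections and partitioned by k-means into K = 4 activity
   states (walking, running, resting, exercising).
2. **Per-cluster group lasso.** For each state, heart rate at time `t` is
   regressed on seven *sensor groups* of window features (body temp, env
   temp, humidity, wrist accel, ankle accel, EDA, lagged-HR history) under
   the group-sparse penalty

   `min_b ||Y - sum_k Z_k b_k||^2 + lambda sum_k ||b_k||_{W_k}`,

   with `W_k = (1/M_k) I` (normalized) or `W_k = (P_k/M_k) I`
   (power-weighted, `P_k` = sensor current draw in mA). Whole sensors drop
   out of the model together as `lambda` grows; `lambda` is selected by
   day-wise cross-validation (training days are the folds).
3. **Power accounting.** Sensors inactive in the current state's model are
   duty-cycled; the current reduction is the sum of their per-sensor
   incremental currents, averaged over states with cluster-size weights,
   and trade-off curves quantify the extra savings available per bpm of
   extra RMSE.

A synthetic multimodal recording generator (state-dependent accelerometer
waveforms, first-order HR dynamics, drifting EDA, near-constant ambient
channels, ground-truth labels) makes the whole pipeline testable without
any device data.

## Worked example

```r
library(wearsel)

rec <- simulate_recording(sim_config(days = 4), seed = 1)
rec
#> <wear_recording> 4 day(s), 22800 s total
#>   target: hr; context: ankle_accel
#>   streams: body_temp (4 Hz, 91200 samples); env_temp (1 Hz, 22800 samples);
#>   humidity (1 Hz, 22800 samples); wrist_accel (32 Hz, 729600 samples);
#>   ankle_accel (100 Hz, 2280000 samples); eda (4 Hz, 91200 samples);
#>   hr (1 Hz, 22800 samples)

report <- run_pipeline(rec, dh = 30, K = 4, scheme = "normalized",
                       power = power_table(), seed = 1)
report
#> <pipeline_report> dh = 30 s, normalized penalty, K = 4
#>   train days: 1, 2, 3; test day: 4
#> # A tibble: 3 × 5
#>   model                mae  rmse  nrmse r_squared
#>   <chr>              <dbl> <dbl>  <dbl>     <dbl>
#> 1 clustered           1.56  2.55 0.0310     0.986
#> 2 unclustered         1.99  3.13 0.0380     0.978
#> 3 constant_predictor  4.45  8.76 0.107      0.829
#>   average current reduction: 0.667 mA (6.71%)
```

The clustered model beats both the single global model and the
persistence baseline (`yhat(t) = y(t - 30)`): RMSE 2.55 bpm vs 3.13 and
8.76, while duty-cycling the sensors each activity state does not need.
Per-state sensor sets and savings:

```r
report$power_report
#> # A tibble: 4 × 5
#>   cluster     n delta_ma delta_pct active
#> * <chr>   <dbl>    <dbl>     <dbl> <list>
#> 1 C1       2510    0.838      8.42 <chr [4]>
#> 2 C2       1808    0.575      5.78 <chr [5]>
#> 3 C3        899    0.575      5.78 <chr [5]>
#> 4 C4        447    0.263      2.64 <chr [6]>
```

(Numbers above are what these calls print at seed 1 on this machine.)
The largest state (C1, mostly walking) needs only the two accelerometers,
EDA and heart rate, so the three near-constant ambient/body channels are
idled for an 8.42% current saving; the rarer states keep more sensors at
the cross-validated penalty, and the trade-off curves
(`autoplot(report$tradeoffs$C1)`) show what further savings would cost.
`tidy()` / `glance()` expose coefficients and summaries as tibbles;
`autoplot()` draws regularization paths and accuracy–power trade-off
curves; `dropout_levels()` reports the penalty level at which each sensor
leaves each model.

The per-sensor current tables (`power_table()`, `power_table("measured")`)
and their derivation are documented in the methods vignette
(`vignettes/activity-aware-sensor-selection.Rmd`). A thin command-line
front-end is provided in `exec/wearsel`
(`wearsel simulate|run|power ...`).

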