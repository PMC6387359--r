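---
title: "Activity-aware sensor selection for power-efficient heart-rate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-aware sensor selection for power-efficient heart-rate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(wearsel)
```

## The problem

A body sensor network streams several modalities — ambient temperature and
humidity, skin temperature, wrist and ankle 3-axis acceleration,
electrodermal activity (EDA), and EKG-based heart rate — to an aggregator.
Keeping every sensor powered and transmitting dominates the energy budget
of such devices. wearsel implements an activity-aware strategy: predict
heart rate from the other streams, let a group-sparse regression decide
which **sensors** each activity state actually needs, and duty-cycle the
rest. The package covers the whole pipeline: data model and alignment,
sliding-window features, activity clustering, the group lasso and its
regularization path, day-wise cross-validation, current-reduction
accounting, and accuracy–power trade-off curves, plus a synthetic-data
generator so everything is testable without device recordings.

## Model

At 1 Hz analysis resolution, each time `t` carries a feature vector built
from the streams over the preceding 5 s window, partitioned into
`N_g = 7` sensor groups: body temperature (window mean, 1 feature),
environmental temperature (1), humidity (1), wrist acceleration (21),
ankle acceleration (21), EDA (6), and heart-rate history (3). The
accelerometer group contains, per axis, the mean, variance, skewness,
excess kurtosis, peak periodogram magnitude and its frequency, plus the
three pairwise covariances. The EDA group contains mean, least-squares
trend, variance, skewness, kurtosis and range. The heart-rate group is
`y(t-dh)` and its first and second discrete differences, where `dh` is the
history horizon in seconds; `dh = Inf` drops the group (6 groups, p = 51).

An activity cluster function assigns each row to one of `K = 4` states:
the 21 ankle-accelerometer features are standardized, projected to 3
dimensions by locality preserving projections (LPP; k-NN heat-kernel graph,
`knn = 10`, bandwidth = median squared k-NN distance), and clustered by
k-means (20 restarts, labels sorted by cluster size). Cluster semantic
names (walking, running, resting, exercising) are annotations only.

Per cluster `c`, coefficients solve the group lasso

    b^ = argmin_b || Y - sum_k Z_k b_k ||^2 + lambda * sum_k ||b_k||_{W_k},

with `||b||_W = (b' W b)^{1/2}` and `W_k = c_k I`. The *normalized* scheme
uses `c_k = 1/M_k` (`M_k` features in group k); the *weighted* scheme uses
`c_k = P_k/M_k` with `P_k` the sensor's current draw, so power-hungry
sensors are penalized harder. All columns and the response are
standardized to mean 0, sd 1 on the training rows; the intercept is
handled by centering and never penalized. The penalty is **not** divided
by the sample size — the printed objective is implemented literally —
which makes `lambda` values data-size dependent; this is harmless because
`lambda` is always searched on a grid relative to `lambda_max`, the
smallest penalty with an all-zero solution
(`max_k 2 ||Z_k' Y|| / sqrt(c_k)`).

Sensors whose groups are inactive at the selected penalty are duty-cycled
off whenever that cluster's model is running; the current reduction is the
sum of the disabled sensors' incremental currents, and cluster reductions
are averaged with cluster-size weights `N_ci`.

## Numerical choices

* **Solver.** Cyclic block coordinate descent on the Gram matrices
  (`Z'Z`, `Z'y`), so a sweep costs O(p^2) independent of N. Each block is
  minimized exactly: in the eigenbasis of `Z_k'Z_k` the optimality
  condition reduces to a monotone scalar root (solved by `uniroot` to
  1e-13), with the closed-form zero test `2||Z_k'r|| <= lambda sqrt(c_k)`.
  Convergence is declared when the largest coefficient change in a sweep
  is below 1e-6, with a 10,000-sweep budget (non-convergence warns and
  flags the model). Every fit can be certified by `kkt_check()`;
  the test suite also cross-checks objectives against an independent
  FISTA solver on random instances. At `lambda = 0` the SVD-based
  minimum-norm least-squares solution is returned directly.
* **Path and cross-validation.** Log-spaced grid from `lambda_max` down to
  `lambda_max * 1e-4` (default 40 points) with warm starts. Following the
  recording protocol, days are the cross-validation folds: each training
  day is held out once, the model is fitted on the remaining days' rows of
  the cluster, and `lambda*` minimizes the mean held-out RMSE (ties go to
  the larger penalty); the final model is refitted on all training days.
  A cluster absent from a day skips that fold with a warning.
* **Degenerate columns.** Near-constant channels (ambient conditions
  indoors are essentially flat) would divide by zero under
  standardization; columns with training sd below 1e-10 are dropped with a
  warning, and a group whose columns all degenerate is excluded.
* **Spectral features.** Mean-removed rectangular-taper periodogram, peak
  searched over bins in (0, Nyquist]; skewness/kurtosis of a zero-variance
  window are defined as 0. Windows are half-open `[t - w, t)` over the raw
  native-rate samples, so spectral features keep the sensor's full
  bandwidth; rows with insufficient heart-rate history are dropped, not
  imputed.
* **Ties.** Cluster assignment breaks centroid-distance ties toward the
  lower cluster index; LPP eigenvector signs are fixed by making each
  column's largest-magnitude loading positive.
* **Scalability.** The LPP graph and k-means are fitted on at most 3000
  evenly spaced training rows (a dense k-NN distance matrix over a full
  multi-day recording would be prohibitively large); projection and
  assignment of all rows are exact.

## The power table

Two per-sensor current tables ship with the package. The *measured* table
contains bench measurements of the prototype wristband (full function
4.13 mA; accelerometer increment 0.32; environmental pair 0.27) and chest
patch (5.89 mA; accelerometer 2.70; EKG 2.67), with the ankle
accelerometer assigned the chest-accelerometer increment and skin
temperature/EDA assigned the wrist-accelerometer increment. These raw
measurements, however, are not mutually consistent with the published
per-configuration reduction accounting. The *default* table is therefore
reconstructed: each published reduction cell equals the sum of the
disabled sensors' increments, which yields a small linear system; with the
symmetry assumption that the environmental-temperature and humidity
sensors draw equal current, the increments are exactly determined
(body temperature 0.312, environmental temperature 0.263, humidity 0.263,
EDA 0.312, heart rate 2.673 mA), and the total system current (9.9466 mA)
is pinned by the published percentage values. The wrist/ankle
accelerometer increments are not identifiable from those cells (they are
active in every configuration) and carry the measured values; they only
matter for the weighted penalty scheme. The weighted-scheme reduction
table published for the prototype is internally inconsistent with either
current table (its largest cells imply a wrist increment near 3.2 mA);
the package documents rather than resolves this, and makes no claim to
reproduce it.

## The synthetic-data generator

`simulate_recording()` emulates a four-day exercise protocol: 10 min walk,
20 min alternating walk/run laps (150 s / 90 s), 10 min rest, two 15 min
exercise sessions separated by 5 min rest, and two final 10 min walks.
Alternatively a semi-Markov schedule (transition matrix + exponential
dwells) generates free-living-like state sequences. Signals are
deliberately minimal mechanistic models:

* **Accelerometers** — per state, a sinusoid of state-specific amplitude
  (rest 0.05 g, walk 0.5, exercise 0.8, run 1.2) and frequency (0.3, 1.8,
  0.9/1.3 alternating in 10 s bursts, 2.8 Hz) plus white noise, modulated
  by a slow per-sensor lognormal intensity factor (sd 0.05, 10 s blocks).
  The modulation reflects that movement intensity fluctuates within an
  activity and that wrist and ankle intensities are not perfectly coupled;
  without it the two accelerometers would be exactly collinear at the
  state level and no sensor-selection question would be well posed. The
  default is kept small because the amplitude-driven features dominate
  the clustering metric; the support-recovery test harness raises it to
  0.2, where cross-sensor identifiability rather than state separability
  is the property under test.
* **Heart rate** — first-order relaxation to per-state setpoints (70, 100,
  130, 150 bpm; time constant 30 s) observed with 1 bpm noise. This is the
  simplest identifiable model of the activity–heart-rate coupling the
  method exploits.
* **EDA** — first-order response (60 s) to per-state arousal gains plus a
  slow tonic drift; **temperatures/humidity** — near-constant with small
  noise, matching the observation that ambient conditions barely move
  within a session.

Ground-truth labels (state and protocol segment) are emitted for testing
only; the pipeline never reads them. Each day uses a fresh seed offset, so
days are independent realizations and honest cross-validation folds. What
the generator does *not* model: motion artifacts, sensor dropouts, device
noise spectra, HR variability beyond first-order dynamics, or
physiologically validated EDA. Passing tests on this generator demonstrate
the estimation machinery, not clinical validity on real recordings.

`plant_linear_response()` overwrites the heart-rate stream with a known
sparse linear signal for support-recovery testing: chosen groups
contribute through their standardized window features, and the heart-rate
group contributes autoregressively (coefficient on the response lagged by
`dh`), so that the history features later rebuilt from the new stream are
genuinely predictive. A flat formulation — coefficients on the *original*
stream's history features — would make the planted heart-rate support
unrecoverable after the target is replaced.

## What cross-validation can and cannot select

With strong planted signal the day-wise CV reliably *contains* the true
sensor support: in the package's recovery tests no planted sensor is
dropped, and on the regularization path the planted groups persist to
larger penalties than every decoy. Exact recovery of the support is a
different matter: for any penalty above the first noise group's entry
point the CV curve is still decreasing (active-group shrinkage is still
being resolved while noise groups cost nothing), so the RMSE-minimizing
penalty sits slightly *below* that entry point and typically admits a
small-coefficient noise group — the familiar over-selection of
CV-minimum rules. Applications that need a harder cut should inspect
`dropout_levels()` and the trade-off curve rather than rely on the raw
argmin; the curve makes explicit how much accuracy each additional
excluded sensor costs.

## Problem sizes

The package's tests exercise the full pipeline on shortened protocols
(four 60 s segments per day, 2–4 days, both accelerometers at 32 Hz) and
the clustering and recovery properties at the study scale (one full
4800 s protocol day at native rates; 3 semi-Markov days of ~2000 analysis
rows each for 20 planted-support seeds). These sizes were chosen so the
complete suite exercises every code path at realistic signal-to-noise
while remaining comfortable to run repeatedly during development.

## Known limitations

* The activity model is fitted once on training days; there is no online
  adaptation or streaming update.
* Current accounting assumes the aggregator knows the active cluster and
  switches sensor sets instantaneously; transition costs and radio energy
  are out of scope.
* The weighted scheme's published reduction table cannot be reproduced
  from any self-consistent per-sensor table (see above); weighted-scheme
  results are computed from the package's tables instead.
* Feature extraction is fixed to the documented 21/6/3-feature sets;
  wavelet or HRV-style features are out of scope.
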