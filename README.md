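# pmcast

Hybrid spatio-temporal forecasting for urban PM2.5 sensor networks.

Dense city monitoring networks mix a few reference-grade government
monitors with many low-cost sensors that are noisy and intermittently
available (availability on the order of 90% vs 30%). `pmcast` is for
researchers who want fine-grained hourly pollution predictions — including
at locations with no working sensor — from such a network, and who need
the whole chain to be testable offline: the package ships a seeded
synthetic-city generator that reproduces the statistical structure the
models assume.

## The model

A reading `y_{v,t}` at sensor `v` and hour `t` is decomposed into three
parts, each handled by a dedicated stage:

1. **Gap filling.** A linear-Gaussian spatio-temporal hierarchical
   state-space model: `y_{v,t} = a_v + s_{hour(t)} + z_{v,t} + eps`, with a
   latent field `z_t = phi z_{t-1} + eta_t`, `eta ~ N(0, sigma_sp^2
   exp(-d/rho))` over pairwise distances `d`. It is fit by EM (Kalman
   smoothing in the E-step; closed-form M-step with a profile search over
   `rho`), handles missing cells exactly, and imputes them with the
   smoothed posterior mean.
2. **Diurnal baseline.** Per sensor, one ordinary-least-squares cubic
   `alpha t^3 + beta t^2 + kappa t + nu` per 8-hour slot of the day
   (midnight-8am, 8am-4pm, 4pm-midnight), pooled across days — the
   "average day" at that location.
3. **Residual dynamics.** A message-passing recurrent neural network on
   the complete sensor graph. Each hour, every node encodes its reading
   into a hidden state (`O_v`), exchanges messages with all other nodes
   through a shared operator that embeds the pairwise Euclidean distance
   (`M`, summed over neighbors, then `U`), advances a per-node LSTM
   (`T_v`), and decodes the next-hour prediction (`R_v`). A prediction at
   a node never consumes that node's own readings, so the network predicts
   at unmonitored ("virtual") locations by construction. Forward and
   backward passes are authored in vectorized base R and verified against
   finite differences.

Stages compose additively (`prediction = baseline + residual model`), in
either order, and every composition in the standard ten-model comparison
is available as a named preset (`pipeline_presets()`), including the best
performer: per-sensor spline with state-space imputation plus residual
MPRNN (`preset_pipeline("best")`).

Evaluation is masked (only truly observed cells count), reports MAPE and
RMSE per sensor and per tier, daily hazard-exceedance precision/recall
against the 60 ug/m3 daily standard, co-location correlation diagnostics,
and network-size ablations.

## Worked example

```r
library(pmcast)

city <- simulate_city(sim_config(n_sites = 20, n_days = 120, seed = 1))
city$observed
#> <readings_panel> 20 sites x 2880 hours  [2018-05-01 00:00 IST .. 2018-08-28 23:00 IST]
#>   observed: 59.7%  mean: 133.7 ug/m3

fit <- fit_pipeline(preset_pipeline("best", seed = 1, profile = "desk"),
                    city$observed, city$sites, split = 0.75)
truth_test <- split_train_test(city$truth, 0.75)$test
mape(fit$predictions, truth_test)
#> [1] 64.52745
rmse(fit$predictions, truth_test)
#> [1] 31.0683
```

The test span covers the last 30 synthetic days; ~65% mean absolute
percentage error against the noiseless ground truth (the MAPE denominator
is punishing when the truth dips toward zero) and ~31 ug/m3 RMSE — versus
88.8% / 34.8 ug/m3 for the spline baseline alone on the same split, so the
residual network and imputation stages carry real signal. The `"full"`
profile (hidden size 256, 30 epochs, every sliding window) is the
full-scale configuration; `"desk"` (hidden 32, 12 epochs, stride-2
windows) is sized for laptops and CI.

A thin command-line front end is installed with the package
(`system.file("cli", "pmcast", package = "pmcast")`) with subcommands
`simulate`, `impute`, `fit-spline`, `train`, `predict`, `evaluate`, and
`run`.

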