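# optorc

Reverse-correlation and linear–nonlinear (LN) analysis of two-state
navigation behavior under binary optogenetic stimulation.

## The problem

Navigating fly larvae alternate between two motor states — *runs*
(forward crawling) and *turns* (head sweeping) — and chemosensory
input steers them by modulating the rates of the two transitions,
run→turn and turn→run.  Driving a chemosensory neuron optogenetically
with binary white noise (lights ON/OFF, coded +1/−1, at 4 Hz) turns
the whole animal into a transducer whose input–output relation can be
measured by reverse correlation.  `optorc` implements that analysis
chain for anyone modeling state-transition behavior driven by a
designed stimulus:

1. **Stimulus design** — Bernoulli white noise for estimation; steps
   and pulse trains ("defined flicker") for validation.
2. **Filter estimation** — the event-triggered average
   `C(τ)` (mean ± SEM stimulus history preceding each transition)
   becomes a causal linear filter via the mean event rate:
   `h(τ) = (n̄/T)·C(−τ)`, with `T = 1200` s trials.
3. **Static nonlinearity** — the linear prediction `h∗s` is compared
   with the observed per-bin transition rates and fitted by least
   squares (sigmoid for run→turn, line for turn→run).
4. **LN prediction** — per-bin transition probability
   `p(t) = 1 − exp(−N((h∗s)(t))·dt)` for *any* stimulus waveform.
5. **Significance machinery** — pooled two-proportion z-tests of PSTH
   bins against baseline (with the `np ≥ 5` validity rule) and
   per-lag Welch t-tests of triggered averages against controls.
6. **Synthetic ground truth** — a stochastic two-state simulator whose
   hazards are LN functionals of the stimulus, with crawling-speed
   traces that decelerate 1 s before each run→turn transition, so the
   whole chain is testable by parameter recovery without any external
   data.

## Worked example

Simulate a population of 120 larvae expressing a repellant-type
response, then recover what generated it:

```r
library(optorc)

stim   <- generate_bernoulli(duration = 1200, dt = 0.25, p_on = 0.5, seed = 7)
truth  <- default_ground_truth("repulsive-monophasic")
tracks <- simulate_population(truth, stim, n_animals = 120, seed = 100,
                              speed_model = speed_model())

events <- extract_transitions(tracks)
table(events$kind)
#> RUN_TO_TURN TURN_TO_RUN
#>        2875        2868

ta <- triggered_average(events, stim, kind = "RUN_TO_TURN", window = 4)
ta
#> <triggered_average> RUN_TO_TURN, 2860 events (15 excluded), 17 lags over [-4, 0] s
```

2875 run→turn transitions from 120 animals; 15 happened too early in
the trial to have a full 4 s stimulus history and are excluded.  The
average is converted to a filter and, here, checked against the
generative truth:

```r
f <- filter_from_ta(ta, mean_events_per_trial = ta$n_events / length(tracks))
cor(f$h, truth$filters$RUN_TO_TURN$h)
#> [1] 0.983
```

Fit the full LN model (filters and nonlinearities for both transition
directions) and predict the response to a stimulus the model never
saw — a step from OFF to ON at t = 30 s:

```r
model <- fit_ln_model(tracks, stim)
model$nonlins$RUN_TO_TURN$r_squared
#> [1] 0.941

step <- make_step(60, switch_times = 30, initial = -1)
pred <- predict_response(model, step, kind = "RUN_TO_TURN")
round(subset(pred, time_s >= 28 & time_s <= 34)$p, 4)
#>  [1] 0.0018 0.0018 0.0018 0.0018 0.0018 0.0018 0.0018 0.0018 0.0018 0.0022
#> [11] 0.0031 0.0049 0.0077 0.0102 0.0117 0.0124 0.0125 0.0126 0.0125 0.0122
#> [21] 0.0120 0.0120 0.0118 0.0116 0.0115
```

The per-bin turn probability rises ~7-fold over the two seconds after
lights ON — the repellant response — and settles as the 4 s filter
window fills.  The speed machinery recovers the built-in deceleration
lead:

```r
on <- deceleration_onsets(tracks)
mean(on$onset_s, na.rm = TRUE)
#> [1] -1.15
```

i.e. runs start slowing about one second before the turn begins.

## Command line

Every stage is scriptable via the bundled CLI wrapper
(`inst/cli/optorc`), e.g.:

```sh
optorc stim bernoulli --duration 1200 --seed 7 --out stim.csv
optorc simulate --model repulsive-monophasic --stim stim.csv \
       --n-animals 120 --seed 100 --out tracks.csv
optorc fit --tracks tracks.csv --stim stim.csv --out model.json
optorc predict --model model.json --stim step.csv --out pred.csv
optorc demo --dir demo --seed 1     # end-to-end pipeline on simulated data
```

All artifacts are plain CSV/JSON with documented columns.

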