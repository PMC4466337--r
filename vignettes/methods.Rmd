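---
title: "Reverse correlation and LN models of run/turn navigation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse correlation and LN models of run/turn navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optorc)
```

## The model

Larval navigation is abstracted as alternation between two motor
states: *runs* (forward peristaltic crawling) and *turns* (head
sweeping until a new heading is chosen).  A sensory stimulus modulates
the instantaneous hazard of leaving the current state.  For each
transition direction (run→turn, turn→run) the hazard is modeled as a
linear–nonlinear (LN) cascade:

$$ r(t) \;=\; N\!\Big( \sum_k h(\tau_k)\, s(t - \tau_k)\, \Delta t \Big), $$

where $s(t) \in \{-1, +1\}$ is the binary optogenetic stimulus (−1
lights OFF, +1 ON) on a 4 Hz clock, $h(\tau)$ is a causal linear filter
over the last 4 s of stimulus history, and $N$ is a memoryless
nonnegative function (a sigmoid or a line) that repairs the two
defects of a purely linear readout: negative rates and missing
saturation.

With a *balanced Bernoulli* stimulus — independent ±1 per sample — the
stimulus autocorrelation is a delta function, so the cross-correlation
of stimulus and transition events is proportional to the filter
itself.  In practice the filter is estimated from the
*event-triggered average* $C(\tau)$, the mean stimulus history
preceding transitions of one kind, scaled by the mean event rate:

$$ h(\tau) \;=\; \frac{\bar n}{T}\, C(-\tau), $$

with $\bar n$ the average number of events per trial and $T$ the trial
duration (1200 s, a 20-minute trial).  Binary (rather than Gaussian)
noise is used because optogenetic activation at a fixed intensity only
requires the assumption of a consistent spiking response to light ON,
not linearity of spiking in intensity.

Per-bin transition probabilities follow from the hazard through
$p = 1 - \exp(-r\,\Delta t)$, which is exact for the underlying
inhomogeneous point process and maps any nonnegative rate to a valid
probability (a plain $r\,\Delta t$ does not).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dt` | 0.25 | s | camera/LED clock (4 Hz); single global clock shared by stimulus and behavior |
| `window` | 4 | s | filter history length; turns last < 4 s, bounding the usable stimulus history |
| `trial_duration` | 1200 | s | 20-minute trials; enters the Eq. above through $\bar n / T$ |
| `p_on` | 0.5 | – | balanced ON/OFF keeps the stimulus zero-mean, making the triggered average unbiased |
| `n_bins` | 20 | – | equal-count drive bins for the nonlinearity fit |
| `alpha` | 0.05 | – | per-bin significance threshold, no multiple-testing correction by default |

The lag grid of a triggered average runs from $-W$ to $0$ *inclusive*
(the sample containing the event is lag 0), so a window of 4 s yields
17 lags and a 17-tap filter.

## What the synthetic-data generator emulates

`simulate_population()` is the package's ground truth: each animal is
a two-state Markov chain on the stimulus clock whose per-bin escape
probabilities are $1 - \exp(-r\,\Delta t)$ with $r$ the LN hazard of
the appropriate transition.  All animals share the stimulus; animal
$i$ consumes an RNG stream seeded `seed + i`, so any animal is
reproducible independently of population size (when comparing two
populations, keep their base seeds more than a population size apart,
or the streams overlap).

`default_ground_truth()` provides four documented worlds spanning the
observed filter shape classes: attractive/repulsive ×
monophasic/biphasic.  Numeric choices, made once:

* **Filter shapes.** Raised-cosine lobes on the 0.25 s grid.
  Monophasic run→turn filters have a single lobe inside the last 2 s;
  biphasic filters add an earlier opposing lobe of equal area (zero net
  integral), which produces transient, adapting step responses.
  Turn→run filters have a single recent lobe of the opposite sign of
  the run→turn valence — the shape observed for every driver.  Filters
  are scaled so the linear drive under Bernoulli stimulation has unit
  SD (0.7 for turn→run), making sigmoid slopes interpretable in
  drive-SD units.
* **Rates.** Sigmoid floor 0.005 /s and amplitude 0.04 /s for
  run→turn; line intercept 0.33 /s (gain 0.1) for turn→run.  These
  give mean runs near 47 s, mean turns near 3 s, and ≈ 20 transitions
  of each kind per animal per 20-minute trial — the per-animal counts
  implied by real recordings (thousands of transitions from 100–200
  larvae).  An earlier draft used hazards ten times higher; see
  *Known limitations* for why that matters.
* **Speed.** Runs at 1.0 mm/s (SD 0.1), turns at 0.3 mm/s (SD 0.05) —
  second-instar crawling speeds with ~10% within-run variability —
  with a *linear* ramp from the run level to the turn level over the
  `decel_lead = 1` s preceding each run→turn transition.  Only the
  onset of deceleration is empirically located; the linear ramp shape
  is a modeling choice.
* **Initial state.** All animals start in RUN; analyses discard a 10 s
  burn-in so the initial condition (and the zero-padded convolution
  history) never enters estimates.

The generator does **not** emulate: 2-D trajectories, head-sweep
kinematics and turn-angle choice, within-turn modulation beyond the
turn→run hazard, animal-to-animal parameter heterogeneity, or tracking
artifacts (lost/merged animals).  A green recovery test therefore
establishes correctness of the estimation chain on its own generative
terms — not that real larvae are two-state LN automata.

## Numerical choices

* **Event timestamps** are the first sample of the new state; events
  whose history window would reach before the stimulus start are
  excluded (and counted) rather than padded.
* **Nonlinearity estimation** pools all at-risk bins, bins them into
  equal-count drive bins, and converts the per-bin transition fraction
  $\hat p$ to a rate with $\hat r = -\log(1-\hat p)/\Delta t$ — the
  exact inverse of the hazard→probability map used by the simulator
  and the predictor.  The naive estimator $\hat p / \Delta t$
  (transitions per unit at-risk time) is available as
  `rate_method = "naive"`; it is biased low by ≈ $r\Delta t/2$, which
  is visible at high hazards.
* **Sigmoid fits** standardize the drive axis internally (the raw
  drive scale is arbitrary, set by $\bar n/T$), use
  `nls(algorithm = "port")` with quantile-based starts and box
  constraints, polish with Nelder–Mead, and map parameters back.
* **Speed standard scores** use the population SD (divide by $n$) over
  RUN samples of the same animal; the convention is fixed everywhere.
* **Deceleration onset** is the last sign change (≥ 0 to < 0) of the
  first difference of a centered moving average (width 0.5 s, i.e.
  3 samples) that is followed by monotone non-increase up to the
  event; multi-dip profiles therefore report the *last* dip.  If the
  speed falls throughout the search window the window start is
  returned; a monotone rise signals not-found.
* **Two-proportion z-tests** use the pooled-proportion statistic with
  the $np \ge 5$, $n(1-p) \ge 5$ validity flag; degenerate bins
  (pooled proportion 0 or 1) are reported invalid rather than failing
  a whole trace.  Per-lag comparisons of triggered averages against a
  control use Welch t-tests reconstructed from the per-lag mean, SD
  and n that every triggered average retains.
* **Discrete bout durations** under a constant hazard are geometric;
  goodness-of-fit tests use the randomized probability integral
  transform (a plain KS test is invalid on tied discrete data), and
  mean-bout checks compare against the exact discrete closed form
  $\Delta t / (1 - e^{-r \Delta t})$.

## Design decisions that were genuinely open

* **Drive units.** The x-axis of the fitted nonlinearity is the
  linearly predicted rate from the scaled filter, so $N$ reads as
  "actual rate as a function of linearly predicted rate".
* **Step-time snapping** rounds to the nearest sample boundary with
  ties toward the earlier sample.
* **Per-bin at-risk accounting** starts when the animal enters the
  source state; an animal mid-turn at stimulus onset counts as at risk
  for turn→run from the first bin it is observed in TURN.
* **Form choice per transition** follows the empirical practice —
  sigmoid for run→turn, line for turn→run — with `form = "auto"`
  (adjusted $R^2$) available.

## Known limitations

**Triggered averages of renewal processes carry a selection bias.**
An event at $t$ requires the animal to occupy the source state at
$t-1$; histories that would have ended the state earlier are
under-represented, and the at-risk pool itself is depleted after
hazard-raising stimulus epochs.  The estimated filter consequently
rides on a small negative (for repulsive valence) pedestal spread over
all lags.  The pedestal scales with hazard × window: at the default
world's realistic rates it is minor, but it grows quadratically as
hazards rise — which is why the generator's rates are anchored to
realistic transition counts rather than convenience values.  Pearson
correlation with the true filter is insensitive to it (criterion-level
recovery r ≈ 0.97–0.99), and predictions for fluctuating (flicker)
stimuli are accurate; the visible casualty is the DC component of
*step* responses, where the predicted baseline can sit a fraction of a
percent (in per-bin probability) away from the truth — the same regime
in which step predictions are reported to degrade for real larvae.
GLM-style estimators would remove the bias but are out of scope: the
triggered average *is* the method under study.

**Prediction horizon.** Filters are limited to ~4 s of history by the
duration of turns, so responses beyond ~4 s of a stimulus change (e.g.
slow adaptation) are outside the model class.

**Acceptance-test scales.** The nonlinearity-recovery battery uses a
faster-switching ground truth (sigmoid floor 0.03, amplitude 0.5 /s)
so that $10^6$ at-risk bins carry ~2×10^5 transitions; at the default
world's rates the same precision would need ~10^7 bins.  The LN
self-consistency check pools step and flicker validation bins and uses
exact (Clopper–Pearson) binomial bands, since baseline step bins have
$np < 5$ where the normal band is invalid by the package's own rule.
Significance onset/offset summaries take the first/last significant
bin at the 0.05 level without multiplicity correction; with ~90
post-step bins an isolated false positive can nudge the offset, which
is why the biphasic-vs-monophasic ordering check reports the margin
rather than a point estimate.
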