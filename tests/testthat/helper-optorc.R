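# Shared fixtures, all built in code.

# "RRRTTR" -> state_track
track_from_string <- function(s, dt = 0.25, t0 = 0, speed = NULL,
                              animal_id = "a1") {
  states <- ifelse(strsplit(s, "")[[1]] == "R", "RUN", "TURN")
  state_track(animal_id, states, dt = dt, t0 = t0, speed = speed)
}

# ground truth with stimulus-independent hazards (zero filters)
constant_hazard_model <- function(r_rt, r_tr, n_taps = 17) {
  ln_model(
    linear_filter(rep(0, n_taps), kind = "RUN_TO_TURN"),
    linear_filter(rep(0, n_taps), kind = "TURN_TO_RUN"),
    static_nonlinearity("linear", list(intercept = r_rt, gain = 0)),
    static_nonlinearity("linear", list(intercept = r_tr, gain = 0))
  )
}

# faster-switching world used by the recovery batteries: same filters as
# the default ground truth but hazards high enough that 1e6 at-risk bins
# carry ~2e5 transitions
fast_ground_truth <- function(kind = "repulsive-monophasic") {
  truth <- default_ground_truth(kind)
  truth$nonlins$RUN_TO_TURN <- static_nonlinearity(
    "sigmoid", list(floor = 0.03, amplitude = 0.5, slope = 1.2, midpoint = 0.3))
  truth$nonlins$TURN_TO_RUN <- static_nonlinearity(
    "linear", list(intercept = 0.5, gain = 0.2))
  truth
}

# brute-force event-triggered average: naive double loop over events and
# lags, independent of the vectorized implementation
naive_triggered_average <- function(event_idx, values, n_lags) {
  acc <- numeric(n_lags)
  for (i in event_idx) {
    for (j in seq_len(n_lags)) {
      acc[j] <- acc[j] + values[i - n_lags + j]
    }
  }
  acc / length(event_idx)
}

# uniformly random event times, independent of any stimulus; sampled
# without replacement so no two events share a stimulus sample (events
# landing on the same sample would inflate the SEM beyond 1/sqrt(n))
null_events <- function(n_events, t_min, t_max, dt = 0.25, seed = 1) {
  set.seed(seed)
  grid <- seq(round(t_min / dt), round(t_max / dt))
  data.frame(
    animal_id = "null",
    time_s = sample(grid, n_events, replace = n_events > length(grid)) * dt,
    kind = "RUN_TO_TURN"
  )
}

# mean per-aligned-bin prediction: average the predicted trace over the
# aligned windows used by an empirical PSTH
aligned_prediction <- function(pred, align_times, rel_times) {
  ok <- !pred$burn_in
  t_ok <- pred$time_s[ok]
  p_ok <- pred$p[ok]
  vapply(rel_times, function(rt) {
    mean(p_ok[vapply(align_times, function(a) which.min(abs(t_ok - (a + rt))),
                     integer(1))])
  }, numeric(1))
}

# exact binomial (Clopper-Pearson) band of an observed PSTH
psth_band <- function(psth, level = 0.95) {
  a <- (1 - level) / 2
  list(lo = qbeta(a, psth$k, psth$n - psth$k + 1),
       hi = qbeta(1 - a, psth$k + 1, psth$n - psth$k))
}
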