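# Ground-truth LN-driven two-state stochastic simulator.  Populations of
# synthetic larvae alternate between RUN and TURN; the hazard of leaving
# the current state is the LN functional of the shared light stimulus,
# and a transition occurs in a bin with probability 1 - exp(-r dt).

#' Construct a state track
#'
#' One animal's RUN/TURN state sequence, aligned to the stimulus clock,
#' with an optional crawling-speed trace of the same length.
#'
#' @param animal_id identifier (coerced to character).
#' @param states character vector over `"RUN"`, `"TURN"`.
#' @param dt sample interval (s).
#' @param t0 time of the first sample (s).
#' @param speed optional numeric speed trace (same length as `states`).
#' @return An object of class `state_track`.
#' @export
state_track <- function(animal_id, states, dt = 0.25, t0 = 0, speed = NULL) {
  check_scalar_number(dt, "dt", positive = TRUE)
  if (length(states) < 1L) stop_invalid("a track needs at least one sample")
  if (!all(states %in% .STATES)) {
    stop_invalid("states must all be \"RUN\" or \"TURN\"")
  }
  if (!is.null(speed) && length(speed) != length(states)) {
    stop_invalid("`speed` must have the same length as `states`")
  }
  structure(
    list(animal_id = as.character(animal_id), states = as.character(states),
         dt = dt, t0 = t0, speed = speed),
    class = "state_track"
  )
}

#' @export
print.state_track <- function(x, ...) {
  cat(sprintf("<state_track> animal %s, %d samples at dt = %g s (%.0f%% RUN)%s\n",
              x$animal_id, length(x$states), x$dt,
              100 * mean(x$states == "RUN"),
              if (is.null(x$speed)) "" else ", with speed"))
  invisible(x)
}

#' Speed model for the simulator
#'
#' Gaussian speed around a state-dependent mean, with a linear
#' deceleration ramp from the run level down to the turn level over the
#' `decel_lead` seconds preceding every run-to-turn transition --
#' emulating the observation that runs decelerate about one second
#' before turning starts.  Defaults are in mm/s and sized for a
#' second-instar larva (runs near 1 mm/s with ~10% variability, slow
#' head-sweeping at 0.3 mm/s).
#'
#' @param run_mean,run_sd mean and SD of speed during runs.
#' @param turn_mean,turn_sd mean and SD during turns.
#' @param decel_lead seconds of pre-transition deceleration (default 1).
#' @return An object of class `speed_model`.
#' @export
speed_model <- function(run_mean = 1.0, run_sd = 0.1,
                        turn_mean = 0.3, turn_sd = 0.05,
                        decel_lead = 1.0) {
  if (!(run_mean > turn_mean && turn_mean >= 0)) {
    stop_invalid("need run_mean > turn_mean >= 0")
  }
  if (run_sd < 0 || turn_sd < 0 || decel_lead < 0) {
    stop_invalid("run_sd, turn_sd and decel_lead must be >= 0")
  }
  structure(list(run_mean = run_mean, run_sd = run_sd, turn_mean = turn_mean,
                 turn_sd = turn_sd, decel_lead = decel_lead),
            class = "speed_model")
}

# raised-cosine bump on the tau grid; the building block of the default
# ground-truth filters
.rc_bump <- function(taus, peak, width) {
  out <- numeric(length(taus))
  sel <- abs(taus - peak) < width
  out[sel] <- 0.5 * (1 + cos(pi * (taus[sel] - peak) / width))
  out
}

#' Default ground-truth LN models
#'
#' Four documented parametric models covering the observed filter shape
#' classes.  The run-to-turn filter of a *repulsive* model has a
#' positive lobe just before the transition (light ON promotes turning);
#' an *attractive* model has the negated shape.  *Monophasic* filters
#' have that single lobe; *biphasic* filters add an earlier opposing
#' lobe of equal area, producing transient (adapting) step responses.
#' Turn-to-run filters carry the opposite sign of the run-to-turn
#' valence with a single recent lobe, as that shape was common to every
#' driver examined.
#'
#' Filters live on a 0.25 s grid with 4 s of support.  Run-to-turn
#' filters are scaled so that the linear drive under balanced Bernoulli
#' stimulation has unit standard deviation; turn-to-run filters are
#' scaled to 0.7 drive SD.  Nonlinearities are a sigmoid for run-to-turn
#' (floor 0.005 /s, amplitude 0.04 /s, slope 1.2 per drive SD, midpoint
#' 0.3) and a clipped line for turn-to-run (intercept 0.33 /s, gain
#' 0.1).  These rates give mean runs near 45 s and mean turns near 3 s,
#' i.e. roughly 20 transitions of each kind per animal per 20-minute
#' trial -- the transition counts reported for real larva populations
#' (thousands of transitions from ~100-200 animals).
#'
#' @param kind one of `"attractive-monophasic"`, `"attractive-biphasic"`,
#'   `"repulsive-monophasic"`, `"repulsive-biphasic"`.
#' @param dt sample interval (s).
#' @return An [ln_model()] usable as a generative ground truth.
#' @export
default_ground_truth <- function(kind = "attractive-monophasic", dt = 0.25) {
  choices <- c("attractive-monophasic", "attractive-biphasic",
               "repulsive-monophasic", "repulsive-biphasic")
  if (!(is.character(kind) && length(kind) == 1L && kind %in% choices)) {
    stop_invalid("`kind` must be one of ", paste(choices, collapse = ", "))
  }
  taus <- seq(0, 4, by = dt) # matches the default 4 s estimation window
  valence <- if (startsWith(kind, "repulsive")) 1 else -1

  if (endsWith(kind, "monophasic")) {
    # single lobe within the last 2 s before the event
    shape <- .rc_bump(taus, peak = 1.0, width = 1.0)
  } else {
    # recent lobe plus an earlier opposing lobe of equal area
    pos <- .rc_bump(taus, peak = 0.6, width = 0.6)
    neg <- .rc_bump(taus, peak = 2.0, width = 1.0)
    shape <- pos - neg * (sum(pos) / sum(neg))
  }
  # unit drive SD under +/-1 Bernoulli stimulation: sqrt(sum((h dt)^2)) = 1
  h_rt <- valence * shape / sqrt(sum((shape * dt)^2))

  tr_shape <- .rc_bump(taus, peak = 0.75, width = 0.75)
  h_tr <- -valence * 0.7 * tr_shape / sqrt(sum((tr_shape * dt)^2))

  ln_model(
    linear_filter(h_rt, dt = dt, kind = .KIND_RT),
    linear_filter(h_tr, dt = dt, kind = .KIND_TR),
    static_nonlinearity("sigmoid", list(floor = 0.005, amplitude = 0.04,
                                        slope = 1.2, midpoint = 0.3)),
    static_nonlinearity("linear", list(intercept = 0.33, gain = 0.1)),
    provenance = list(ground_truth = kind)
  )
}

#' Simulate a population of larvae from a ground-truth LN model
#'
#' Every animal shares the stimulus clock.  At each time bin the hazard
#' of leaving the current state is `r(t) = N(h * s)(t)` for the
#' appropriate transition kind, and a transition occurs with probability
#' `1 - exp(-r(t) dt)` (exact for the underlying inhomogeneous point
#' process, and a valid probability for any nonnegative rate).  All
#' animals start in RUN; discard an initial burn-in downstream before
#' analysis.  Convolution history before the stimulus start is treated
#' as zero (see [linear_predict()]).
#'
#' Reproducibility is animal-by-animal: animal `i` consumes the RNG
#' stream seeded with `seed + i`, so the same animal index yields the
#' same track regardless of population size.
#'
#' @param model an [ln_model()] ground truth.
#' @param stim a [stimulus_train()].
#' @param n_animals number of animals (>= 1).
#' @param seed integer base seed.
#' @param speed_model optional [speed_model()]; when given, tracks carry
#'   speed traces with the pre-transition deceleration ramp.
#' @return A list of [state_track()]s, one per animal.
#' @export
simulate_population <- function(model, stim, n_animals, seed,
                                speed_model = NULL) {
  if (!inherits(model, "ln_model")) stop_invalid("`model` must be an ln_model")
  if (!inherits(stim, "stimulus_train")) stop_invalid("`stim` must be a stimulus_train")
  if (!(is.numeric(n_animals) && length(n_animals) == 1L && n_animals >= 1)) {
    stop_invalid("`n_animals` must be >= 1")
  }
  n_animals <- as.integer(n_animals)
  n <- length(stim$values)
  dt <- stim$dt

  p_leave <- lapply(.KINDS, function(k) {
    r <- eval_nonlinearity(model$nonlins[[k]],
                           linear_predict(model$filters[[k]], stim)$rate)
    if (any(!is.finite(r))) {
      stop_simulation("non-finite ", k, " hazard at time bin ",
                      which(!is.finite(r))[1L])
    }
    1 - exp(-r * dt)
  })
  names(p_leave) <- .KINDS
  p_rt <- p_leave[[.KIND_RT]]
  p_tr <- p_leave[[.KIND_TR]]

  # per-animal RNG streams (counter scheme: seed + animal index)
  U <- matrix(0, nrow = n, ncol = n_animals)
  Z <- if (!is.null(speed_model)) matrix(0, nrow = n, ncol = n_animals)
  for (i in seq_len(n_animals)) {
    set.seed(seed + i)
    U[, i] <- stats::runif(n)
    if (!is.null(Z)) Z[, i] <- stats::rnorm(n)
  }

  # time-major sweep, vectorized over animals; TRUE = RUN
  S <- matrix(NA, nrow = n, ncol = n_animals)
  S[1L, ] <- TRUE
  for (t in seq_len(n)[-1L]) {
    prev <- S[t - 1L, ]
    u <- U[t, ]
    S[t, ] <- (prev & u >= p_rt[t]) | (!prev & u < p_tr[t])
  }

  lead_bins <- if (!is.null(speed_model)) {
    round(speed_model$decel_lead / dt)
  } else 0L

  tracks <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    run <- S[, i]
    states <- ifelse(run, "RUN", "TURN")
    speed <- NULL
    if (!is.null(speed_model)) {
      sm <- speed_model
      mu <- ifelse(run, sm$run_mean, sm$turn_mean)
      sdv <- ifelse(run, sm$run_sd, sm$turn_sd)
      if (lead_bins > 1L) {
        ev <- which(!run & c(FALSE, run[-n])) # first TURN bins
        for (e in ev) {
          for (j in seq_len(lead_bins - 1L)) {
            idx <- e - j
            if (idx < 1L || !run[idx]) break
            frac <- 1 - j * dt / sm$decel_lead
            mu[idx] <- sm$run_mean + (sm$turn_mean - sm$run_mean) * frac
          }
        }
      }
      speed <- mu + sdv * Z[, i]
    }
    tracks[[i]] <- state_track(sprintf("animal_%04d", i), states, dt = dt,
                               t0 = stim$t0, speed = speed)
  }
  tracks
}

# ---- tracks CSV -------------------------------------------------------

#' Read and write track CSV files
#'
#' Long format with columns `animal_id, time_s, state, speed` (speed
#' blank when absent).
#'
#' @param tracks a list of [state_track()]s (for writing).
#' @param path file path.
#' @return `read_tracks_csv()` returns a list of [state_track()]s;
#'   `write_tracks_csv()` returns `path` invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "state_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(
      animal_id = tr$animal_id,
      time_s = tr$t0 + (seq_along(tr$states) - 1L) * tr$dt,
      state = tr$states,
      speed = if (is.null(tr$speed)) NA_real_ else tr$speed
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("animal_id", "time_s", "state")
  if (!all(need %in% names(d))) {
    stop_invalid("tracks CSV needs columns ", paste(need, collapse = ", "))
  }
  lapply(split(d, d$animal_id), function(g) {
    g <- g[order(g$time_s), ]
    dt <- if (nrow(g) > 1L) stats::median(diff(g$time_s)) else 0.25
    sp <- if ("speed" %in% names(g) && any(is.finite(g$speed))) g$speed
    state_track(g$animal_id[1L], g$state, dt = dt, t0 = g$time_s[1L],
                speed = sp)
  })
}
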